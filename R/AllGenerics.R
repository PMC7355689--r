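#' @include AllClasses.R
NULL

#' Number of frames in a scene
#' @param x A [Scene-class] or [SceneConfig-class].
#' @return Integer frame count.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname nFrames
#' @export
setMethod("nFrames", "Scene", function(x) x@config@nFrames)

#' @rdname nFrames
#' @export
setMethod("nFrames", "SceneConfig", function(x) x@nFrames)

#' Millimetres per pixel of a scene or calibration
#'
#' The metric scale implied by the known 8 mm instrument shaft width and the
#' rendered (or measured) shaft width in pixels.
#'
#' @param x A [Scene-class] or a calibration list from [makeCalibration()].
#' @return Numeric scalar, mm per pixel.
#' @export
setGeneric("mmPerPx", function(x) standardGeneric("mmPerPx"))

#' @rdname mmPerPx
#' @export
setMethod("mmPerPx", "Scene", function(x) x@truth$mmPerPx)

#' Ground truth of a synthetic scene
#' @param x A [Scene-class].
#' @return List with per-instrument tip positions, visibility, boxes, mask
#'   pixel indices, camera motion, active-arm schedule, arm sides and the
#'   mm-per-px scale.
#' @export
setGeneric("sceneTruth", function(x) standardGeneric("sceneTruth"))

#' @rdname sceneTruth
#' @export
setMethod("sceneTruth", "Scene", function(x) x@truth)

#' Render one frame of a synthetic scene
#'
#' Deterministically rasterizes frame `i`: seeded background texture shifted
#' by the camera offset, each visible instrument as a flat-shaded capsule
#' shaft with a metallic tapered tip and a per-instrument hue/texture, and
#' the arm-status / camera-arm indicator overlays at their fixed positions.
#'
#' @param x A [Scene-class].
#' @param i Frame index (1-based).
#' @return Numeric `height x width x 3` RGB array in \[0, 1\].
#' @export
setGeneric("renderFrame", function(x, i) standardGeneric("renderFrame"))

setMethod("show", "Scene", function(object) {
  cfg <- object@config
  cat(sprintf("Scene: %d frames @ %g fps, %dx%d px, %d instrument(s)\n",
              cfg@nFrames, cfg@fps, cfg@width, cfg@height,
              length(cfg@instruments)))
  cat(sprintf("  shaft %g px (%.4g mm/px), %d exit, %d camera event(s)\n",
              cfg@shaftWidthPx, object@truth$mmPerPx,
              nrow(cfg@exitEvents), nrow(cfg@cameraEvents)))
  invisible(object)
})

setMethod("show", "SkillCohort", function(object) {
  cat(sprintf("SkillCohort: %d subjects (%s)\n", length(object@subjects),
              paste(sprintf("%s=%d", levels(object@labels),
                            tabulate(object@labels)), collapse = ", ")))
  invisible(object)
})

setMethod("show", "SkillModelFit", function(object) {
  cat(sprintf("SkillModelFit <%s>: %d features, CV accuracy %.3f\n",
              object@kind, length(object@featureNames),
              object@cvReport$bestAccuracy))
  if (length(object@cvReport$best))
    cat("  selected:", paste(names(object@cvReport$best),
                             unlist(object@cvReport$best),
                             sep = "=", collapse = ", "), "\n")
  invisible(object)
})

setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport: RMSE %.3f mm over %d samples\n",
              object@rmseMm, object@nCompared))
  cat("  AUC:", paste(sprintf("%s mm=%.3f", names(object@aucAt),
                              object@aucAt), collapse = ", "), "\n")
  cat(sprintf("  Pearson r: x=%.3f y=%.3f; identity switches: %d\n",
              object@pearson[["x"]], object@pearson[["y"]],
              object@identitySwitches))
  invisible(object)
})

#' Accessors for evaluation reports
#' @param x An [EvalReport-class].
#' @return `rmseMm`: numeric; `aucAt`: named numeric; `identitySwitches`:
#'   integer.
#' @name EvalReport-accessors
NULL

#' @rdname EvalReport-accessors
#' @export
rmseMm <- function(x) x@rmseMm

#' @rdname EvalReport-accessors
#' @export
aucAt <- function(x) x@aucAt

#' @rdname EvalReport-accessors
#' @export
identitySwitches <- function(x) x@identitySwitches

#' Labels of a skill cohort
#' @param x A [SkillCohort-class].
#' @return Factor of class labels.
#' @export
cohortLabels <- function(x) x@labels

#' Subjects of a skill cohort
#' @param x A [SkillCohort-class].
#' @return List of per-subject simulation records.
#' @export
cohortSubjects <- function(x) x@subjects
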