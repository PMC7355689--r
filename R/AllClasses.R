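#' @import methods
NULL

#' Synthetic surgical scene configuration
#'
#' Describes a synthetic robotic-surgery scene: frame geometry, the rigid
#' elongated instruments (each a shaft entering from an image border, pivoting
#' about a fixed trocar-like point outside the view, with the tracked tip at
#' the free end), scheduled exit and camera-motion events, and the per-frame
#' arm-activity schedule. At most three instruments may appear (the
#' robotic-surgery view shows at most three) and at most two may be active at
#' once (two instrument arms are driven at a time).
#'
#' @slot width,height Frame size in pixels.
#' @slot fps Frames per second (default 23, the usual da Vinci capture rate).
#' @slot nFrames Number of frames.
#' @slot shaftWidthPx Rendered shaft width in pixels; together with the known
#'   8 mm physical shaft width this fixes the mm-per-pixel scale.
#' @slot tipLengthPx Length of the tapered tip wedge in pixels.
#' @slot instruments List (length 1-3); each element a list with `pivot`
#'   (numeric xy, outside the frame), `hue` in \[0,1), `armSide` ("left" or
#'   "right"), and either `path` (nFrames x 2 matrix of tip positions) or
#'   `waypoints` (matrix with columns frame, x, y, interpolated by natural
#'   splines).
#' @slot exitEvents data.frame(instrument, from, to): the instrument leaves
#'   the view over the interval and re-enters at its end.
#' @slot cameraEvents data.frame(from, to, dx, dy): global out-and-back view
#'   translation with peak amplitude (dx, dy) px; the camera-arm indicator is
#'   shown throughout the interval.
#' @slot activeIntervals data.frame(instrument, from, to): frames during which
#'   the instrument's arm is active (its arm-status indicator is shown).
#' @slot seed Integer; all scene randomness derives from it.
#' @export
setClass("SceneConfig", representation(
  width = "integer", height = "integer", fps = "numeric",
  nFrames = "integer", shaftWidthPx = "numeric", tipLengthPx = "numeric",
  instruments = "list", exitEvents = "data.frame",
  cameraEvents = "data.frame", activeIntervals = "data.frame",
  seed = "integer"
))

validSceneConfig <- function(object) {
  msg <- character(0)
  n <- length(object@instruments)
  if (n < 1 || n > 3)
    msg <- c(msg, "number of instruments must be 1, 2 or 3")
  if (object@width < 32 || object@height < 32)
    msg <- c(msg, "frame must be at least 32 x 32 px")
  if (object@nFrames < 1) msg <- c(msg, "nFrames must be >= 1")
  if (object@fps <= 0) msg <- c(msg, "fps must be > 0")
  if (object@shaftWidthPx < 2) msg <- c(msg, "shaftWidthPx must be >= 2")
  checkEvents <- function(ev, withInstr) {
    if (nrow(ev) == 0) return(NULL)
    if (any(ev$from < 1 | ev$to > object@nFrames | ev$from > ev$to))
      return("event intervals must lie within [1, nFrames]")
    if (withInstr && any(ev$instrument < 1 | ev$instrument > n))
      return("event references an unknown instrument id")
    NULL
  }
  msg <- c(msg, checkEvents(object@exitEvents, TRUE),
           checkEvents(object@cameraEvents, FALSE),
           checkEvents(object@activeIntervals, TRUE))
  if (nrow(object@activeIntervals) > 0 &&
      all(c("from", "to") %in% names(object@activeIntervals))) {
    act <- matrix(FALSE, object@nFrames, max(n, 1))
    ok <- TRUE
    for (k in seq_len(nrow(object@activeIntervals))) {
      iv <- object@activeIntervals[k, ]
      if (iv$from >= 1 && iv$to <= object@nFrames && iv$instrument <= n)
        act[iv$from:iv$to, iv$instrument] <- TRUE
      else ok <- FALSE
    }
    if (ok && any(rowSums(act) > 2))
      msg <- c(msg, "at most 2 instruments may be active simultaneously")
  }
  for (ins in object@instruments) {
    if (is.null(ins$path) && is.null(ins$waypoints))
      msg <- c(msg, "each instrument needs a path or waypoints")
    if (!is.null(ins$armSide) && !ins$armSide %in% c("left", "right"))
      msg <- c(msg, "armSide must be 'left' or 'right'")
  }
  if (length(msg)) msg else TRUE
}
setValidity("SceneConfig", validSceneConfig)

#' Synthetic scene with complete ground truth
#'
#' Produced by [generateScene()]. Holds the configuration, the per-frame
#' ground truth (masks, boxes, tip pixels, visibility, camera motion, active
#' arms, metric calibration), the seeded background texture field and the
#' indicator templates. Frames are rendered on demand with [renderFrame()]
#' so that long scenes need not be held in memory.
#'
#' @slot config A [SceneConfig-class].
#' @slot truth Ground-truth list; access through [sceneTruth()].
#' @slot background Padded background RGB field sampled under camera motion.
#' @slot templates Indicator templates (see [makeIndicatorTemplates()]).
#' @slot pad Background padding in pixels.
#' @export
setClass("Scene", representation(
  config = "SceneConfig", truth = "list", background = "array",
  templates = "list", pad = "integer"
))

#' Synthetic skill cohort
#'
#' Produced by [generateSkillCohort()]: one simulated operation per subject
#' (tip trajectories in mm, indicator states, tip boxes) with a
#' novice/skilled/expert label and the realized motion statistics used by
#' parameter-recovery tests.
#'
#' @slot subjects List of per-subject lists (`trajectory`, `states`, `boxes`,
#'   `realized`, `fps`).
#' @slot labels Factor of class labels (novice < skilled < expert).
#' @slot params The class-conditional generator parameters used.
#' @slot seed Integer seed.
#' @export
setClass("SkillCohort", representation(
  subjects = "list", labels = "factor", params = "list", seed = "integer"
))

setValidity("SkillCohort", function(object) {
  if (length(object@subjects) != length(object@labels))
    return("one label per subject required")
  TRUE
})

#' Fitted surgical-skill classifier
#'
#' Returned by [trainSkillModel()]: the refitted model, the metric
#' normalization transform it expects, and the cross-validation report used
#' for hyperparameter selection.
#'
#' @slot kind "linear", "svm_rbf" or "random_forest".
#' @slot model The underlying fit (nnet::multinom, e1071::svm or
#'   randomForest::randomForest object).
#' @slot transform Metric normalization transform (see [normalizeMetrics()]),
#'   or NULL when features are supplied pre-normalized.
#' @slot featureNames Feature column order expected by the model.
#' @slot cvReport List: per-fold accuracies, grid, selected hyperparameters.
#' @slot levels Class labels in fixed order novice < skilled < expert.
#' @export
setClass("SkillModelFit", representation(
  kind = "character", model = "ANY", transform = "ANY",
  featureNames = "character", cvReport = "list", levels = "character"
))

#' Tracking evaluation report
#'
#' Scores tracking output against ground truth: tip RMSE (mm), rank-based AUC
#' at 1/2/5 mm tolerances, per-axis Pearson correlation of the trajectories,
#' and the identity-switch count.
#'
#' @slot rmseMm Root mean squared tip error in mm.
#' @slot aucAt Named numeric, AUC at the evaluated tolerances (mm).
#' @slot pearson Named numeric c(x=, y=).
#' @slot identitySwitches Integer count.
#' @slot nCompared Number of compared samples.
#' @export
setClass("EvalReport", representation(
  rmseMm = "numeric", aucAt = "numeric", pearson = "numeric",
  identitySwitches = "integer", nCompared = "integer"
))

setValidity("EvalReport", function(object) {
  msg <- character(0)
  if (any(object@aucAt < -1e-9 | object@aucAt > 1 + 1e-9))
    msg <- c(msg, "AUC values must lie in [0, 1]")
  if (any(object@pearson < -1 - 1e-9 | object@pearson > 1 + 1e-9, na.rm = TRUE))
    msg <- c(msg, "Pearson correlations must lie in [-1, 1]")
  if (length(msg)) msg else TRUE
})
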