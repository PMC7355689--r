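#' @include tracker.R reid.R tips.R metrics.R detection.R evaluation.R
NULL

#' Re-identification configuration
#'
#' @param k Bag-of-visual-words vocabulary size.
#' @param galleryCapacity Exemplars per identity (FIFO).
#' @param tieEps Cosine-distance margin treated as an appearance tie.
#' @param windowFrames Online-learning window (the previous ten frames).
#' @param newIdentityThreshold Minimum gallery distance for a newly
#'   confirmed track to be given a fresh identity rather than an existing
#'   one.
#' @param galleryConfMin Minimum detection confidence for gallery updates.
#' @param seed Seed for the online k-means.
#' @return A `reidConfig` list.
#' @export
reidConfig <- function(k = 32, galleryCapacity = 50, tieEps = 0.02,
                       windowFrames = 10, newIdentityThreshold = 0.35,
                       galleryConfMin = 0.9, seed = 1L) {
  list(k = k, galleryCapacity = galleryCapacity, tieEps = tieEps,
       windowFrames = windowFrames,
       newIdentityThreshold = newIdentityThreshold,
       galleryConfMin = galleryConfMin, seed = as.integer(seed))
}

liveIdentityOwners <- function(ts, excludeId = NA) {
  out <- list()
  for (tr in ts$tracks) {
    if (!is.na(tr$identity) && tr$status %in% c("confirmed", "lost") &&
        (is.na(excludeId) || tr$id != excludeId))
      out[[as.character(tr$identity)]] <- tr$id
  }
  out
}

## pooled BOVW training material from the live tracks' recent patch windows
poolPatchWindows <- function(ts, sinceFrame) {
  descs <- list(); ids <- list()
  for (tr in ts$tracks) {
    if (is.na(tr$identity)) next
    for (entry in tr$patchWindow) {
      if (entry$frame < sinceFrame) next
      if (nrow(entry$desc) == 0) next
      descs[[length(descs) + 1]] <- entry$desc
      ids[[length(ids) + 1]] <- rep(tr$identity, nrow(entry$desc))
    }
  }
  if (!length(descs)) return(NULL)
  list(descriptors = do.call(rbind, descs), identity = unlist(ids))
}

#' Run the full tracking and skill-metric pipeline on a scene
#'
#' Executes the stages in order: detect (ground-truth oracle with optional
#' corruption, or the classical color segmenter) -> non-maximum suppression
#' -> SORT-style tracking -> cascaded re-identification -> indicator
#' recognition -> tip localization -> metric calibration -> trajectory
#' gating -> motion metrics. Deterministic for a fixed scene and
#' configuration.
#'
#' @param scene A [Scene-class].
#' @param detector "oracle", "color", or "file" (JSON-lines detections via
#'   `detectionsPath`).
#' @param noise [noiseConfig()] for the oracle detector.
#' @param segmentParams Parameters for [colorSegment()].
#' @param detectionsPath JSON-lines detections (detector = "file").
#' @param trackerCfg [trackerConfig()].
#' @param reidCfg [reidConfig()].
#' @param templates Indicator templates: NULL for the scene's own, or a
#'   directory containing a template manifest.
#' @param nmsIou NMS IOU threshold.
#' @param outDir Optional output directory (trajectory.csv, states.csv,
#'   metrics.csv, tracks.csv are written there deterministically).
#' @param shaftWidthMm Physical shaft width for calibration.
#' @return List: `trajectory` (gated, calibrated tip trajectory),
#'   `tracks` (per-frame confirmed track table), `states`, `metrics`,
#'   `calibration`, `overlaps`, `armOf`, `gallery`, `fps`.
#' @export
runPipeline <- function(scene, detector = c("oracle", "color", "file"),
                        noise = noiseConfig(), segmentParams = list(),
                        detectionsPath = NULL,
                        trackerCfg = trackerConfig(),
                        reidCfg = reidConfig(), templates = NULL,
                        nmsIou = 0.5, outDir = NULL, shaftWidthMm = 8) {
  detector <- match.arg(detector)
  cfg <- scene@config
  h <- cfg@height; w <- cfg@width; n <- cfg@nFrames
  tpls <- if (is.null(templates)) scene@templates else
    tryCatch(readTemplates(templates),
             error = function(e) stop("indicators stage: cannot load ",
                                      "template manifest from '", templates,
                                      "': ", conditionMessage(e)))
  fileDets <- NULL
  if (detector == "file") {
    if (is.null(detectionsPath) || !file.exists(detectionsPath))
      stop("detection stage: detections file not found")
    allDets <- readDetections(detectionsPath)
    fileDets <- split(allDets, vapply(allDets, `[[`, numeric(1), "frame"))
  }

  ts <- newTracker(trackerCfg)
  gallery <- newGallery(reidCfg$galleryCapacity)
  stateRows <- vector("list", n)
  trackRows <- list()
  overlapRows <- list()
  widths <- numeric(0)

  for (t in seq_len(n)) {
    frame <- renderFrame(scene, t)
    dets <- switch(detector,
      oracle = oracleDetect(scene, t, noise),
      color = {
        dd <- colorSegment(frame, segmentParams)
        for (i in seq_along(dd)) dd[[i]]$frame <- t
        dd
      },
      file = fileDets[[as.character(t)]] %||% list())
    dets <- nmsFilter(dets, nmsIou)
    descs <- lapply(dets, function(d)
      tryCatch(extractDescriptor(frame, d$box, d$maskIdx),
               error = function(e) NULL))
    ts <- trackerStep(ts, dets, descs)

    stateRows[[t]] <- indicatorStateFrame(frame, tpls, t)

    if (length(widths) < 10) {
      for (d in dets) {
        wpx <- tryCatch(measureShaftWidth(d$maskIdx, d$h, d$w),
                        error = function(e) NA_real_)
        if (!is.na(wpx)) widths <- c(widths, wpx)
        if (length(widths) >= 10) break
      }
    }

    asg <- ts$assignments
    asg <- asg[asg$status == "confirmed", , drop = FALSE]
    for (r in seq_len(nrow(asg))) {
      id <- asg$trackId[r]; di <- asg$detIdx[r]
      tr <- getTrack(ts, id)
      desc <- descs[[di]]
      patches <- localPatchDescriptors(frame, dets[[di]]$box,
                                       dets[[di]]$maskIdx)
      pw <- c(tr$patchWindow, list(list(frame = t, desc = patches)))
      pw <- pw[vapply(pw, function(e) e$frame > t - reidCfg$windowFrames,
                      logical(1))]
      ts <- setTrackField(ts, id, "patchWindow", pw)
      tr <- getTrack(ts, id)
      if (is.null(desc)) next

      occluded <- FALSE
      for (j in seq_along(dets)) {
        if (j != di && boxIou(dets[[di]]$box, dets[[j]]$box) > 0) {
          occluded <- TRUE; break
        }
      }

      decided <- tr$identity
      if (id %in% ts$newlyConfirmed || is.na(tr$identity)) {
        if (length(gallery$identities) == 0) {
          decided <- 1L
        } else {
          ranked <- galleryRank(desc, gallery)
          used <- as.integer(names(gallery$identities))
          if (ranked$distance[1] > reidCfg$newIdentityThreshold &&
              length(used) < 3) {
            decided <- setdiff(1:3, used)[1]
          } else {
            decided <- ranked$identity[1]
          }
        }
      } else if (length(gallery$identities)) {
        ranked <- galleryRank(desc, gallery)
        if (nrow(ranked) && ranked$identity[1] != tr$identity) {
          pool <- poolPatchWindows(ts, t - reidCfg$windowFrames)
          dec <- cascadeReid(tr$identity, desc, gallery,
                             windowDescriptors = pool$descriptors,
                             windowIdentity = pool$identity,
                             queryPatches = patches, k = reidCfg$k,
                             tieEps = reidCfg$tieEps, seed = reidCfg$seed)
          decided <- dec$identity
        }
      }

      # identity uniqueness: at most one live confirmed track per identity.
      # A lost owner is a stale hypothesis of the same instrument (it left
      # the view and re-entered as this track): it yields the identity.
      owners <- liveIdentityOwners(ts, excludeId = id)
      if (!is.na(decided) && !is.null(owners[[as.character(decided)]])) {
        other <- getTrack(ts, owners[[as.character(decided)]])
        freeIds <- setdiff(1:3, as.integer(names(owners)))
        if (other$status == "lost") {
          ts <- setTrackField(ts, other$id, "identity", NA_integer_)
        } else {
          myD <- if (length(gallery$identities)) {
            rk <- galleryRank(desc, gallery)
            rk$distance[match(decided, rk$identity)]
          } else NA_real_
          otherD <- if (length(other$appBuffer) &&
                        length(gallery$identities)) {
            rk2 <- galleryRank(other$appBuffer[[length(other$appBuffer)]],
                               gallery)
            rk2$distance[match(decided, rk2$identity)]
          } else NA_real_
          winnerIsMe <- is.na(otherD) || (!is.na(myD) && myD <= otherD)
          if (winnerIsMe) {
            ts <- setTrackField(ts, other$id, "identity",
                                if (length(freeIds)) freeIds[1] else
                                  NA_integer_)
          } else {
            decided <- if (length(freeIds)) freeIds[1] else tr$identity
          }
        }
      }
      if (!is.na(decided)) ts <- setTrackField(ts, id, "identity", decided)
      tr <- getTrack(ts, id)

      if (!is.na(tr$identity) && !occluded &&
          dets[[di]]$confidence >= reidCfg$galleryConfMin)
        gallery <- galleryAdd(gallery, tr$identity, desc)
    }

    # per-frame confirmed track output with tip localization
    asg2 <- ts$assignments
    asg2 <- asg2[asg2$status == "confirmed", , drop = FALSE]
    for (r in seq_len(nrow(asg2))) {
      tr <- getTrack(ts, asg2$trackId[r])
      d <- dets[[asg2$detIdx[r]]]
      tip <- detectTip(d$maskIdx, d$h, d$w)
      trackRows[[length(trackRows) + 1]] <- data.frame(
        frame = t, trackId = tr$id, identity = tr$identity,
        x = d$box[1], y = d$box[2], w = d$box[3], h = d$box[4],
        x_px = tip[["x"]], y_px = tip[["y"]],
        confidence = d$confidence, status = tr$status)
    }
    if (nrow(asg2) >= 2) {
      for (a in seq_len(nrow(asg2) - 1)) for (b in (a + 1):nrow(asg2)) {
        ia <- getTrack(ts, asg2$trackId[a])$identity
        ib <- getTrack(ts, asg2$trackId[b])$identity
        if (is.na(ia) || is.na(ib) || ia == ib) next
        if (length(intersect(dets[[asg2$detIdx[a]]]$maskIdx,
                             dets[[asg2$detIdx[b]]]$maskIdx)) > 0)
          overlapRows[[length(overlapRows) + 1]] <-
            data.frame(frame = t, a = ia, b = ib)
      }
    }
  }

  if (length(widths) == 0)
    stop("calibration stage: no sufficiently elongated mask found")
  calibration <- makeCalibration(round(stats::median(widths)), shaftWidthMm)

  tracks <- if (length(trackRows)) do.call(rbind, trackRows) else
    stop("tracking stage: no confirmed tracks produced")
  states <- do.call(rbind, stateRows)
  overlaps <- if (length(overlapRows)) unique(do.call(rbind, overlapRows))
  else data.frame(frame = integer(0), a = integer(0), b = integer(0))

  traj <- tracks[!is.na(tracks$identity),
                 c("frame", "identity", "x_px", "y_px", "confidence")]
  # one sample per identity per frame (highest confidence wins)
  traj <- traj[order(traj$frame, traj$identity, -traj$confidence), ]
  traj <- traj[!duplicated(traj[, c("frame", "identity")]), ]
  traj$visible <- TRUE
  traj <- calibrateTrajectory(traj, calibration)
  armOf <- inferArmAssignment(traj, center = w / 2)
  traj <- gateTrajectory(traj, states, armOf = armOf)

  metrics <- computeMetrics(traj, states, cfg@fps, overlaps = overlaps,
                            armOf = armOf)

  result <- list(trajectory = traj, tracks = tracks, states = states,
                 metrics = metrics, calibration = calibration,
                 overlaps = overlaps, armOf = armOf, gallery = gallery,
                 fps = cfg@fps, width = w, height = h)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(traj, file.path(outDir, "trajectory.csv"),
                     row.names = FALSE)
    utils::write.csv(states, file.path(outDir, "states.csv"),
                     row.names = FALSE)
    utils::write.csv(metrics, file.path(outDir, "metrics.csv"),
                     row.names = FALSE)
    utils::write.csv(tracks, file.path(outDir, "tracks.csv"),
                     row.names = FALSE)
  }
  result
}
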