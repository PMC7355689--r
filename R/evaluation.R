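#' @include AllClasses.R tracker.R
NULL

subsampleFrames <- function(frames, fps, sampleRate) {
  if (is.null(fps) || is.null(sampleRate)) return(rep(TRUE, length(frames)))
  every <- max(1L, round(fps / sampleRate))
  (frames - 1L) %% every == 0L
}

mergeTrajectories <- function(pred, gt) {
  merge(pred, gt, by = c("frame", "identity"), suffixes = c("_p", "_g"))
}

#' Tip RMSE between predicted and ground-truth trajectories
#'
#' Root mean squared Euclidean tip error over identity-matched samples,
#' compared at a subsampled cadence (default 2 samples per second,
#' mirroring how ground truth is labeled; set `fullRate = TRUE` to compare
#' every frame).
#'
#' @param pred,gt data.frames with columns frame, identity, x_mm, y_mm.
#' @param fps Frames per second (required unless `fullRate`).
#' @param sampleRate Comparison cadence in samples/second.
#' @param fullRate Compare at every frame.
#' @return RMSE in mm.
#' @export
tipRmse <- function(pred, gt, fps = NULL, sampleRate = 2, fullRate = FALSE) {
  m <- mergeTrajectories(pred, gt)
  if (!fullRate) m <- m[subsampleFrames(m$frame, fps, sampleRate), ,
                        drop = FALSE]
  if (nrow(m) == 0) stop("no overlapping samples to compare")
  sqrt(mean((m$x_mm_p - m$x_mm_g)^2 + (m$y_mm_p - m$y_mm_g)^2))
}

#' Rank-based AUC of tip localization within a tolerance
#'
#' Each compared prediction is a true positive when its tip lies within the
#' tolerance of the same-identity ground-truth tip, a false positive
#' otherwise. The ROC is traced by sweeping the detection-confidence
#' threshold; the area equals the Mann-Whitney statistic (probability a
#' random within-tolerance prediction outranks a random out-of-tolerance
#' one; ties weighted 1/2). With no out-of-tolerance predictions the AUC is
#' 1; with none within tolerance it is 0.
#'
#' @param distances Tip errors in mm, one per compared prediction.
#' @param confidences Detection confidences, parallel to `distances`.
#' @param toleranceMm Tolerance (> 0).
#' @return AUC in \[0, 1\].
#' @export
toleranceAuc <- function(distances, confidences, toleranceMm) {
  stopifnot(toleranceMm > 0, length(distances) == length(confidences))
  if (length(distances) == 0) stop("no samples")
  pos <- distances <= toleranceMm
  np <- sum(pos); nn <- sum(!pos)
  if (nn == 0) return(1)
  if (np == 0) return(0)
  r <- rank(confidences)
  (sum(r[pos]) - np * (np + 1) / 2) / (np * nn)
}

#' Per-axis Pearson correlation of trajectories
#'
#' Product-moment correlation between predicted and ground-truth tip
#' coordinates on the compared samples, per axis.
#'
#' @inheritParams tipRmse
#' @return Named numeric c(x, y).
#' @export
trajectoryPearson <- function(pred, gt, fps = NULL, sampleRate = 2,
                              fullRate = FALSE) {
  m <- mergeTrajectories(pred, gt)
  if (!fullRate) m <- m[subsampleFrames(m$frame, fps, sampleRate), ,
                        drop = FALSE]
  if (nrow(m) < 3) stop("need at least 3 overlapping samples")
  if (stats::sd(m$x_mm_p) == 0 || stats::sd(m$x_mm_g) == 0 ||
      stats::sd(m$y_mm_p) == 0 || stats::sd(m$y_mm_g) == 0)
    stop("zero variance on an axis")
  c(x = stats::cor(m$x_mm_p, m$x_mm_g), y = stats::cor(m$y_mm_p, m$y_mm_g))
}

## per-frame GT-to-track matching by IOU (Hungarian); returns
## data.frame(frame, instrument, label)
matchTracksToTruth <- function(tracks, scene, iouThreshold = 0.3,
                               labelCol = "identity") {
  st <- scene@truth
  out <- list()
  for (f in sort(unique(tracks$frame))) {
    gtIds <- which(st$visible[f, ])
    if (!length(gtIds)) next
    d <- tracks[tracks$frame == f, , drop = FALSE]
    if (!nrow(d)) next
    cost <- matrix(0, length(gtIds), nrow(d))
    adm <- matrix(FALSE, length(gtIds), nrow(d))
    for (a in seq_along(gtIds)) {
      gb <- st$boxes[[gtIds[a]]][f, ]
      for (b in seq_len(nrow(d))) {
        iou <- boxIou(gb, c(d$x[b], d$y[b], d$w[b], d$h[b]))
        cost[a, b] <- 1 - iou
        adm[a, b] <- iou >= iouThreshold
      }
    }
    res <- associate(cost, adm)
    for (k in seq_len(nrow(res$matches)))
      out[[length(out) + 1]] <- data.frame(
        frame = f, instrument = gtIds[res$matches[k, 1]],
        label = d[[labelCol]][res$matches[k, 2]])
  }
  if (!length(out)) return(data.frame(frame = integer(0),
                                      instrument = integer(0),
                                      label = integer(0)))
  do.call(rbind, out)
}

#' Count identity switches against ground truth
#'
#' Standard multi-object-tracking identity-switch count on the post-ReID
#' identity labels: ground-truth instruments are matched to track boxes per
#' frame (Hungarian, IOU-gated) and a switch is counted whenever a
#' ground-truth instrument's matched label differs from its previously
#' matched label. A track lost and re-linked to the same identity does not
#' count.
#'
#' @param tracks data.frame(frame, identity, x, y, w, h) of confirmed track
#'   output.
#' @param scene The [Scene-class] providing ground truth.
#' @param iouThreshold Match gate.
#' @return Integer switch count.
#' @export
countIdentitySwitches <- function(tracks, scene, iouThreshold = 0.3) {
  m <- matchTracksToTruth(tracks, scene, iouThreshold)
  total <- 0L
  for (g in unique(m$instrument)) {
    lab <- m$label[m$instrument == g][order(m$frame[m$instrument == g])]
    lab <- lab[!is.na(lab)]
    if (length(lab) > 1) total <- total + sum(diff(as.integer(lab)) != 0)
  }
  total
}

#' Ground-truth tables of a scene
#'
#' Ground truth in the same tabular layout the pipeline produces, so the
#' metric functions can be applied to perfect information: calibrated tip
#' trajectory (with validity gating from the true camera/active schedules),
#' indicator states, instrument mask-overlap table and the arm map.
#'
#' @param scene A [Scene-class].
#' @return List: `trajectory`, `states`, `overlaps`, `armOf`, `fps`.
#' @export
groundTruthTables <- function(scene) {
  st <- scene@truth
  n <- nFrames(scene)
  nInstr <- length(scene@config@instruments)
  rows <- list()
  for (i in seq_len(nInstr)) {
    vis <- which(st$visible[, i])
    if (!length(vis)) next
    rows[[i]] <- data.frame(frame = vis, identity = i,
                            x_px = st$tip[[i]][vis, 1],
                            y_px = st$tip[[i]][vis, 2],
                            confidence = 1, visible = TRUE)
  }
  traj <- do.call(rbind, rows)
  traj <- calibrateTrajectory(traj, makeCalibration(
    scene@config@shaftWidthPx, SHAFT_WIDTH_MM))
  armSide <- st$armSide
  states <- data.frame(
    frame = seq_len(n), cameraMoving = st$cameraMoving,
    leftActive = apply(st$active & rep(armSide == "left", each = n), 1, any),
    rightActive = apply(st$active & rep(armSide == "right", each = n), 1, any))
  armOf <- st$armSide
  names(armOf) <- as.character(seq_len(nInstr))
  overlaps <- list()
  for (f in seq_len(n)) {
    vis <- which(st$visible[f, ])
    if (length(vis) < 2) next
    for (a in seq_along(vis)) for (b in seq_along(vis)) {
      if (a < b && length(intersect(st$maskIdx[[vis[a]]][[f]],
                                    st$maskIdx[[vis[b]]][[f]])) > 0)
        overlaps[[length(overlaps) + 1]] <-
          data.frame(frame = f, a = vis[a], b = vis[b])
    }
  }
  overlaps <- if (length(overlaps)) do.call(rbind, overlaps) else
    data.frame(frame = integer(0), a = integer(0), b = integer(0))
  traj <- gateTrajectory(traj, states, armOf = armOf)
  list(trajectory = traj, states = states, overlaps = overlaps,
       armOf = armOf, fps = scene@config@fps)
}

#' Evaluate a pipeline run against scene ground truth
#'
#' Maps tracked identities to ground-truth instruments by majority box
#' overlap, then computes tip RMSE (mm), AUC at the requested tolerances,
#' per-axis Pearson correlation and the identity-switch count. Predictions
#' are matched to ground truth by identity label (the identified
#' instrument's tip is what is being scored), at the ground-truth labeling
#' cadence of 2 samples per second unless `fullRate`.
#'
#' @param result A [runPipeline()] result.
#' @param scene The scene it was run on.
#' @param tolerances AUC tolerances in mm.
#' @param sampleRate,fullRate Comparison cadence.
#' @return An [EvalReport-class].
#' @export
evaluateTracking <- function(result, scene, tolerances = c(1, 2, 5),
                             sampleRate = 2, fullRate = FALSE) {
  m <- matchTracksToTruth(result$tracks, scene)
  # majority mapping ground-truth instrument -> identity label
  tab <- table(m$instrument, m$label)
  if (nrow(tab) == 0) stop("no ground-truth/track overlap to evaluate")
  cost <- -as.matrix(tab)
  sol <- solveAssignment(cost)
  map <- integer(0)
  for (k in seq_len(nrow(sol))) {
    gi <- as.integer(rownames(tab)[sol[k, "row"]])
    map[[as.character(gi)]] <- as.integer(colnames(tab)[sol[k, "col"]])
  }
  st <- scene@truth
  gtRows <- list()
  for (gi in names(map)) {
    i <- as.integer(gi)
    vis <- which(st$visible[, i])
    gtRows[[gi]] <- data.frame(frame = vis, identity = map[[gi]],
                               x_mm = st$tip[[i]][vis, 1] * st$mmPerPx,
                               y_mm = st$tip[[i]][vis, 2] * st$mmPerPx)
  }
  gt <- do.call(rbind, gtRows)
  pred <- result$trajectory[, c("frame", "identity", "x_mm", "y_mm",
                                "confidence")]
  fps <- scene@config@fps
  mm <- mergeTrajectories(pred, gt)
  keep <- if (fullRate) rep(TRUE, nrow(mm)) else
    subsampleFrames(mm$frame, fps, sampleRate)
  mm <- mm[keep, , drop = FALSE]
  if (nrow(mm) == 0) stop("no compared samples")
  dist <- sqrt((mm$x_mm_p - mm$x_mm_g)^2 + (mm$y_mm_p - mm$y_mm_g)^2)
  aucs <- vapply(tolerances, function(tol)
    toleranceAuc(dist, mm$confidence, tol), numeric(1))
  names(aucs) <- as.character(tolerances)
  pears <- c(x = stats::cor(mm$x_mm_p, mm$x_mm_g),
             y = stats::cor(mm$y_mm_p, mm$y_mm_g))
  new("EvalReport", rmseMm = sqrt(mean(dist^2)), aucAt = aucs,
      pearson = pears,
      identitySwitches = countIdentitySwitches(result$tracks, scene),
      nCompared = nrow(mm))
}

#' Write an evaluation report to JSON
#' @param report An [EvalReport-class].
#' @param path File path.
#' @return Invisibly, `path`.
#' @export
writeEvalReport <- function(report, path) {
  jsonlite::write_json(list(
    rmse_mm = report@rmseMm,
    auc = as.list(report@aucAt),
    pearson = as.list(report@pearson),
    identity_switches = report@identitySwitches,
    n_compared = report@nCompared
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
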