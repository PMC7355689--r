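#' @include indicators.R
NULL

# Nine motion metrics computed from gated, calibrated tip trajectories:
# time to completion, instruments out of view, instrument collisions,
# economy of motion, average speed, number of movements, economic factor,
# instrument changes, laparoscopy usage (count + duration).

validFlag <- function(traj) {
  v <- rep(TRUE, nrow(traj))
  if ("valid_motion" %in% names(traj)) v <- v & traj$valid_motion
  if ("active" %in% names(traj)) v <- v & traj$active
  if ("visible" %in% names(traj)) v <- v & traj$visible
  v
}

## per-identity step table: frame (pair start), step length (mm), positions
stepTable <- function(traj) {
  v <- validFlag(traj)
  ids <- if ("identity" %in% names(traj)) traj$identity else rep(1L, nrow(traj))
  out <- list()
  for (g in unique(ids)) {
    d <- traj[ids == g, , drop = FALSE]
    vg <- v[ids == g]
    o <- order(d$frame)
    d <- d[o, , drop = FALSE]; vg <- vg[o]
    if (nrow(d) < 2) next
    consec <- diff(d$frame) == 1 & vg[-length(vg)] & vg[-1]
    if (!any(consec)) next
    i <- which(consec)
    out[[as.character(g)]] <- data.frame(
      identity = g, frame = d$frame[i],
      step = sqrt((d$x_mm[i + 1] - d$x_mm[i])^2 +
                    (d$y_mm[i + 1] - d$y_mm[i])^2),
      x0 = d$x_mm[i], y0 = d$y_mm[i], x1 = d$x_mm[i + 1], y1 = d$y_mm[i + 1])
  }
  if (length(out) == 0)
    return(data.frame(identity = integer(0), frame = integer(0),
                      step = numeric(0), x0 = numeric(0), y0 = numeric(0),
                      x1 = numeric(0), y1 = numeric(0)))
  do.call(rbind, out)
}

#' Economy of motion
#'
#' Total tip path length in millimetres, summed over instruments across
#' consecutive valid-motion samples. Displacement during camera motion or
#' while an instrument's arm is inactive is excluded by the validity flags
#' (see [gateTrajectory()]).
#'
#' @param trajectory Calibrated trajectory data.frame (`frame`, `x_mm`,
#'   `y_mm`, optional `identity` and validity flags).
#' @return Path length in mm (0 for an empty trajectory).
#' @export
economyOfMotion <- function(trajectory) {
  if (nrow(trajectory) == 0) return(0)
  sum(stepTable(trajectory)$step)
}

#' Average tip speed
#'
#' Economy of motion divided by the total valid-motion duration (the time
#' spanned by consecutive valid sample pairs, summed over instruments).
#'
#' @inheritParams economyOfMotion
#' @param fps Frames per second (> 0).
#' @return Speed in mm/s.
#' @export
averageSpeed <- function(trajectory, fps) {
  stopifnot(fps > 0)
  st <- stepTable(trajectory)
  if (nrow(st) == 0) stop("no valid motion samples: zero duration")
  sum(st$step) / (nrow(st) / fps)
}

#' Count out-of-view episodes
#'
#' Number of maximal intervals during which an arm marked active by the
#' indicators has no confirmed in-view instrument on its side of the view.
#'
#' @param presence data.frame(frame, identity) of in-view confirmed samples.
#' @param states Indicator states ([indicatorStates()]).
#' @param armOf Named vector identity -> "left"/"right".
#' @return Integer event count.
#' @export
countOutOfView <- function(presence, states, armOf) {
  total <- 0L
  for (side in c("left", "right")) {
    activeCol <- if (side == "left") states$leftActive else states$rightActive
    sideIds <- names(armOf)[armOf == side]
    covered <- states$frame %in%
      presence$frame[as.character(presence$identity) %in% sideIds]
    deficit <- activeCol & !covered
    total <- total + nrow(trueRuns(deficit))
  }
  total
}

#' Count instrument collisions
#'
#' A collision is an onset event: a pair of distinct confirmed instruments
#' whose masks overlap after at least one frame without overlap for that
#' pair.
#'
#' @param overlaps data.frame(frame, a, b) listing frames on which the mask
#'   (or box) footprints of identities `a` and `b` overlap.
#' @return Integer event count.
#' @export
countCollisions <- function(overlaps) {
  if (is.null(overlaps) || nrow(overlaps) == 0) return(0L)
  key <- paste(pmin(overlaps$a, overlaps$b), pmax(overlaps$a, overlaps$b))
  total <- 0L
  for (k in unique(key)) {
    fr <- sort(unique(overlaps$frame[key == k]))
    total <- total + 1L + sum(diff(fr) > 1)
  }
  total
}

## smoothed speed series per identity; NA outside valid pairs
smoothedSpeeds <- function(trajectory, fps, window = 5) {
  st <- stepTable(trajectory)
  out <- list()
  for (g in unique(st$identity)) {
    d <- st[st$identity == g, , drop = FALSE]
    frames <- seq(min(d$frame), max(d$frame))
    sp <- rep(NA_real_, length(frames))
    sp[match(d$frame, frames)] <- d$step * fps
    # moving average within contiguous non-NA segments (partial at edges)
    sm <- sp
    ok <- !is.na(sp)
    half <- window %/% 2
    idx <- which(ok)
    for (i in idx) {
      lo <- i; hi <- i
      while (lo > i - half && lo > 1 && ok[lo - 1]) lo <- lo - 1
      while (hi < i + half && hi < length(sp) && ok[hi + 1]) hi <- hi + 1
      sm[i] <- mean(sp[lo:hi])
    }
    out[[as.character(g)]] <- data.frame(identity = g, frame = frames,
                                         speed = sm)
  }
  if (length(out) == 0)
    return(data.frame(identity = integer(0), frame = integer(0),
                      speed = numeric(0)))
  do.call(rbind, out)
}

#' Movement episodes
#'
#' The tip speed series is smoothed (moving average, window 5 samples) and
#' maximal runs above the speed threshold lasting at least `minDurationS`
#' are movement episodes.
#'
#' @inheritParams averageSpeed
#' @param speedThreshold Speed threshold in mm/s.
#' @param minDurationS Minimum episode duration in seconds.
#' @param window Smoothing window in samples.
#' @return data.frame(identity, from, to): pair-start frame ranges.
#' @export
movementEpisodes <- function(trajectory, fps, speedThreshold = 2,
                             minDurationS = 0.2, window = 5) {
  sp <- smoothedSpeeds(trajectory, fps, window)
  minLen <- max(1, round(minDurationS * fps))
  out <- list()
  for (g in unique(sp$identity)) {
    d <- sp[sp$identity == g, , drop = FALSE]
    runs <- trueRuns(!is.na(d$speed) & d$speed > speedThreshold)
    runs <- runs[runs$to - runs$from + 1 >= minLen, , drop = FALSE]
    if (nrow(runs))
      out[[as.character(g)]] <- data.frame(identity = g,
                                           from = d$frame[runs$from],
                                           to = d$frame[runs$to])
  }
  if (length(out) == 0)
    return(data.frame(identity = integer(0), from = integer(0),
                      to = integer(0)))
  do.call(rbind, out)
}

#' Number of movements
#' @inheritParams movementEpisodes
#' @return Integer episode count.
#' @export
countMovements <- function(trajectory, fps, speedThreshold = 2,
                           minDurationS = 0.2, window = 5) {
  nrow(movementEpisodes(trajectory, fps, speedThreshold, minDurationS,
                        window))
}

#' Economic factor (movement straightness)
#'
#' Mean over movement episodes of net displacement divided by episode path
#' length, in (0, 1\]; straight-line movements score 1, round-about or
#' zero-net movements score toward 0.
#'
#' @inheritParams movementEpisodes
#' @param episodes Optional precomputed [movementEpisodes()] table.
#' @return Numeric scalar, or NA (with a message) when there are no
#'   episodes.
#' @export
economicFactor <- function(trajectory, fps, episodes = NULL,
                           speedThreshold = 2, minDurationS = 0.2,
                           window = 5) {
  if (is.null(episodes))
    episodes <- movementEpisodes(trajectory, fps, speedThreshold,
                                 minDurationS, window)
  if (nrow(episodes) == 0) {
    message("no movement episodes; economic factor undefined")
    return(NA_real_)
  }
  st <- stepTable(trajectory)
  ratios <- numeric(nrow(episodes))
  for (k in seq_len(nrow(episodes))) {
    ep <- episodes[k, ]
    d <- st[st$identity == ep$identity & st$frame >= ep$from &
              st$frame <= ep$to, , drop = FALSE]
    path <- sum(d$step)
    net <- sqrt((d$x1[nrow(d)] - d$x0[1])^2 + (d$y1[nrow(d)] - d$y0[1])^2)
    ratios[k] <- if (path > 0) net / path else 0
  }
  mean(ratios)
}

#' Count instrument changes
#'
#' An instrument change swaps one instrument for another on the same arm:
#' one identity leaves the view for good (or for a long absence) and a
#' different identity appears shortly after. Counted as paired
#' departure/arrival events of different identities within `pairWindow`
#' frames; an identity re-entering after its own absence is not a change.
#'
#' @param presence data.frame(frame, identity) of in-view samples.
#' @param nFrames Total video length in frames.
#' @param gapFrames Minimum absence (frames) for a departure/arrival to
#'   count as such.
#' @param pairWindow Maximum frames between a departure and the arrival
#'   pairing with it.
#' @return Integer event count.
#' @export
countInstrumentChanges <- function(presence, nFrames,
                                   gapFrames = 30, pairWindow = 60) {
  if (nrow(presence) == 0) return(0L)
  arrivals <- list(); departures <- list()
  for (g in unique(presence$identity)) {
    fr <- sort(unique(presence$frame[presence$identity == g]))
    # merge visibility runs separated by short gaps
    brk <- which(diff(fr) > gapFrames)
    starts <- fr[c(1, brk + 1)]
    ends <- fr[c(brk, length(fr))]
    for (r in seq_along(starts)) {
      arrivals[[length(arrivals) + 1]] <- c(t = starts[r], id = g)
      if (nFrames - ends[r] >= gapFrames || r < length(starts))
        departures[[length(departures) + 1]] <- c(t = ends[r], id = g)
    }
  }
  if (!length(arrivals) || !length(departures)) return(0L)
  arr <- do.call(rbind, arrivals); dep <- do.call(rbind, departures)
  arr <- arr[order(arr[, "t"]), , drop = FALSE]
  dep <- dep[order(dep[, "t"]), , drop = FALSE]
  usedDep <- rep(FALSE, nrow(dep))
  count <- 0L
  for (i in seq_len(nrow(arr))) {
    # the replacement instrument arrives after (or just as) the old leaves
    cand <- which(!usedDep & dep[, "id"] != arr[i, "id"] &
                    arr[i, "t"] - dep[, "t"] >= -2 &
                    arr[i, "t"] - dep[, "t"] <= pairWindow)
    if (length(cand)) {
      usedDep[cand[1]] <- TRUE
      count <- count + 1L
    }
  }
  count
}

#' Laparoscopy usage
#'
#' Number and total duration of maximal camera-motion intervals (the camera
#' arm indicator marks laparoscope movement).
#'
#' @param states Indicator states.
#' @param fps Frames per second.
#' @return Numeric c(count, durationS).
#' @export
laparoscopyUsage <- function(states, fps) {
  runs <- trueRuns(states$cameraMoving)
  c(count = nrow(runs), durationS = sum(runs$to - runs$from + 1) / fps)
}

#' Compute the nine motion metrics of one operation
#'
#' @param trajectory Gated, calibrated trajectory ([gateTrajectory()],
#'   [calibrateTrajectory()]).
#' @param states Indicator states covering the video.
#' @param fps Frames per second.
#' @param overlaps Optional data.frame(frame, a, b) of instrument footprint
#'   overlaps for collision counting.
#' @param armOf Named identity -> side map for out-of-view counting
#'   (inferred from `center` when NULL).
#' @param center View center x for [inferArmAssignment()].
#' @param speedThreshold,minDurationS Movement-episode parameters.
#' @return One-row data.frame of the metric vector.
#' @export
computeMetrics <- function(trajectory, states, fps, overlaps = NULL,
                           armOf = NULL, center = NULL,
                           speedThreshold = 2, minDurationS = 0.2) {
  if (is.null(armOf)) {
    if (is.null(center)) stop("supply armOf or center")
    armOf <- inferArmAssignment(trajectory, center)
  }
  vis <- if ("visible" %in% names(trajectory)) trajectory$visible else TRUE
  presence <- trajectory[vis, c("frame", "identity")]
  episodes <- movementEpisodes(trajectory, fps, speedThreshold, minDurationS)
  lap <- laparoscopyUsage(states, fps)
  data.frame(
    timeToCompletionS = nrow(states) / fps,
    outOfViewCount = countOutOfView(presence, states, armOf),
    collisionCount = countCollisions(overlaps),
    economyOfMotionMm = economyOfMotion(trajectory),
    averageSpeedMmS = tryCatch(averageSpeed(trajectory, fps),
                               error = function(e) NA_real_),
    movementCount = nrow(episodes),
    economicFactor = suppressMessages(
      economicFactor(trajectory, fps, episodes)),
    instrumentChangeCount = countInstrumentChanges(presence, nrow(states)),
    laparoscopyCount = unname(lap["count"]),
    laparoscopyDurationS = unname(lap["durationS"])
  )
}

RATE_COLS <- c("outOfViewCount", "collisionCount", "movementCount",
               "instrumentChangeCount", "laparoscopyCount")

stage1Normalize <- function(tbl) {
  t_s <- tbl$timeToCompletionS
  out <- tbl
  for (cn in RATE_COLS) out[[cn]] <- tbl[[cn]] / t_s * 60  # events/min
  out$economyOfMotionMm <- tbl$economyOfMotionMm / t_s     # mm/s
  out$laparoscopyDurationS <- tbl$laparoscopyDurationS / t_s
  out
}

#' Normalize a cohort of metric vectors
#'
#' Two-stage normalization for modelling: each duration-dependent metric is
#' first divided by its video's operation time (counts become per-minute
#' rates, economy of motion becomes mm/s, laparoscopy duration becomes a
#' fraction; time to completion itself is retained raw), then every column
#' is standardized to zero mean and unit variance across the cohort. The
#' returned transform reapplies both stages to new subjects.
#'
#' @param tbl data.frame of metric vectors (rows = videos) as produced by
#'   [computeMetrics()].
#' @return List: `normalized` (data.frame), `transform`.
#' @export
normalizeMetrics <- function(tbl) {
  stopifnot(nrow(tbl) >= 2)
  s1 <- stage1Normalize(tbl)
  center <- vapply(s1, mean, numeric(1), na.rm = TRUE)
  scale <- vapply(s1, stats::sd, numeric(1), na.rm = TRUE)
  if (any(scale == 0, na.rm = TRUE))
    warning("zero-variance metric column(s) standardized to zeros: ",
            paste(names(s1)[which(scale == 0)], collapse = ", "))
  tf <- list(center = center, scale = scale, names = names(s1))
  list(normalized = applyMetricTransform(tf, tbl), transform = tf)
}

#' @rdname normalizeMetrics
#' @param transform A transform from `normalizeMetrics`.
#' @export
applyMetricTransform <- function(transform, tbl) {
  s1 <- stage1Normalize(tbl[, transform$names, drop = FALSE])
  out <- s1
  for (cn in transform$names) {
    sc <- transform$scale[[cn]]
    out[[cn]] <- if (is.na(sc) || sc == 0) rep(0, nrow(s1))
    else (s1[[cn]] - transform$center[[cn]]) / sc
  }
  out
}
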