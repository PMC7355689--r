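#' @include AllClasses.R metrics.R
NULL

#' Default class-conditional motion parameters
#'
#' The three surgeon groups differ in the motion statistics their
#' trajectories realize: experts move faster, straighter and with fewer
#' pauses, out-of-view episodes, collisions and instrument changes than
#' skilled surgeons, who in turn beat novices. Class means are ordered
#' (expert <= skilled <= novice in path inefficiency, out-of-view rate and
#' collision rate); effect sizes keep the classes separable but
#' overlapping.
#'
#' Units: `speed` mm/s while moving; `inefficiency` path length / net
#' displacement per movement (>= 1); `pauseFrac` fraction of operating time
#' spent pausing; `oovRate`, `collisionRate`, `changeRate`, `cameraRate`
#' events per minute.
#'
#' @return Named list of per-class parameter lists.
#' @export
defaultSkillParams <- function() {
  list(
    novice = list(speed = 3.0, inefficiency = 1.90, pauseFrac = 0.45,
                  oovRate = 1.2, collisionRate = 0.8, changeRate = 0.55,
                  cameraRate = 1.5),
    skilled = list(speed = 4.5, inefficiency = 1.45, pauseFrac = 0.32,
                   oovRate = 0.6, collisionRate = 0.4, changeRate = 0.35,
                   cameraRate = 1.0),
    expert = list(speed = 6.0, inefficiency = 1.12, pauseFrac = 0.20,
                  oovRate = 0.2, collisionRate = 0.15, changeRate = 0.20,
                  cameraRate = 0.7)
  )
}

## one curved movement episode from `from` toward `to`, resampled to
## constant speed; returns matrix of positions (excluding the start point)
episodeCurve <- function(from, to, inefficiency, stepMm) {
  d <- sqrt(sum((to - from)^2))
  if (d < 1e-9) return(matrix(numeric(0), 0, 2))
  dirv <- (to - from) / d
  perp <- c(-dirv[2], dirv[1])
  amp <- d * sqrt(max(0, inefficiency^2 - 1)) / pi
  tt <- seq(0, 1, length.out = 200)
  curve <- cbind(from[1] + tt * d * dirv[1] + amp * sin(pi * tt) * perp[1],
                 from[2] + tt * d * dirv[2] + amp * sin(pi * tt) * perp[2])
  seg <- sqrt(rowSums(diff(curve)^2))
  arc <- c(0, cumsum(seg))
  total <- arc[length(arc)]
  nS <- max(2, ceiling(total / stepMm))
  at <- seq_len(nS) * total / nS
  cbind(stats::approx(arc, curve[, 1], xout = at, rule = 2)$y,
        stats::approx(arc, curve[, 2], xout = at, rule = 2)$y)
}

## simulate one instrument's tip series until `taskMm` net progress
simInstrumentSeries <- function(start, bounds, speed, inefficiency,
                                pauseFrac, taskMm, fps) {
  pos <- start
  xs <- start[1]; ys <- start[2]
  moving <- FALSE
  net <- 0
  stepMm <- speed / fps
  while (net < taskMm) {
    d <- stats::runif(1, 8, 30)
    repeat {
      ang <- stats::runif(1, 0, 2 * pi)
      target <- pos + d * c(cos(ang), sin(ang))
      if (target[1] > bounds[1] && target[1] < bounds[2] &&
          target[2] > bounds[3] && target[2] < bounds[4]) break
    }
    curve <- episodeCurve(pos, target, inefficiency, stepMm)
    if (nrow(curve) == 0) next
    xs <- c(xs, curve[, 1]); ys <- c(ys, curve[, 2])
    moving <- c(moving, rep(TRUE, nrow(curve)))
    pos <- target
    net <- net + d
    moveT <- nrow(curve) / fps
    pauseT <- stats::rexp(1, rate = 1 / max(0.2, moveT * pauseFrac /
                                              max(0.05, 1 - pauseFrac)))
    nP <- round(pauseT * fps)
    if (nP > 0) nP <- max(nP, 5)  # a pause shorter than ~1 s is not a pause
    if (nP > 0) {
      xs <- c(xs, rep(pos[1], nP)); ys <- c(ys, rep(pos[2], nP))
      moving <- c(moving, rep(FALSE, nP))
    }
  }
  list(x = xs, y = ys, moving = moving)
}

pickIntervals <- function(nEvents, nT, durFun, minGap) {
  iv <- data.frame(from = integer(0), to = integer(0))
  tries <- 0
  while (nrow(iv) < nEvents && tries < 200) {
    tries <- tries + 1
    dur <- max(2L, as.integer(durFun()))
    f <- sample.int(max(1, nT - dur - 1), 1)
    t2 <- min(nT, f + dur)
    if (!nrow(iv) || all(f > iv$to + minGap | t2 < iv$from - minGap))
      iv <- rbind(iv, data.frame(from = f, to = t2))
  }
  iv[order(iv$from), , drop = FALSE]
}

#' Generate a synthetic skill cohort
#'
#' Simulates one operation per subject at the class-conditional motion
#' statistics: two working instruments (left and right arm) performing
#' movement episodes with class-dependent speed, path inefficiency and
#' pause structure until a fixed productive task length is reached, plus
#' Poisson-scheduled out-of-view episodes, instrument collisions (the right
#' tip briefly excursions to the left tip), instrument changes (identity 2
#' is swapped for identity 3 on the right arm with a visibility gap) and
#' laparoscope moves (global out-and-back view drift flagged by the camera
#' indicator). Per-subject parameters are drawn around the class means with
#' a between-subject coefficient of variation.
#'
#' @param nPerClass Integer scalar or length-3 vector (novice, skilled,
#'   expert): subjects per class; unequal counts give a deliberately
#'   imbalanced cohort.
#' @param params Class parameter list (see [defaultSkillParams()]); class
#'   means must respect the expert <= skilled <= novice ordering in
#'   inefficiency, out-of-view rate and collision rate.
#' @param betweenSubjectCv Coefficient of variation of subject-level
#'   parameters.
#' @param taskMm Productive net displacement per instrument (mm).
#' @param fps Trajectory sampling rate (Hz).
#' @param seed Integer seed.
#' @return A [SkillCohort-class].
#' @export
generateSkillCohort <- function(nPerClass = 18, params = defaultSkillParams(),
                                betweenSubjectCv = 0.12, taskMm = 150,
                                fps = 5, seed = 1L) {
  if (length(nPerClass) == 1) nPerClass <- rep(nPerClass, 3)
  stopifnot(length(nPerClass) == 3, all(nPerClass >= 1))
  ord <- function(fieldName) {
    v <- vapply(params, `[[`, numeric(1), fieldName)
    v[["expert"]] <= v[["skilled"]] && v[["skilled"]] <= v[["novice"]]
  }
  if (!ord("inefficiency") || !ord("oovRate") || !ord("collisionRate"))
    stop("class means must be ordered expert <= skilled <= novice in ",
         "inefficiency, out-of-view rate and collision rate")
  subjects <- list()
  labels <- character(0)
  k <- 0L
  for (ci in seq_along(SKILL_LEVELS)) {
    cls <- SKILL_LEVELS[ci]
    for (s in seq_len(nPerClass[ci])) {
      k <- k + 1L
      subjects[[k]] <- withSeed(seed + 1000L * ci + s,
        simulateSubject(params[[cls]], betweenSubjectCv, taskMm, fps))
      labels <- c(labels, cls)
    }
  }
  new("SkillCohort", subjects = subjects,
      labels = factor(labels, levels = SKILL_LEVELS),
      params = list(classParams = params, cv = betweenSubjectCv,
                    taskMm = taskMm, fps = fps), seed = as.integer(seed))
}

simulateSubject <- function(p, cv, taskMm, fps) {
  draw <- function(mu, lo = 1e-3) max(lo, stats::rnorm(1, mu, cv * mu))
  speed <- draw(p$speed)
  ineff <- max(1, draw(p$inefficiency))
  pauseFrac <- clamp(draw(p$pauseFrac), 0.02, 0.85)
  bounds1 <- c(-85, -10, -55, 55)
  bounds2 <- c(10, 85, -55, 55)
  s1 <- simInstrumentSeries(c(-45, 0), bounds1, speed, ineff, pauseFrac,
                            taskMm, fps)
  s2 <- simInstrumentSeries(c(45, 0), bounds2, speed, ineff, pauseFrac,
                            taskMm, fps)
  nT <- max(length(s1$x), length(s2$x))
  padTo <- function(v, n) c(v, rep(v[length(v)], n - length(v)))
  x1 <- padTo(s1$x, nT); y1 <- padTo(s1$y, nT)
  x2 <- padTo(s2$x, nT); y2 <- padTo(s2$y, nT)
  minutes <- nT / fps / 60

  # collisions: right tip excursions onto the left tip
  nCol <- stats::rpois(1, p$collisionRate * minutes)
  colIv <- pickIntervals(nCol, nT, function() fps * 1.2, minGap = 3 * fps)
  for (r in seq_len(nrow(colIv))) {
    tt <- colIv$from[r]:colIv$to[r]
    mid <- colIv$from[r] + (colIv$to[r] - colIv$from[r]) / 2
    b <- sstep(1 - abs(tt - mid) / max(1, (colIv$to[r] - colIv$from[r]) / 2))
    tgt <- c(x1[round(mid)] + 5, y1[round(mid)])
    x2[tt] <- (1 - b) * x2[tt] + b * tgt[1]
    y2[tt] <- (1 - b) * y2[tt] + b * tgt[2]
  }

  # instrument changes: identity 2 <-> 3 swaps with a visibility gap
  nChg <- stats::rpois(1, p$changeRate * minutes)
  chgIv <- pickIntervals(nChg, nT, function() 2 * fps, minGap = 25 * fps)
  ident2 <- rep(2L, nT)
  gap2 <- rep(FALSE, nT)
  cur <- 2L
  for (r in seq_len(nrow(chgIv))) {
    gap2[chgIv$from[r]:chgIv$to[r]] <- TRUE
    cur <- if (cur == 2L) 3L else 2L
    if (chgIv$to[r] < nT) ident2[(chgIv$to[r] + 1):nT] <- cur
  }

  # out-of-view episodes per instrument
  visible1 <- rep(TRUE, nT); visible2 <- !gap2
  nOov <- stats::rpois(2, p$oovRate * minutes / 2)
  oov1 <- pickIntervals(nOov[1], nT, function() fps * (3 + stats::rexp(1, 1 / 3)),
                        minGap = 5 * fps)
  for (r in seq_len(nrow(oov1))) visible1[oov1$from[r]:oov1$to[r]] <- FALSE
  oov2 <- pickIntervals(nOov[2], nT, function() fps * (3 + stats::rexp(1, 1 / 3)),
                        minGap = 5 * fps)
  for (r in seq_len(nrow(oov2))) visible2[oov2$from[r]:oov2$to[r]] <- FALSE

  # laparoscope moves: global out-and-back drift, camera indicator on
  nCam <- stats::rpois(1, p$cameraRate * minutes)
  camIv <- pickIntervals(nCam, nT, function() fps * (2 + stats::rexp(1, 1 / 2)),
                         minGap = 4 * fps)
  cameraMoving <- rep(FALSE, nT)
  for (r in seq_len(nrow(camIv))) {
    tt <- camIv$from[r]:camIv$to[r]
    u <- (tt - camIv$from[r]) / max(1, camIv$to[r] - camIv$from[r])
    drift <- 12 * sin(pi * u)^2
    x1[tt] <- x1[tt] + drift; x2[tt] <- x2[tt] + drift
    y1[tt] <- y1[tt] + 0.5 * drift; y2[tt] <- y2[tt] + 0.5 * drift
    cameraMoving[tt] <- TRUE
  }

  frames <- seq_len(nT)
  trajectory <- rbind(
    data.frame(frame = frames, identity = 1L, x_mm = x1, y_mm = y1,
               visible = visible1),
    data.frame(frame = frames, identity = ident2, x_mm = x2, y_mm = y2,
               visible = visible2))
  trajectory <- trajectory[trajectory$visible, , drop = FALSE]
  states <- data.frame(frame = frames, cameraMoving = cameraMoving,
                       leftActive = TRUE, rightActive = !gap2)
  boxSide <- 14
  boxes <- data.frame(frame = trajectory$frame, identity = trajectory$identity,
                      x = trajectory$x_mm - boxSide / 2,
                      y = trajectory$y_mm - boxSide / 2,
                      w = boxSide, h = boxSide)
  movingMask1 <- padTo(s1$moving, nT); movingMask2 <- padTo(s2$moving, nT)
  realized <- list(
    speed = speed, inefficiency = ineff, pauseFrac = pauseFrac,
    movingTimeS = (sum(movingMask1) + sum(movingMask2)) / fps,
    nCollisions = nrow(colIv), nChanges = nrow(chgIv),
    nOov = nrow(oov1) + nrow(oov2), nCamera = nrow(camIv),
    cameraDurationS = sum(cameraMoving) / fps, durationS = nT / fps)
  list(trajectory = trajectory, states = states, boxes = boxes,
       realized = realized, fps = fps)
}

boxOverlapTable <- function(boxes) {
  out <- list()
  for (f in unique(boxes$frame)) {
    d <- boxes[boxes$frame == f, , drop = FALSE]
    if (nrow(d) < 2) next
    for (a in seq_len(nrow(d) - 1)) for (b in (a + 1):nrow(d)) {
      if (d$identity[a] == d$identity[b]) next
      if (boxIou(c(d$x[a], d$y[a], d$w[a], d$h[a]),
                 c(d$x[b], d$y[b], d$w[b], d$h[b])) > 0)
        out[[length(out) + 1]] <- data.frame(frame = f,
                                             a = d$identity[a],
                                             b = d$identity[b])
    }
  }
  if (!length(out)) return(data.frame(frame = integer(0), a = integer(0),
                                      b = integer(0)))
  do.call(rbind, out)
}

#' Motion-metric table of a skill cohort
#'
#' Gates each subject's trajectory with its indicator states, computes the
#' nine motion metrics and returns one row per subject.
#'
#' @param cohort A [SkillCohort-class].
#' @return List: `metrics` (data.frame), `labels` (factor).
#' @export
cohortMetrics <- function(cohort) {
  armOf <- c("1" = "left", "2" = "right", "3" = "right")
  rows <- lapply(cohort@subjects, function(su) {
    traj <- gateTrajectory(su$trajectory, su$states, armOf = armOf)
    computeMetrics(traj, su$states, su$fps,
                   overlaps = boxOverlapTable(su$boxes), armOf = armOf)
  })
  list(metrics = do.call(rbind, rows), labels = cohort@labels)
}

#' Feature-level metric cohort with an injected dominant metric
#'
#' Draws metric-table rows directly (standard-normal noise per column) and
#' injects a class effect into one chosen column only, so that recovery of
#' that column as the top-ranked feature validates the importance analysis.
#'
#' @param nPerClass Subjects per class (scalar or length 3).
#' @param dominant Column receiving the class effect.
#' @param separation Class step size in s.d. units.
#' @param seed Integer seed.
#' @return List: `features` (data.frame with metric column names),
#'   `labels`.
#' @export
simulateMetricCohort <- function(nPerClass = 18,
                                 dominant = "economyOfMotionMm",
                                 separation = 2, seed = 1L) {
  if (length(nPerClass) == 1) nPerClass <- rep(nPerClass, 3)
  cols <- c("timeToCompletionS", "outOfViewCount", "collisionCount",
            "economyOfMotionMm", "averageSpeedMmS", "movementCount",
            "economicFactor", "instrumentChangeCount", "laparoscopyCount",
            "laparoscopyDurationS")
  stopifnot(dominant %in% cols)
  n <- sum(nPerClass)
  labels <- factor(rep(SKILL_LEVELS, nPerClass), levels = SKILL_LEVELS)
  withSeed(seed, {
    x <- matrix(stats::rnorm(n * length(cols)), n,
                dimnames = list(NULL, cols))
    shift <- (as.integer(labels) - 2) * separation
    x[, dominant] <- x[, dominant] + shift
    list(features = as.data.frame(x), labels = labels)
  })
}
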