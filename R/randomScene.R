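#' @include sceneSim.R
NULL

## piecewise hold/glide path through anchor points with smoothstep easing;
## anchors: matrix(frame, x, y), frames increasing, constant outside range
holdGlidePath <- function(anchors, nFrames) {
  path <- matrix(NA_real_, nFrames, 2)
  a <- anchors[order(anchors[, 1]), , drop = FALSE]
  path[1:max(1, a[1, 1]), 1] <- a[1, 2]
  path[1:max(1, a[1, 1]), 2] <- a[1, 3]
  for (k in seq_len(nrow(a) - 1)) {
    f1 <- a[k, 1]; f2 <- a[k + 1, 1]
    if (f2 <= f1) next
    t <- f1:f2
    b <- sstep((t - f1) / (f2 - f1))
    path[t, 1] <- a[k, 2] + b * (a[k + 1, 2] - a[k, 2])
    path[t, 2] <- a[k, 3] + b * (a[k + 1, 3] - a[k, 3])
  }
  last <- a[nrow(a), 1]
  if (last < nFrames) {
    path[last:nFrames, 1] <- a[nrow(a), 2]
    path[last:nFrames, 2] <- a[nrow(a), 3]
  }
  path
}

## alternate hold/glide anchors inside a rectangular region
wanderAnchors <- function(fromFrame, toFrame, region, start = NULL,
                          glide = c(18, 30), hold = c(14, 24)) {
  f <- fromFrame
  pt <- start %||% c(stats::runif(1, region[1], region[2]),
                     stats::runif(1, region[3], region[4]))
  anchors <- matrix(c(f, pt), 1, 3)
  repeat {
    g <- round(stats::runif(1, glide[1], glide[2]))
    # never compress a glide into the remaining frames: the tip would jump
    if (f + g > toFrame) break
    f <- f + g
    pt <- c(stats::runif(1, region[1], region[2]),
            stats::runif(1, region[3], region[4]))
    anchors <- rbind(anchors, c(f, pt))
    h <- round(stats::runif(1, hold[1], hold[2]))
    if (f + h >= toFrame) break
    f <- f + h
    anchors <- rbind(anchors, c(f, pt))
  }
  anchors
}

#' Build a structured random scene
#'
#' Convenience generator for test and benchmark scenes: 1-3 instruments
#' wandering in separated home regions with hold/glide motion, optional
#' scheduled crossings (two tips meet at the view center so their masks
#' overlap), exit/re-entry events, a mid-scene third instrument that enters
#' from the top and leaves again, and out-and-back camera-motion events.
#' All schedule positions are fractions of `nFrames`, so scenes scale.
#'
#' @param nInstruments 1, 2 or 3.
#' @param nFrames Scene length in frames (>= 100 recommended).
#' @param width,height,fps,shaftWidthPx Passed to [sceneConfig()].
#' @param withCrossings,withExits,withCamera Toggle the scheduled events.
#' @param thirdWandersFullScene If TRUE the third instrument is visible for
#'   the whole scene instead of entering mid-scene from the top.
#' @param seed Integer seed.
#' @return A [Scene-class].
#' @export
randomScene <- function(nInstruments = 3, nFrames = 500, width = 320,
                        height = 240, fps = 23, shaftWidthPx = 16,
                        withCrossings = nInstruments >= 2, withExits = TRUE,
                        withCamera = TRUE, thirdWandersFullScene = FALSE,
                        seed = 1L) {
  stopifnot(nInstruments >= 1, nInstruments <= 3, nFrames >= 60)
  fr <- function(f) as.integer(pmax(1, pmin(nFrames, round(f * nFrames))))
  w <- width; h <- height

  built <- withSeed(seed, {
    reg1 <- c(0.16 * w, 0.44 * w, 0.40 * h, 0.80 * h)
    reg2 <- c(0.56 * w, 0.84 * w, 0.40 * h, 0.80 * h)
    reg3 <- c(0.52 * w, 0.78 * w, 0.14 * h, 0.40 * h)
    instruments <- list(
      list(pivot = c(-0.4 * w, 0.75 * h), armSide = "left", hue = 0.58),
      list(pivot = c(1.4 * w, 0.75 * h), armSide = "right", hue = 0.12),
      list(pivot = c(0.75 * w, -0.5 * h), armSide = "right", hue = 0.83)
    )[seq_len(nInstruments)]

    paths <- vector("list", nInstruments)
    paths[[1]] <- holdGlidePath(wanderAnchors(10, nFrames - 5, reg1), nFrames)
    if (nInstruments >= 2)
      paths[[2]] <- holdGlidePath(wanderAnchors(10, nFrames - 5, reg2), nFrames)
    if (nInstruments >= 3) {
      if (thirdWandersFullScene) {
        paths[[3]] <- holdGlidePath(wanderAnchors(10, nFrames - 5, reg3),
                                    nFrames)
      } else {
        f1 <- fr(0.42); f2 <- fr(0.70)
        park <- c(0.68 * w, -0.25 * h)
        inside <- wanderAnchors(min(f1 + 15, f2 - 16), f2 - 15, reg3)
        anchors <- rbind(c(max(1, f1 - 1), park), inside,
                         c(min(nFrames, f2 + 14), park))
        paths[[3]] <- holdGlidePath(anchors, nFrames)
      }
    }

    if (withCrossings && nInstruments >= 2) {
      meet <- c(0.5 * w, 0.62 * h)
      for (ev in list(c(0.50, 0.58), c(0.64, 0.71))) {
        g1 <- fr(ev[1]); g2 <- fr(ev[2])
        m <- meet + stats::runif(2, -6, 6)
        ramp <- max(4, round((g2 - g1) / 3))
        for (t in g1:g2) {
          b <- sstep(min(1, (t - g1) / ramp, (g2 - t) / ramp))
          # tips pass each other so the shafts genuinely cross/overlap
          paths[[1]][t, ] <- (1 - b) * paths[[1]][t, ] + b * (m + c(7, -3))
          paths[[2]][t, ] <- (1 - b) * paths[[2]][t, ] + b * (m + c(-7, 3))
        }
      }
    }

    exitEvents <- noEvents(instrument = TRUE)
    if (withExits) {
      exitEvents <- data.frame(
        instrument = c(2L, 1L, 2L),
        from = c(fr(0.12), fr(0.26), fr(0.74)),
        to = c(fr(0.22), fr(0.36), fr(0.94)))
      exitEvents <- exitEvents[exitEvents$instrument <= nInstruments, ]
    }

    cameraEvents <- if (withCamera)
      data.frame(from = fr(0.95), to = fr(0.99), dx = 12, dy = 6)
    else noEvents(camera = TRUE)

    activeIntervals <- data.frame(instrument = 1L, from = 10L,
                                  to = as.integer(nFrames))
    if (nInstruments >= 2) {
      if (nInstruments >= 3) {
        activeIntervals <- rbind(activeIntervals,
          data.frame(instrument = 2L,
                     from = c(10L, fr(0.73)), to = c(fr(0.41), as.integer(nFrames))),
          data.frame(instrument = 3L, from = fr(0.44), to = fr(0.69)))
      } else {
        activeIntervals <- rbind(activeIntervals,
          data.frame(instrument = 2L, from = 10L, to = as.integer(nFrames)))
      }
    }

    for (i in seq_len(nInstruments)) instruments[[i]]$path <- paths[[i]]
    list(instruments = instruments, exitEvents = exitEvents,
         cameraEvents = cameraEvents, activeIntervals = activeIntervals)
  })

  cfg <- sceneConfig(width = width, height = height, fps = fps,
                     nFrames = nFrames, instruments = built$instruments,
                     shaftWidthPx = shaftWidthPx,
                     exitEvents = built$exitEvents,
                     cameraEvents = built$cameraEvents,
                     activeIntervals = built$activeIntervals,
                     seed = seed)
  generateScene(cfg)
}
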