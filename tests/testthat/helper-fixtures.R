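# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

# 120-frame two-instrument scene with crossings, exits and a camera event
fixtureScene <- function() {
  if (is.null(.fixtures$scene2))
    .fixtures$scene2 <- randomScene(nInstruments = 2, nFrames = 120,
                                    seed = 3)
  .fixtures$scene2
}

# single static horizontal instrument: tip fixed at (120, 60)
staticSceneConfig <- function(nFrames = 10, tipX = 120, tipY = 60) {
  sceneConfig(
    width = 200, height = 120, nFrames = nFrames,
    instruments = list(list(
      pivot = c(-80, tipY), armSide = "left", hue = 0.55,
      waypoints = matrix(c(1, tipX, tipY), 1, 3))),
    activeIntervals = data.frame(instrument = 1L, from = 1L,
                                 to = as.integer(nFrames)),
    seed = 11L)
}

# rectangular mask as a logical matrix (0-based half-open box)
rectMask <- function(h, w, x, y, bw, bh) {
  m <- matrix(FALSE, h, w)
  m[(y + 1):(y + bh), (x + 1):(x + bw)] <- TRUE
  m
}

# rotated-rectangle mask: pixels within width/2 of a segment
rotRectMask <- function(h, w, cx, cy, len, wid, angleDeg) {
  a <- angleDeg * pi / 180
  dir <- c(cos(a), sin(a))
  px <- rep(0:(w - 1), each = h)
  py <- rep(0:(h - 1), times = w)
  rx <- px - cx; ry <- py - cy
  s <- rx * dir[1] + ry * dir[2]
  q <- rx * dir[2] - ry * dir[1]
  matrix(abs(s) <= len / 2 & q >= -wid / 2 & q < wid / 2, h, w)
}

# brute-force minimum assignment cost by permutation enumeration
bruteForceAssignmentCost <- function(cost) {
  if (nrow(cost) > ncol(cost)) cost <- t(cost)
  n <- nrow(cost); m <- ncol(cost)
  best <- Inf
  rec <- function(i, used, acc) {
    if (i > n) { best <<- min(best, acc); return() }
    for (j in seq_len(m)) {
      if (!used[j]) {
        u <- used; u[j] <- TRUE
        rec(i + 1, u, acc + cost[i, j])
      }
    }
  }
  rec(1, rep(FALSE, m), 0)
  best
}

# simple one-identity trajectory table in mm
mmTrajectory <- function(x, y, fps = 10, identity = 1L) {
  data.frame(frame = seq_along(x),
             identity = rep(identity, length.out = length(x)),
             x_mm = x, y_mm = y,
             valid_motion = rep(TRUE, length(x)),
             active = rep(TRUE, length(x)),
             visible = rep(TRUE, length(x)))
}

blankStates <- function(n, camera = rep(FALSE, n)) {
  data.frame(frame = seq_len(n), cameraMoving = camera,
             leftActive = TRUE, rightActive = TRUE)
}
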