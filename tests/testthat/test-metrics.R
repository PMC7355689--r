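test_that("economy of motion matches closed forms", {
  expect_equal(economyOfMotion(mmTrajectory(rep(5, 10), rep(5, 10))), 0)
  # straight segment (0,0) -> (30,40): length 50 at any sampling
  for (n in c(5, 20, 173)) {
    t <- seq(0, 1, length.out = n)
    expect_equal(economyOfMotion(mmTrajectory(30 * t, 40 * t)), 50,
                 tolerance = 1e-9)
  }
  # one revolution of a radius-10 circle, 1000 samples
  t <- seq(0, 2 * pi, length.out = 1001)
  circ <- economyOfMotion(mmTrajectory(10 * cos(t), 10 * sin(t)))
  expect_lt(abs(circ - 20 * pi), 0.1)
  expect_equal(economyOfMotion(mmTrajectory(numeric(0), numeric(0))), 0)
})

test_that("average speed divides path by valid-motion duration", {
  t <- seq(0, 1, length.out = 101)
  traj <- mmTrajectory(30 * t, 40 * t, fps = 10)  # 50 mm over 10 s
  expect_equal(averageSpeed(traj, fps = 10), 5)
  still <- mmTrajectory(rep(1, 5), rep(1, 5))
  expect_equal(averageSpeed(still, 10), 0)
  expect_error(averageSpeed(still[1, ], 10), "duration")
})

test_that("metrics are invariant under time reversal", {
  withr::with_seed(2, {
    x <- cumsum(rnorm(200)); y <- cumsum(rnorm(200))
    fwd <- mmTrajectory(x, y)
    rev <- mmTrajectory(rev(x), rev(y))
    expect_equal(economyOfMotion(fwd), economyOfMotion(rev))
    expect_equal(averageSpeed(fwd, 10), averageSpeed(rev, 10))
  })
})

test_that("resampling a fixed path changes economy by under 2 percent", {
  path <- function(n) {
    t <- seq(0, 4 * pi, length.out = n)
    mmTrajectory(t * 3, 10 * sin(t))
  }
  e1 <- economyOfMotion(path(400))
  e2 <- economyOfMotion(path(4000))
  expect_lt(abs(e1 - e2) / e2, 0.02)
})

test_that("out-of-view counts deficit episodes per active side", {
  presence <- data.frame(frame = c(1:10, 16:30), identity = 1L)
  states <- blankStates(30)
  armOf <- c("1" = "left")
  states$rightActive <- FALSE
  expect_equal(countOutOfView(presence, states, armOf), 1)
  full <- data.frame(frame = 1:30, identity = 1L)
  expect_equal(countOutOfView(full, states, armOf), 0)
  # three separated absences -> three events
  p3 <- data.frame(frame = setdiff(1:60, c(10:12, 25:28, 50:55)),
                   identity = 1L)
  s3 <- blankStates(60)
  s3$rightActive <- FALSE  # no identity works the right arm here
  expect_equal(countOutOfView(p3, s3, armOf), 3)
})

test_that("collisions count pair-onset events, not overlap frames", {
  expect_equal(countCollisions(NULL), 0L)
  ov <- data.frame(frame = c(5, 6, 7, 20, 21), a = 1, b = 2)
  expect_equal(countCollisions(ov), 2L)
  ov2 <- rbind(ov, data.frame(frame = c(6, 30), a = 2, b = 3))
  expect_equal(countCollisions(ov2), 4L)
})

test_that("movement episodes count smoothed bursts above threshold", {
  still <- mmTrajectory(rep(0, 50), rep(0, 50))
  expect_equal(countMovements(still, fps = 10), 0)
  glide <- mmTrajectory(seq(0, 30, length.out = 50), rep(0, 50))
  expect_equal(countMovements(glide, fps = 10), 1)
  # five bursts separated by pauses
  seg <- function(v, n) rep(v, n)
  speeds <- c()
  for (b in 1:5) speeds <- c(speeds, seg(0.8, 10), seg(0, 12))
  x <- cumsum(speeds)  # 0.8 mm/sample at fps 10 = 8 mm/s bursts
  expect_equal(countMovements(mmTrajectory(x, rep(0, length(x)), fps = 10),
                              fps = 10), 5)
})

test_that("economic factor matches straight and half-circle closed forms", {
  t <- seq(0, 1, length.out = 60)
  straight <- mmTrajectory(50 * t, rep(0, 60))
  expect_equal(economicFactor(straight, fps = 10), 1, tolerance = 1e-6)
  # half circle of radius r: net 2r over path pi*r -> 2/pi
  th <- seq(0, pi, length.out = 200)
  half <- mmTrajectory(20 * cos(th), 20 * sin(th))
  expect_equal(economicFactor(half, fps = 10), 2 / pi, tolerance = 0.01)
  # zero-net loop counts as 0, included in the mean
  th2 <- seq(0, 2 * pi, length.out = 400)
  loop <- mmTrajectory(20 * cos(th2), 20 * sin(th2))
  expect_lt(economicFactor(loop, fps = 10), 0.05)
  expect_message(val <- economicFactor(mmTrajectory(rep(0, 9), rep(0, 9)),
                                       fps = 10), "undefined")
  expect_true(is.na(val))
})

test_that("instrument changes pair departures with different arrivals", {
  # constant instrument set
  p0 <- data.frame(frame = rep(1:100, 2), identity = rep(1:2, each = 100))
  expect_equal(countInstrumentChanges(p0, 100), 0L)
  # swap: identity 2 leaves for good at 40, identity 3 enters at 50
  p1 <- rbind(data.frame(frame = 1:100, identity = 1L),
              data.frame(frame = 1:40, identity = 2L),
              data.frame(frame = 50:100, identity = 3L))
  expect_equal(countInstrumentChanges(p1, 100), 1L)
  # an identity re-entering after its own absence is not a change
  p2 <- rbind(data.frame(frame = 1:100, identity = 1L),
              data.frame(frame = c(1:30, 75:100), identity = 2L))
  expect_equal(countInstrumentChanges(p2, 100), 0L)
  # two swaps
  p3 <- rbind(data.frame(frame = 1:200, identity = 1L),
              data.frame(frame = 1:50, identity = 2L),
              data.frame(frame = 60:130, identity = 3L),
              data.frame(frame = 140:200, identity = 2L))
  expect_equal(countInstrumentChanges(p3, 200), 2L)
})

test_that("laparoscopy usage counts camera intervals and durations", {
  states <- blankStates(100)
  expect_equal(unname(laparoscopyUsage(states, 23)), c(0, 0))
  states$cameraMoving[31:50] <- TRUE
  u <- laparoscopyUsage(states, 23)
  expect_equal(unname(u["count"]), 1)
  expect_equal(unname(u["durationS"]), 20 / 23, tolerance = 1e-9)
  states$cameraMoving[80:85] <- TRUE
  u2 <- laparoscopyUsage(states, 23)
  expect_equal(unname(u2["count"]), 2)
  expect_equal(unname(u2["durationS"]), 26 / 23, tolerance = 1e-9)
})

test_that("normalization: identical rows collapse to zeros with a warning", {
  row <- data.frame(timeToCompletionS = 100, outOfViewCount = 2,
                    collisionCount = 1, economyOfMotionMm = 500,
                    averageSpeedMmS = 5, movementCount = 10,
                    economicFactor = 0.8, instrumentChangeCount = 1,
                    laparoscopyCount = 2, laparoscopyDurationS = 8)
  tbl <- rbind(row, row, row)
  expect_warning(out <- normalizeMetrics(tbl), "zero-variance")
  expect_true(all(as.matrix(out$normalized) == 0))
})

test_that("doubling video length with identical motion halves stage-1 rates", {
  row <- data.frame(timeToCompletionS = 100, outOfViewCount = 2,
                    collisionCount = 1, economyOfMotionMm = 500,
                    averageSpeedMmS = 5, movementCount = 10,
                    economicFactor = 0.8, instrumentChangeCount = 1,
                    laparoscopyCount = 2, laparoscopyDurationS = 8)
  long <- row; long$timeToCompletionS <- 200
  s1 <- sitrack:::stage1Normalize(rbind(row, long))
  expect_equal(s1$outOfViewCount[2], s1$outOfViewCount[1] / 2)
  expect_equal(s1$economyOfMotionMm[2], s1$economyOfMotionMm[1] / 2)
  expect_equal(s1$averageSpeedMmS, c(5, 5))  # intensive metric untouched
})

test_that("z-scoring gives mean 0, sd 1 and a reusable transform", {
  withr::with_seed(6, {
    tbl <- as.data.frame(matrix(rexp(10 * 12, 0.1), 12))
    names(tbl) <- c("timeToCompletionS", "outOfViewCount", "collisionCount",
                    "economyOfMotionMm", "averageSpeedMmS", "movementCount",
                    "economicFactor", "instrumentChangeCount",
                    "laparoscopyCount", "laparoscopyDurationS")
    out <- normalizeMetrics(tbl)
    expect_equal(unname(colMeans(out$normalized)), rep(0, 10),
                 tolerance = 1e-9)
    expect_equal(unname(vapply(out$normalized, sd, numeric(1))), rep(1, 10),
                 tolerance = 1e-9)
    again <- applyMetricTransform(out$transform, tbl)
    expect_equal(again, out$normalized)
  })
})
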