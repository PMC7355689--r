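test_that("Kalman prediction advances by the constant-velocity model", {
  st <- kalmanInit(c(0, 0, 20, 20))
  st$mean[1:2] <- c(10, 10)
  st$mean[5:6] <- c(3, 0)
  pr <- kalmanPredict(st)
  expect_equal(pr$mean[1], 13)
  expect_equal(pr$mean[2], 10)
  # zero-velocity: position unchanged, covariance strictly grows
  st0 <- kalmanInit(c(0, 0, 20, 20))
  pr0 <- kalmanPredict(st0)
  expect_equal(pr0$mean[1:4], st0$mean[1:4])
  expect_gt(sum(diag(pr0$cov)), sum(diag(st0$cov)))
})

test_that("zero innovation leaves the mean unchanged; noise->0 limit", {
  st <- kalmanInit(c(10, 10, 20, 20))
  z <- st$mean[1:4]
  up <- kalmanUpdate(st, z)
  expect_equal(up$mean[1:4], z, tolerance = 1e-9)
  # measurement noise -> 0: posterior mean -> measurement
  z2 <- z + c(5, -3, 0.1, 2)
  up2 <- kalmanUpdate(st, z2, measurementVar = 1e-12)
  expect_equal(up2$mean[1:4], z2, tolerance = 1e-5)
  expect_error(kalmanUpdate(st, c(0, 0, 1, -5)), "positive")
})

test_that("scalar analogue: equal prior and measurement variance gives gain 1/2", {
  st <- kalmanInit(c(0, 0, 10, 10))
  st$cov <- diag(8)  # prior variance 1 on each measured component
  z <- st$mean[1:4] + c(1, 0, 0, 0)
  up <- kalmanUpdate(st, z, measurementVar = 1)
  expect_equal(up$mean[1] - st$mean[1], 0.5, tolerance = 1e-9)
})

test_that("velocity estimate converges on noiseless constant-velocity input", {
  st <- kalmanInit(c(0, 0, 20, 20))
  for (k in 1:50) {
    st <- kalmanPredict(st)
    st <- kalmanUpdate(st, c(10 + 2 * k, 10 + 0.5 * k, 1, 20),
                       measurementVar = 1e-8)
  }
  expect_equal(st$mean[5], 2, tolerance = 1e-3)
  expect_equal(st$mean[6], 0.5, tolerance = 1e-3)
})

test_that("IOU matches closed forms and symmetry", {
  a <- c(0, 0, 10, 10)
  expect_equal(boxIou(a, a), 1)
  expect_equal(boxIou(a, c(20, 20, 5, 5)), 0)
  expect_equal(boxIou(a, c(5, 0, 10, 10)), 1 / 3)
  expect_equal(boxIou(c(5, 0, 10, 10), a), 1 / 3)
  expect_equal(boxIou(c(0, 0, 0, 0), c(0, 0, 0, 0)), 0)
})

test_that("assignment equals the exhaustive-permutation optimum", {
  res <- associate(matrix(c(0.1, 0.9, 0.9, 0.1), 2, byrow = TRUE))
  expect_equal(res$matches[, "col"], res$matches[, "row"])
  withr::with_seed(13, {
    for (rep in 1:200) {
      nr <- sample(1:4, 1); nc <- sample(1:4, 1)
      cost <- matrix(runif(nr * nc), nr, nc)
      sol <- solveAssignment(cost)
      expect_equal(sum(cost[sol]), bruteForceAssignmentCost(cost),
                   tolerance = 1e-9)
    }
  })
  # empty input
  e <- associate(matrix(numeric(0), 0, 0))
  expect_equal(nrow(e$matches), 0)
})

test_that("gated pairs are never matched", {
  cost <- matrix(c(0.1, 0.2, 0.3, 0.4), 2)
  adm <- matrix(c(FALSE, TRUE, TRUE, FALSE), 2)
  res <- associate(cost, adm)
  for (k in seq_len(nrow(res$matches)))
    expect_true(adm[res$matches[k, 1], res$matches[k, 2]])
})

test_that("two clean instruments give two confirmed tracks, no switches", {
  sc <- randomScene(nInstruments = 2, nFrames = 100, withExits = FALSE,
                    withCamera = FALSE, withCrossings = FALSE, seed = 6)
  st <- sceneTruth(sc)
  ts <- newTracker()
  for (t in 1:100) ts <- trackerStep(ts, oracleDetect(sc, t))
  expect_equal(countTracks(ts, "confirmed"), 2)
  # boxes equal GT after confirmation lag
  ids <- vapply(ts$tracks, `[[`, integer(1), "id")
  for (tr in ts$tracks[order(ids)]) expect_equal(length(tr$box), 4)
})

test_that("confirmed tracks never exceed three under five detection streams", {
  h <- 100; w <- 200
  mkDet <- function(x, y) {
    m <- rectMask(h, w, x, y, 14, 10)
    makeDetection(1, which(m), h, w, 0.95)
  }
  ts <- newTracker()
  maxConf <- 0
  for (t in 1:40) {
    dets <- list(mkDet(5, 5), mkDet(60, 5), mkDet(120, 5),
                 mkDet(5, 70), mkDet(120, 70))
    ts <- trackerStep(ts, dets)
    maxConf <- max(maxConf, countTracks(ts, "confirmed"))
    expect_lte(countTracks(ts, c("confirmed", "lost")), 3)
  }
  expect_equal(maxConf, 3)
})

test_that("a blocked track confirms when a slot frees", {
  h <- 100; w <- 220
  mkDet <- function(x) makeDetection(1, which(rectMask(h, w, x, 10, 14, 10)),
                                     h, w, 0.9)
  ts <- newTracker(trackerConfig(maxAge = 3))
  for (t in 1:10) ts <- trackerStep(ts, lapply(c(5, 55, 105, 155), mkDet))
  expect_equal(countTracks(ts, "confirmed"), 3)
  # drop stream 1; its track dies after maxAge, then the 4th stream confirms
  for (t in 1:8) ts <- trackerStep(ts, lapply(c(55, 105, 155), mkDet))
  expect_equal(countTracks(ts, "confirmed"), 3)
  xs <- vapply(ts$tracks, function(tr) tr$box[1], numeric(1))
  expect_setequal(round(xs), c(55, 105, 155))
})

test_that("track lifecycle: lost after absence, deleted after maxAge", {
  h <- 80; w <- 120
  det <- makeDetection(1, which(rectMask(h, w, 30, 30, 16, 10)), h, w, 1)
  ts <- newTracker(trackerConfig(maxAge = 5))
  for (t in 1:5) ts <- trackerStep(ts, list(det))
  expect_equal(ts$tracks[[1]]$status, "confirmed")
  for (t in 1:3) ts <- trackerStep(ts, list())
  expect_equal(ts$tracks[[1]]$status, "lost")
  for (t in 1:5) ts <- trackerStep(ts, list())
  expect_length(ts$tracks, 0)
  # re-entry spawns a new track
  ts <- trackerStep(ts, list(det))
  expect_equal(ts$tracks[[1]]$status, "tentative")
})
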