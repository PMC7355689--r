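test_that("tip RMSE matches closed forms", {
  gt <- data.frame(frame = 1:50, identity = 1, x_mm = seq(0, 49),
                   y_mm = rep(2, 50))
  expect_equal(tipRmse(gt, gt, fullRate = TRUE), 0)
  off <- gt; off$x_mm <- off$x_mm + 3; off$y_mm <- off$y_mm + 4
  expect_equal(tipRmse(off, gt, fullRate = TRUE), 5)
  expect_error(tipRmse(transform(gt, identity = 2), gt, fullRate = TRUE),
               "overlapping")
})

test_that("Gaussian tip error composes to sigma*sqrt(2) RMSE", {
  withr::with_seed(17, {
    n <- 10000
    gt <- data.frame(frame = 1:n, identity = 1, x_mm = runif(n, 0, 100),
                     y_mm = runif(n, 0, 100))
    pred <- gt
    pred$x_mm <- pred$x_mm + rnorm(n, 0, 2)
    pred$y_mm <- pred$y_mm + rnorm(n, 0, 2)
    expect_lt(abs(tipRmse(pred, gt, fullRate = TRUE) - 2 * sqrt(2)), 0.05)
  })
})

test_that("subsampling compares at the ground-truth labeling cadence", {
  gt <- data.frame(frame = 1:46, identity = 1, x_mm = 1:46, y_mm = 0)
  pred <- gt
  pred$x_mm[2] <- 999  # an error on a frame not at the 2/s cadence
  expect_equal(tipRmse(pred, gt, fps = 23, sampleRate = 2), 0)
  expect_gt(tipRmse(pred, gt, fullRate = TRUE), 0)
})

test_that("tolerance AUC: perfect separation, chance, and nesting", {
  expect_equal(toleranceAuc(rep(0.5, 20), runif(20), 1), 1)
  expect_equal(toleranceAuc(rep(5, 20), runif(20), 1), 0)
  withr::with_seed(23, {
    # confidences independent of correctness -> AUC ~ 0.5
    aucs <- vapply(1:40, function(i) {
      d <- c(runif(50, 0, 1), runif(50, 2, 4))
      toleranceAuc(d, runif(100), 1)
    }, numeric(1))
    expect_lt(abs(mean(aucs) - 0.5), 0.05)
    # strictly ranked confidences (no ties): nesting is exact
    for (rep in 1:10) {
      d <- rexp(200, 0.5)
      aucs <- vapply(c(1, 2, 5), function(tol)
        toleranceAuc(d, 1 / (1 + d), tol), numeric(1))
      expect_false(is.unsorted(aucs + 1e-12))
      # noisy confidences: nesting holds up to small rank perturbations
      conf <- 1 / (1 + d) + rnorm(200, 0, 0.02)
      aucsN <- vapply(c(1, 2, 5), function(tol) toleranceAuc(d, conf, tol),
                      numeric(1))
      expect_true(all(diff(aucsN) > -0.05))
    }
  })
  expect_error(toleranceAuc(numeric(0), numeric(0), 1), "samples")
})

test_that("trajectory Pearson hits its closed forms", {
  withr::with_seed(31, {
    gt <- data.frame(frame = 1:500, identity = 1,
                     x_mm = cumsum(rnorm(500)), y_mm = cumsum(rnorm(500)))
    expect_equal(unname(trajectoryPearson(gt, gt, fullRate = TRUE)),
                 c(1, 1))
    neg <- gt; neg$x_mm <- -neg$x_mm; neg$y_mm <- -neg$y_mm
    expect_equal(unname(trajectoryPearson(neg, gt, fullRate = TRUE)),
                 c(-1, -1))
    # signal + independent noise at SNR 10: r = 1/sqrt(1 + 1/SNR^2)
    snr <- 10
    sdS <- sd(gt$x_mm)
    noisy <- gt
    noisy$x_mm <- noisy$x_mm + rnorm(500, 0, sdS / snr)
    noisy$y_mm <- noisy$y_mm + rnorm(500, 0, sd(gt$y_mm) / snr)
    r <- trajectoryPearson(noisy, gt, fullRate = TRUE)
    expect_equal(unname(r), rep(1 / sqrt(1 + 1 / snr^2), 2),
                 tolerance = 0.005)
    flat <- gt; flat$x_mm <- 1
    expect_error(trajectoryPearson(flat, gt, fullRate = TRUE), "variance")
  })
})

test_that("identity switches: perfect tracking 0; a swap counts per identity", {
  sc <- fixtureScene()
  gt <- groundTruthTables(sc)
  st <- sceneTruth(sc)
  mkTracks <- function(swapAfter = NULL) {
    rows <- list()
    for (f in seq_len(nFrames(sc))) for (i in 1:2) {
      if (!st$visible[f, i]) next
      lab <- i
      if (!is.null(swapAfter) && f > swapAfter) lab <- 3 - i
      b <- st$boxes[[i]][f, ]
      rows[[length(rows) + 1]] <- data.frame(frame = f, identity = lab,
                                             x = b[1], y = b[2], w = b[3],
                                             h = b[4])
    }
    do.call(rbind, rows)
  }
  expect_equal(countIdentitySwitches(mkTracks(), sc), 0L)
  expect_equal(countIdentitySwitches(mkTracks(swapAfter = 60), sc), 2L)
  # a gap with the same label on re-link is not a switch
  tr <- mkTracks()
  tr <- tr[!(tr$frame %in% 40:55), ]
  expect_equal(countIdentitySwitches(tr, sc), 0L)
})

test_that("full pipeline on a zero-noise scene scores perfectly", {
  sc <- fixtureScene()
  res <- runPipeline(sc)
  ev <- evaluateTracking(res, sc)
  expect_equal(rmseMm(ev), 0)
  expect_equal(unname(aucAt(ev)), c(1, 1, 1))
  expect_equal(unname(ev@pearson), c(1, 1), tolerance = 1e-12)
  expect_equal(identitySwitches(ev), 0L)
  path <- withr::local_tempfile(fileext = ".json")
  writeEvalReport(ev, path)
  back <- jsonlite::fromJSON(path)
  expect_equal(back$rmse_mm, 0)
})

test_that("median RMSE degrades monotonically with box jitter", {
  sc <- randomScene(nInstruments = 1, nFrames = 150, withExits = FALSE,
                    withCamera = FALSE, withCrossings = FALSE, seed = 12)
  st <- sceneTruth(sc)
  mpp <- mmPerPx(sc)
  rmseAt <- function(sigmaPx, seed) {
    errs <- vapply(1:150, function(t) {
      if (!st$visible[t, 1]) return(NA_real_)
      dets <- oracleDetect(sc, t, noiseConfig(boxJitterSd = sigmaPx,
                                              seed = seed))
      if (!length(dets)) return(NA_real_)
      tip <- detectTip(dets[[1]]$maskIdx, dets[[1]]$h, dets[[1]]$w)
      sqrt(sum((tip - st$tip[[1]][t, ])^2)) * mpp
    }, numeric(1))
    sqrt(mean(errs^2, na.rm = TRUE))
  }
  meds <- vapply(c(1, 3, 6), function(sig)
    median(vapply(1:5, function(s) rmseAt(sig, s), numeric(1))), numeric(1))
  expect_true(all(diff(meds) > 0))
})
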