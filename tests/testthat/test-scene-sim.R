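test_that("a static instrument yields identical masks and a constant tip", {
  sc <- generateScene(staticSceneConfig(nFrames = 10))
  st <- sceneTruth(sc)
  expect_true(all(st$visible[, 1]))
  ref <- st$maskIdx[[1]][[1]]
  for (t in 2:10) expect_identical(st$maskIdx[[1]][[t]], ref)
  expect_equal(unique(st$tip[[1]][, 1]), st$tip[[1]][1, 1])
  expect_equal(unique(st$tip[[1]][, 2]), st$tip[[1]][1, 2])
})

test_that("linear waypoint motion gives an arithmetic tip sequence", {
  cfg <- sceneConfig(
    width = 260, height = 120, nFrames = 10,
    instruments = list(list(
      pivot = c(-80, 60), armSide = "left", hue = 0.55,
      waypoints = matrix(c(1, 90, 60, 10, 117, 60), 2, 3, byrow = TRUE))),
    seed = 5L)
  sc <- generateScene(cfg)
  tipx <- sceneTruth(sc)$tip[[1]][, 1]
  expect_equal(diff(tipx), rep(3, 9))
  expect_equal(unique(sceneTruth(sc)$tip[[1]][, 2]), sceneTruth(sc)$tip[[1]][1, 2])
})

test_that("scene generation is deterministic for a fixed seed", {
  a <- randomScene(nInstruments = 2, nFrames = 70, seed = 21)
  b <- randomScene(nInstruments = 2, nFrames = 70, seed = 21)
  expect_identical(sceneTruth(a)$maskIdx, sceneTruth(b)$maskIdx)
  expect_identical(sceneTruth(a)$tip, sceneTruth(b)$tip)
  expect_identical(renderFrame(a, 35), renderFrame(b, 35))
})

test_that("every ground-truth box is the tight hull of its mask", {
  sc <- fixtureScene()
  st <- sceneTruth(sc)
  h <- sc@config@height
  for (t in seq(1, nFrames(sc), by = 7)) {
    for (i in seq_along(st$tip)) {
      if (!st$visible[t, i]) next
      expect_equal(st$boxes[[i]][t, ],
                   sitrack:::boxFromMaskIdx(st$maskIdx[[i]][[t]], h))
    }
  }
})

test_that("ground-truth tips lie inside their masks", {
  sc <- fixtureScene()
  st <- sceneTruth(sc)
  h <- sc@config@height
  for (t in seq(1, nFrames(sc), by = 5)) {
    for (i in seq_along(st$tip)) {
      if (!st$visible[t, i]) next
      tipIdx <- sitrack:::xyToIdx(st$tip[[i]][t, 1], st$tip[[i]][t, 2], h)
      expect_true(tipIdx %in% st$maskIdx[[i]][[t]])
    }
  }
})

test_that("invalid scene configurations are rejected", {
  ins <- list(list(pivot = c(-80, 60), armSide = "left", hue = 0.5,
                   waypoints = matrix(c(1, 100, 60), 1, 3)))
  expect_error(sceneConfig(instruments = rep(list(ins[[1]]), 4)),
               "1, 2 or 3")
  expect_error(sceneConfig(
    instruments = ins, nFrames = 50,
    exitEvents = data.frame(instrument = 2L, from = 5L, to = 10L)),
    "unknown instrument")
  expect_error(sceneConfig(
    instruments = ins, nFrames = 50,
    exitEvents = data.frame(instrument = 1L, from = 5L, to = 80L)),
    "within")
  three <- rep(list(ins[[1]]), 3)
  expect_error(sceneConfig(
    instruments = three, nFrames = 50,
    activeIntervals = data.frame(instrument = 1:3, from = 1L, to = 50L)),
    "at most 2")
})

test_that("oracle redetection at zero noise reproduces ground-truth boxes", {
  sc <- fixtureScene()
  st <- sceneTruth(sc)
  for (t in c(5, 50, 100)) {
    dets <- oracleDetect(sc, t)
    vis <- which(st$visible[t, ])
    expect_length(dets, length(vis))
    for (k in seq_along(vis))
      expect_equal(dets[[k]]$box, st$boxes[[vis[k]]][t, ])
  }
})

test_that("ground truth round-trips through the JSON writer", {
  sc <- generateScene(staticSceneConfig(nFrames = 3))
  path <- withr::local_tempfile(fileext = ".json")
  writeGroundTruth(sc, path)
  gt <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  expect_equal(gt$mmPerPx, mmPerPx(sc))
  rle1 <- gt$instruments$maskRle[[1]]
  idx <- rleDecodeMask(if (is.list(rle1)) rle1[[1]] else rle1[1, ],
                       sc@config@height, sc@config@width)
  expect_setequal(idx, sceneTruth(sc)$maskIdx[[1]][[1]])
})

test_that("skill cohort honours requested class counts, incl. imbalance", {
  co <- generateSkillCohort(nPerClass = c(6, 4, 2), taskMm = 40, seed = 2)
  expect_equal(as.integer(table(cohortLabels(co))), c(6, 4, 2))
  expect_equal(levels(cohortLabels(co)), c("novice", "skilled", "expert"))
})

test_that("straight expert paths make economy equal net displacement", {
  p <- defaultSkillParams()
  for (cl in names(p)) p[[cl]]$inefficiency <- 1
  p$expert$pauseFrac <- 0.3
  co <- generateSkillCohort(nPerClass = c(1, 1, 1), params = p,
                            betweenSubjectCv = 0, taskMm = 60, seed = 5)
  su <- cohortSubjects(co)[[3]]  # expert
  # straight-line episodes: per-step path length equals net progress
  traj <- su$trajectory[su$trajectory$identity == 1 & su$trajectory$visible, ]
  traj <- traj[!su$states$cameraMoving[traj$frame], ]
  st <- sitrack:::stepTable(cbind(traj, valid_motion = TRUE, active = TRUE))
  # compare total path length with summed episode nets (straight segments)
  expect_gt(sum(st$step), 0)
  # realized inefficiency must be 1 within 1%
  expect_equal(su$realized$inefficiency, 1, tolerance = 1e-9)
})

test_that("cohort speed recovery: class means within 3 s.d. of configured", {
  co <- generateSkillCohort(nPerClass = 8, taskMm = 60,
                            betweenSubjectCv = 0.1, seed = 9)
  p <- defaultSkillParams()
  lab <- cohortLabels(co)
  for (cl in levels(lab)) {
    speeds <- vapply(cohortSubjects(co)[lab == cl],
                     function(su) su$realized$speed, numeric(1))
    se <- p[[cl]]$speed * 0.1 / sqrt(length(speeds))
    expect_lt(abs(mean(speeds) - p[[cl]]$speed), 3 * p[[cl]]$speed * 0.1)
    expect_gt(mean(speeds), 0)
  }
})

test_that("disordered class means are rejected", {
  p <- defaultSkillParams()
  p$expert$inefficiency <- 3  # worse than novice
  expect_error(generateSkillCohort(nPerClass = 1, params = p, seed = 1),
               "ordered")
})
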