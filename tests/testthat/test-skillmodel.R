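test_that("SMOTE balances classes and synthesizes on segments", {
  withr::with_seed(1, {
    x <- rbind(matrix(rnorm(40, 0), ncol = 2),
               matrix(rnorm(20, 5), ncol = 2),
               matrix(rnorm(10, 10), ncol = 2))
    y <- rep(c("a", "b", "c"), c(20, 10, 5))
  })
  out <- smote(x, y, kNeighbors = 3, seed = 9)
  expect_equal(as.integer(table(out$labels)), c(20, 20, 20))
  # original rows are untouched and come first
  expect_equal(out$features[1:35, ], x, ignore_attr = TRUE)
  # every synthetic point lies on a segment between a minority point and a
  # same-class neighbour: for each synthetic s there exist p1, p2 in its
  # class with s = p1 + u (p2 - p1), i.e. s - p1 is parallel to p2 - p1
  synth <- out$features[36:60, , drop = FALSE]
  synthLab <- out$labels[36:60]
  onSegment <- vapply(seq_len(nrow(synth)), function(i) {
    pts <- x[y == as.character(synthLab[i]), , drop = FALSE]
    for (a in seq_len(nrow(pts))) for (b in seq_len(nrow(pts))) {
      if (a == b) next
      v <- pts[b, ] - pts[a, ]; wv <- synth[i, ] - pts[a, ]
      u <- sum(wv * v) / sum(v * v)
      if (u >= -1e-9 && u <= 1 + 1e-9 &&
          sqrt(sum((wv - u * v)^2)) < 1e-8) return(TRUE)
    }
    FALSE
  }, logical(1))
  expect_true(all(onSegment))
})

test_that("SMOTE is deterministic, no-ops when balanced, errors on singletons", {
  x <- matrix(rnorm(30), ncol = 2)
  y <- rep(c("a", "b", "c"), each = 5)
  out <- smote(x, y, seed = 3)
  expect_equal(out$features, x, ignore_attr = TRUE)
  x2 <- rbind(x, c(0, 0))
  y2 <- c(y, "d")
  expect_error(smote(x2, y2, seed = 1), "single member")
  xi <- rbind(matrix(rnorm(20), ncol = 2), matrix(rnorm(6, 4), ncol = 2))
  yi <- rep(c("a", "b"), c(10, 3))
  expect_warning(o1 <- smote(xi, yi, kNeighbors = 5, seed = 2), "shrunk")
  o2 <- suppressWarnings(smote(xi, yi, kNeighbors = 5, seed = 2))
  expect_identical(o1$features, o2$features)
})

test_that("all three model kinds reach CV accuracy 1 on separable classes", {
  withr::with_seed(11, {
    x <- rbind(matrix(rnorm(60, 0, 0.3), ncol = 3),
               matrix(rnorm(60, 4, 0.3), ncol = 3),
               matrix(rnorm(60, 8, 0.3), ncol = 3))
    colnames(x) <- c("f1", "f2", "f3")
    y <- factor(rep(c("novice", "skilled", "expert"), each = 20),
                levels = c("novice", "skilled", "expert"))
  })
  for (kind in c("linear", "svm_rbf", "random_forest")) {
    grid <- switch(kind, linear = data.frame(decay = 0.01),
                   svm_rbf = data.frame(cost = 10),
                   random_forest = data.frame(ntree = 100, maxnodes = NA))
    fit <- trainSkillModel(x, y, kind = kind, tuneGrid = grid, seed = 5)
    expect_equal(fit@cvReport$bestAccuracy, 1)
    expect_equal(as.character(predictSkill(fit, x)), as.character(y))
  }
})

test_that("permuted labels score near chance", {
  withr::with_seed(12, {
    x <- matrix(rnorm(52 * 5), ncol = 5)
    colnames(x) <- paste0("f", 1:5)
    y <- factor(rep(c("novice", "skilled", "expert"), c(18, 17, 17)))
    accs <- c()
    for (p in 1:4) {
      fit <- trainSkillModel(x, sample(y), kind = "random_forest",
                             tuneGrid = data.frame(ntree = 100,
                                                   maxnodes = NA),
                             seed = p)
      accs <- c(accs, fit@cvReport$bestAccuracy)
    }
  })
  expect_lt(abs(mean(accs) - 1 / 3), 0.15)
})

test_that("tuning never selects a grid point worse than the default", {
  withr::with_seed(21, {
    simc <- simulateMetricCohort(nPerClass = 10, separation = 1.2, seed = 4)
    grid <- data.frame(cost = c(1, 0.1, 10))
    fit <- trainSkillModel(simc$features, simc$labels, kind = "svm_rbf",
                           tuneGrid = grid, seed = 2)
    expect_gte(fit@cvReport$bestAccuracy, fit@cvReport$meanAccuracy[1])
  })
})

test_that("held-out accuracy is non-decreasing in class separation", {
  accs <- vapply(c(0.4, 1.2, 3), function(sep) {
    simc <- simulateMetricCohort(nPerClass = 18, separation = sep, seed = 31)
    test <- withr::with_seed(31, unlist(lapply(levels(simc$labels), function(cl)
      sample(which(simc$labels == cl), 4))))
    train <- setdiff(seq_len(nrow(simc$features)), test)
    fit <- trainSkillModel(simc$features[train, ], simc$labels[train],
                           kind = "random_forest",
                           tuneGrid = data.frame(ntree = 200, maxnodes = NA),
                           seed = 31)
    mean(predictSkill(fit, simc$features[test, ]) == simc$labels[test])
  }, numeric(1))
  expect_false(is.unsorted(accs))
})

test_that("prediction bookkeeping: single rows, probabilities, confusion", {
  withr::with_seed(14, {
    simc <- simulateMetricCohort(nPerClass = c(12, 12, 12), separation = 3,
                                 seed = 8)
    test <- unlist(lapply(levels(simc$labels), function(cl)
      sample(which(simc$labels == cl), 4)))
  })
  train <- setdiff(seq_len(nrow(simc$features)), test)
  fit <- trainSkillModel(simc$features[train, ], simc$labels[train],
                         kind = "random_forest",
                         tuneGrid = data.frame(ntree = 100, maxnodes = NA),
                         seed = 3)
  one <- predictSkill(fit, simc$features[test[1], , drop = FALSE])
  expect_length(one, 1)
  pred <- predictSkill(fit, simc$features[test, ])
  cmat <- confusionMatrix(simc$labels[test], pred)
  expect_equal(dim(cmat), c(3, 3))
  expect_equal(unname(rowSums(cmat)), c(4, 4, 4))
  expect_equal(rownames(cmat), c("novice", "skilled", "expert"))
  probs <- attr(pred, "probabilities")
  expect_equal(unname(rowSums(probs)), rep(1, 12), tolerance = 1e-9)
  # unlimited-depth forest interpolates its training data
  expect_equal(mean(predictSkill(fit, simc$features[train, ]) ==
                      simc$labels[train]), 1)
  expect_error(predictSkill(fit, simc$features[, 1:3]), "columns")
})

test_that("Gini importances are normalized and expose injected structure", {
  fitFor <- function(seed) {
    simc <- simulateMetricCohort(nPerClass = 15, separation = 2.5,
                                 seed = seed)
    trainSkillModel(simc$features, simc$labels, kind = "random_forest",
                    tuneGrid = data.frame(ntree = 200, maxnodes = NA),
                    seed = seed)
  }
  fit <- fitFor(2)
  imp <- featureImportance(fit)
  expect_equal(sum(imp$importance), 1, tolerance = 1e-9)
  expect_equal(imp$metric[1], "economyOfMotionMm")
  linfit <- trainSkillModel(simulateMetricCohort(seed = 2)$features,
                            simulateMetricCohort(seed = 2)$labels,
                            kind = "linear",
                            tuneGrid = data.frame(decay = 0), seed = 1)
  expect_error(featureImportance(linfit), "random forest")
  # a pure-noise feature appended to a separable cohort ranks last (median
  # over seeded runs); every real feature carries class signal here
  ranks <- vapply(1:7, function(s) {
    n <- 36
    y <- factor(rep(c("novice", "skilled", "expert"), each = 12),
                levels = c("novice", "skilled", "expert"))
    feats <- withr::with_seed(s, {
      shift <- (as.integer(y) - 2) * 2
      x <- matrix(rnorm(n * 5), n) + shift
      colnames(x) <- paste0("m", 1:5)
      cbind(as.data.frame(x), pureNoise = rnorm(n))
    })
    f <- trainSkillModel(feats, y, kind = "random_forest",
                         tuneGrid = data.frame(ntree = 150, maxnodes = NA),
                         seed = s)
    which(featureImportance(f)$metric == "pureNoise")
  }, integer(1))
  expect_gte(median(ranks), 6)
})

test_that("skill models persist and restore through the archive format", {
  simc <- simulateMetricCohort(nPerClass = 8, separation = 3, seed = 5)
  fit <- trainSkillModel(simc$features, simc$labels, kind = "random_forest",
                         tuneGrid = data.frame(ntree = 50, maxnodes = NA),
                         seed = 1)
  path <- withr::local_tempfile(fileext = ".json")
  writeSkillModel(fit, path)
  back <- readSkillModel(path)
  expect_equal(as.character(predictSkill(back, simc$features)),
               as.character(predictSkill(fit, simc$features)))
})
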