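#' @include AllClasses.R
NULL

SKILL_LEVELS <- c("novice", "skilled", "expert")

asFeatureMatrix <- function(features) {
  m <- as.matrix(features)
  storage.mode(m) <- "double"
  if (is.null(colnames(m))) colnames(m) <- paste0("f", seq_len(ncol(m)))
  m
}

#' Synthetic minority over-sampling (SMOTE)
#'
#' Equalizes class counts to the majority class by interpolated synthetic
#' minority samples: each synthetic point lies on the segment between a
#' minority sample `x` and one of its `k` nearest same-class neighbours
#' `x_nn`, at `x + u (x_nn - x)` with `u ~ Uniform(0, 1)`. Majority points
#' are never altered.
#'
#' @param features Numeric matrix/data.frame (rows = samples).
#' @param labels Factor or vector of class labels.
#' @param kNeighbors Neighbourhood size (shrunk with a warning for classes
#'   with fewer members; a single-member class cannot be over-sampled).
#' @param seed Integer seed (fixed seed, identical synthetic points).
#' @return List: `features` (matrix), `labels` (factor), original rows
#'   first.
#' @export
smote <- function(features, labels, kNeighbors = 5, seed = 1L) {
  x <- asFeatureMatrix(features)
  labels <- factor(labels)
  counts <- table(labels)
  target <- max(counts)
  newX <- list(); newY <- list()
  withSeed(seed, {
    for (cls in names(counts)) {
      need <- target - counts[[cls]]
      if (need == 0) next
      rows <- which(labels == cls)
      if (length(rows) == 1)
        stop("class '", cls, "' has a single member; SMOTE needs neighbors")
      k <- kNeighbors
      if (k > length(rows) - 1) {
        k <- length(rows) - 1
        warning("kNeighbors shrunk to ", k, " for class '", cls, "'")
      }
      sub <- x[rows, , drop = FALSE]
      dmat <- as.matrix(stats::dist(sub))
      diag(dmat) <- Inf
      nn <- t(apply(dmat, 1, function(dr) order(dr)[seq_len(k)]))
      pick <- sample(length(rows), need, replace = TRUE)
      pickNn <- nn[cbind(pick, sample(k, need, replace = TRUE))]
      u <- stats::runif(need)
      synth <- sub[pick, , drop = FALSE] +
        u * (sub[pickNn, , drop = FALSE] - sub[pick, , drop = FALSE])
      newX[[cls]] <- synth
      newY[[cls]] <- rep(cls, need)
    }
  })
  if (length(newX)) {
    x <- rbind(x, do.call(rbind, newX))
    labels <- factor(c(as.character(labels), unlist(newY)),
                     levels = levels(labels))
  }
  list(features = x, labels = labels)
}

defaultGrid <- function(kind) {
  switch(kind,
    linear = data.frame(decay = c(0, 0.01, 0.1)),
    svm_rbf = data.frame(cost = c(0.1, 1, 10, 100)),
    random_forest = expand.grid(ntree = c(50, 100, 200, 500),
                                maxnodes = c(4, 8, 32, NA)),
    stop("unknown model kind: ", kind))
}

fitOne <- function(kind, hyper, x, y, seed, final = FALSE) {
  withSeed(seed, switch(kind,
    linear = {
      df <- data.frame(x, .y = y, check.names = FALSE)
      nnet::multinom(.y ~ ., data = df, decay = hyper$decay,
                     trace = FALSE, maxit = 300)
    },
    svm_rbf = e1071::svm(x, y, kernel = "radial", cost = hyper$cost,
                         probability = final),
    random_forest = {
      args <- list(x = x, y = y, ntree = hyper$ntree, importance = final)
      if (!is.na(hyper$maxnodes)) args$maxnodes <- hyper$maxnodes
      do.call(randomForest::randomForest, args)
    }))
}

predictOne <- function(kind, model, x) {
  switch(kind,
    linear = stats::predict(model, newdata = data.frame(x, check.names = FALSE),
                            type = "class"),
    svm_rbf = stats::predict(model, x),
    random_forest = stats::predict(model, x))
}

stratifiedFolds <- function(labels, nFolds, seed) {
  folds <- integer(length(labels))
  withSeed(seed, for (cls in levels(labels)) {
    rows <- which(labels == cls)
    folds[rows] <- sample(rep_len(seq_len(nFolds), length(rows)))
  })
  folds
}

#' Train a surgical-skill classifier
#'
#' Fits a novice/skilled/expert classifier on normalized motion-metric
#' vectors: hyperparameters are selected by stratified 5-fold
#' cross-validated accuracy with SMOTE applied inside each training fold
#' only (synthetic samples must never leak into validation folds), then the
#' selected model is refit on all training data (with SMOTE).
#'
#' @param features Numeric matrix/data.frame of (normalized) metric vectors.
#' @param labels Class labels; coerced to the fixed order
#'   novice < skilled < expert when those names are used.
#' @param kind "random_forest" (Gini impurity), "svm_rbf" (Gaussian kernel,
#'   tuned regularization) or "linear" (multinomial logistic).
#' @param cvFolds Cross-validation folds (default 5; at least `cvFolds`
#'   samples per class required).
#' @param tuneGrid Optional data.frame of hyperparameter combinations; the
#'   built-in grids are cost in \{0.1, 1, 10, 100\} for the SVM and
#'   trees x depth for the forest.
#' @param smoteK SMOTE neighbourhood size.
#' @param transform Optional metric normalization transform to embed (so
#'   [predictSkill()] can take raw metric tables).
#' @param seed Integer seed.
#' @return A [SkillModelFit-class].
#' @export
trainSkillModel <- function(features, labels,
                            kind = c("random_forest", "svm_rbf", "linear"),
                            cvFolds = 5, tuneGrid = NULL, smoteK = 5,
                            transform = NULL, seed = 1L) {
  kind <- match.arg(kind)
  x <- asFeatureMatrix(features)
  labels <- if (all(unique(as.character(labels)) %in% SKILL_LEVELS))
    factor(labels, levels = SKILL_LEVELS) else factor(labels)
  labels <- droplevels(labels)
  if (nlevels(labels) < 2) stop("need at least two classes")
  if (min(table(labels)) < cvFolds)
    stop("need at least cvFolds samples per class")
  grid <- tuneGrid %||% defaultGrid(kind)
  folds <- stratifiedFolds(labels, cvFolds, seed)
  gridAcc <- matrix(NA_real_, nrow(grid), cvFolds)
  for (gi in seq_len(nrow(grid))) {
    for (f in seq_len(cvFolds)) {
      tr <- folds != f
      bal <- smote(x[tr, , drop = FALSE], labels[tr], kNeighbors = smoteK,
                   seed = seed + 17L * f)
      model <- fitOne(kind, grid[gi, , drop = FALSE], bal$features,
                      bal$labels, seed = seed + 101L * gi + f)
      pred <- predictOne(kind, model, x[!tr, , drop = FALSE])
      gridAcc[gi, f] <- mean(pred == labels[!tr])
    }
  }
  meanAcc <- rowMeans(gridAcc)
  best <- which.max(meanAcc)
  balAll <- smote(x, labels, kNeighbors = smoteK, seed = seed + 7L)
  finalModel <- fitOne(kind, grid[best, , drop = FALSE], balAll$features,
                       balAll$labels, seed = seed + 9999L, final = TRUE)
  new("SkillModelFit", kind = kind, model = finalModel,
      transform = transform, featureNames = colnames(x),
      cvReport = list(grid = grid, foldAccuracy = gridAcc,
                      meanAccuracy = meanAcc,
                      best = as.list(grid[best, , drop = FALSE]),
                      bestAccuracy = meanAcc[best], folds = folds),
      levels = levels(labels))
}

#' Predict skill classes
#'
#' @param fit A [SkillModelFit-class].
#' @param features Metric vectors; raw metric tables are normalized with the
#'   embedded transform when one is present.
#' @return Factor of predicted classes; class probabilities (when the model
#'   supports them) attached as attribute "probabilities".
#' @export
predictSkill <- function(fit, features) {
  if (!is.null(fit@transform))
    features <- applyMetricTransform(fit@transform, features)
  x <- asFeatureMatrix(features)
  if (!all(fit@featureNames %in% colnames(x)))
    stop("feature columns do not match the fitted model")
  x <- x[, fit@featureNames, drop = FALSE]
  pred <- factor(as.character(predictOne(fit@kind, fit@model, x)),
                 levels = fit@levels)
  probs <- switch(fit@kind,
    random_forest = stats::predict(fit@model, x, type = "prob"),
    linear = {
      p <- stats::predict(fit@model, newdata = data.frame(x, check.names = FALSE),
                          type = "probs")
      if (is.null(dim(p))) matrix(p, nrow = 1,
                                  dimnames = list(NULL, names(p))) else p
    },
    NULL)
  if (!is.null(probs)) attr(pred, "probabilities") <- probs
  pred
}

#' Confusion matrix in fixed class order
#' @param truth,pred Class labels.
#' @return Table with rows = truth, columns = predicted.
#' @export
confusionMatrix <- function(truth, pred) {
  lev <- if (all(unique(c(as.character(truth), as.character(pred))) %in%
               SKILL_LEVELS)) SKILL_LEVELS else
    sort(unique(c(as.character(truth), as.character(pred))))
  table(truth = factor(truth, levels = lev),
        predicted = factor(pred, levels = lev))
}

#' Gini feature importance of a fitted forest
#'
#' Mean decrease in Gini impurity per feature, normalized to sum 1 and
#' sorted descending.
#'
#' @param fit A random-forest [SkillModelFit-class].
#' @return data.frame(metric, importance).
#' @export
featureImportance <- function(fit) {
  if (fit@kind != "random_forest")
    stop("feature importance requires a random forest model")
  imp <- randomForest::importance(fit@model, type = 2)[, 1]
  imp <- imp / sum(imp)
  ord <- order(-imp)
  data.frame(metric = names(imp)[ord], importance = as.numeric(imp[ord]),
             row.names = NULL)
}

#' Persist / restore a fitted skill model
#'
#' Single-file archive (base64-encoded serialized object inside JSON, with
#' the embedded normalization transform and feature order).
#'
#' @param fit A [SkillModelFit-class].
#' @param path File path.
#' @return `writeSkillModel`: invisibly `path`; `readSkillModel`: the fit.
#' @export
writeSkillModel <- function(fit, path) {
  raw <- serialize(fit, NULL)
  jsonlite::write_json(list(format = "sitrack-model/1",
                            kind = fit@kind,
                            payload = jsonlite::base64_enc(raw)),
                       path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeSkillModel
#' @export
readSkillModel <- function(path) {
  obj <- jsonlite::fromJSON(path)
  unserialize(jsonlite::base64_dec(obj$payload))
}
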