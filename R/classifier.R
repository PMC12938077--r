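#' @include AllClasses.R
NULL

#' Hyperparameters of the stacking forest
#'
#' Defaults are the tuned optimum used by the shipped model: 703 trees,
#' maximum depth 43, minimum split size 5, minimum leaf size 1, feature
#' sampling ratio 0.23 (of the 12 features, floored to variables per
#' split), and positive class weight 4.8 (compensating the roughly
#' six-fold excess of stacked over non-stacked pairs).
#'
#' @param nTrees,maxDepth,minSplit,minLeaf,featureFraction,positiveClassWeight
#'   forest hyperparameters, see above.
#' @param seed integer RNG seed for deterministic training.
#' @return A named list.
#' @export
stackingHyperparameters <- function(nTrees = 703L, maxDepth = 43L,
                                    minSplit = 5L, minLeaf = 1L,
                                    featureFraction = 0.23,
                                    positiveClassWeight = 4.8,
                                    seed = 1L) {
  stopifnot(nTrees >= 1, maxDepth >= 1, minSplit >= 2, minLeaf >= 1,
            featureFraction > 0, featureFraction <= 1,
            positiveClassWeight > 0)
  list(nTrees = as.integer(nTrees), maxDepth = as.integer(maxDepth),
       minSplit = as.integer(minSplit), minLeaf = as.integer(minLeaf),
       featureFraction = featureFraction,
       positiveClassWeight = positiveClassWeight, seed = as.integer(seed))
}

.checkFeatureFrame <- function(features) {
  missing <- setdiff(FEATURE_NAMES, names(features))
  if (length(missing))
    stop("feature table is missing column(s): ",
         paste(missing, collapse = ", "))
  x <- features[, FEATURE_NAMES, drop = FALSE]
  if (anyNA(x)) stop("missing feature values are not allowed")
  x
}

.fitForest <- function(x, y, hp, seed = hp$seed) {
  mtry <- max(1L, floor(hp$featureFraction * ncol(x)))
  ranger::ranger(
    x = x, y = factor(y, levels = c(0L, 1L)),
    num.trees = hp$nTrees, mtry = mtry, max.depth = hp$maxDepth,
    min.node.size = hp$minSplit, min.bucket = hp$minLeaf,
    class.weights = c(1, hp$positiveClassWeight),
    probability = TRUE, importance = "impurity",
    seed = seed, num.threads = 1L)
}

#' Train the binary coaxial-stacking forest
#'
#' Fits a probability random forest on a labeled pseudo two-way junction
#' feature table with the configured class weighting. Unless a threshold
#' is pinned explicitly, the decision threshold is estimated from the
#' out-of-bag predicted probabilities of the two classes via
#' [estimateThreshold()] (KDE crossing point). Training is deterministic
#' given the seed.
#'
#' @param features data.frame containing the 12 feature columns (extra
#'   columns such as `id` are ignored).
#' @param labels integer/numeric 0-1 vector, one per row; alternatively a
#'   `label` column of `features` is used.
#' @param hp hyperparameters from [stackingHyperparameters()].
#' @param threshold optional fixed decision threshold (e.g. the published
#'   0.42 of the reference training distribution) overriding KDE
#'   estimation.
#' @param parameterVersion recorded parameter-set version string.
#' @return A [StackingModel-class].
#' @export
trainStackingForest <- function(features, labels = features$label,
                                hp = stackingHyperparameters(),
                                threshold = NULL,
                                parameterVersion = "turner2004") {
  x <- .checkFeatureFrame(features)
  labels <- as.integer(labels)
  stopifnot(length(labels) == nrow(x), !anyNA(labels))
  if (length(unique(labels)) < 2L)
    stop("training data must contain both classes")
  if (min(table(labels)) < 2L)
    stop("need at least 2 samples per class")
  fit <- .fitForest(x, labels, hp)
  oob <- fit$predictions[, "1"]
  thr <- if (is.null(threshold)) {
    ok <- !is.na(oob)
    estimateThreshold(oob[ok & labels == 1L], oob[ok & labels == 0L])
  } else threshold
  fingerprint <- sprintf("n%d-p%d-s%.6f", nrow(x), ncol(x),
                         sum(colSums(x)) %% 1e6)
  new("StackingModel", forest = fit, hyperparameters = hp,
      threshold = thr, featureNames = FEATURE_NAMES,
      trainingData = list(x = x, y = labels),
      metadata = list(nSamples = nrow(x), nPositive = sum(labels == 1L),
                      seed = hp$seed, parameterVersion = parameterVersion,
                      fingerprint = fingerprint,
                      thresholdSource = if (is.null(threshold)) "kde" else "fixed"))
}

#' KDE-based decision threshold
#'
#' Estimates Gaussian kernel densities (Silverman's rule-of-thumb
#' bandwidth) of the predicted probabilities of positive and negative
#' samples on a fixed 512-point grid over `[0, 1]` and returns the first
#' grid point, scanning upward, where the positive-class density crosses
#' above the negative-class density. If the densities never cross inside
#' (0, 1) the threshold falls back to 0.5 with a warning.
#'
#' @param posProbs,negProbs nonempty numeric vectors of predicted
#'   probabilities for positive and negative samples.
#' @param gridSize number of evaluation points (default 512).
#' @return Threshold probability in (0, 1).
#' @export
estimateThreshold <- function(posProbs, negProbs, gridSize = 512L) {
  if (!length(posProbs) || !length(negProbs))
    stop("both probability vectors must be nonempty")
  bwOf <- function(x) {
    bw <- tryCatch(stats::bw.nrd0(x), error = function(e) NA_real_)
    if (!is.finite(bw) || bw <= 0) 0.05 else bw
  }
  dp <- density(posProbs, bw = bwOf(posProbs), from = 0, to = 1, n = gridSize)
  dn <- density(negProbs, bw = bwOf(negProbs), from = 0, to = 1, n = gridSize)
  diffp <- dp$y - dn$y
  cross <- which(diffp[-1] > 0 & diffp[-length(diffp)] <= 0) + 1L
  cross <- cross[dp$x[cross] > 0 & dp$x[cross] < 1]
  if (!length(cross)) {
    warning("probability densities do not cross; falling back to 0.5")
    return(0.5)
  }
  dp$x[cross[1]]
}

#' Predict stacking probabilities for pseudo two-way junctions
#'
#' @param model a [StackingModel-class].
#' @param features data.frame containing the model's 12 feature columns
#'   (order is reconciled by name; missing columns are an error).
#' @return data.frame with `pair_id`, `probability` and binary `label`
#'   (`probability > threshold(model)`); zero rows for empty input.
#' @export
predictStacking <- function(model, features) {
  stopifnot(is(model, "StackingModel"))
  if (!nrow(features))
    return(data.frame(pair_id = character(0), probability = numeric(0),
                      label = integer(0), stringsAsFactors = FALSE))
  missing <- setdiff(model@featureNames, names(features))
  if (length(missing))
    stop("feature-order mismatch: missing column(s) ",
         paste(missing, collapse = ", "))
  x <- features[, model@featureNames, drop = FALSE]
  if (anyNA(x)) stop("missing feature values are not allowed")
  p <- predict(model@forest, data = x, num.threads = 1L,
               seed = model@hyperparameters$seed)$predictions[, "1"]
  ids <- if ("id" %in% names(features)) features$id
         else as.character(seq_len(nrow(features)))
  data.frame(pair_id = ids, probability = as.numeric(p),
             label = as.integer(p > model@threshold),
             stringsAsFactors = FALSE)
}

#' Split-based feature importances
#'
#' `"gini"` returns the impurity-decrease importances of the trained
#' forest. `"information_gain"` trains a criterion-specific bagged
#' ensemble of entropy-split trees on the stored training data (bootstrap
#' resampling, same depth/size constraints) and aggregates their
#' information-gain importances. Both are normalized to sum to 1 and
#' returned in decreasing order.
#'
#' @param model a [StackingModel-class].
#' @param criterion `"gini"` or `"information_gain"`.
#' @param nTrees ensemble size for the information-gain ensemble.
#' @return Named numeric vector over the 12 features, decreasing.
#' @export
featureImportances <- function(model, criterion = c("gini", "information_gain"),
                               nTrees = 200L) {
  stopifnot(is(model, "StackingModel"))
  criterion <- match.arg(criterion)
  if (criterion == "gini") {
    imp <- model@forest$variable.importance
  } else {
    x <- model@trainingData$x
    y <- model@trainingData$y
    hp <- model@hyperparameters
    set.seed(hp$seed)
    imp <- setNames(numeric(length(model@featureNames)), model@featureNames)
    dat <- cbind(x, .label = factor(y, levels = c(0L, 1L)))
    for (b in seq_len(nTrees)) {
      idx <- sample.int(nrow(dat), replace = TRUE)
      fit <- rpart::rpart(.label ~ ., data = dat[idx, ],
                          method = "class",
                          parms = list(split = "information"),
                          control = rpart::rpart.control(
                            minsplit = hp$minSplit, minbucket = hp$minLeaf,
                            maxdepth = min(30L, hp$maxDepth), cp = 0,
                            xval = 0))
      vi <- fit$variable.importance
      if (!is.null(vi)) imp[names(vi)] <- imp[names(vi)] + vi
    }
  }
  full <- setNames(numeric(length(model@featureNames)), model@featureNames)
  full[names(imp)] <- pmax(imp, 0)
  if (sum(full) > 0) full <- full / sum(full)
  sort(full, decreasing = TRUE)
}

# stratified, seeded fold assignment
.stratifiedFolds <- function(labels, k, seed) {
  set.seed(seed)
  folds <- integer(length(labels))
  for (cls in unique(labels)) {
    idx <- which(labels == cls)
    folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  folds
}

#' Cross-validated performance of the stacking forest
#'
#' Stratified k-fold cross-validation (seeded) returning per-fold AUC and
#' accuracy. Used as the objective of the hyperparameter search and by the
#' ablation analysis.
#'
#' @param features feature table with the 12 columns.
#' @param labels 0-1 labels.
#' @param hp hyperparameters.
#' @param folds number of folds (default 10).
#' @param seed fold-assignment seed.
#' @param threshold probability cutoff for the accuracy metric.
#' @return list with `auc`, `accuracy` (means) and `perFold` data.frame.
#' @export
crossValidateForest <- function(features, labels = features$label,
                                hp = stackingHyperparameters(), folds = 10L,
                                seed = hp$seed, threshold = 0.5) {
  x <- .checkFeatureFrame(features)
  labels <- as.integer(labels)
  fold <- .stratifiedFolds(labels, folds, seed)
  per <- lapply(seq_len(folds), function(f) {
    tr <- fold != f; te <- fold == f
    if (length(unique(labels[tr])) < 2L || !any(te))
      return(c(auc = NA_real_, accuracy = NA_real_))
    fit <- .fitForest(x[tr, , drop = FALSE], labels[tr], hp,
                      seed = hp$seed + f)
    p <- predict(fit, data = x[te, , drop = FALSE],
                 num.threads = 1L)$predictions[, "1"]
    auc <- if (length(unique(labels[te])) < 2L) NA_real_ else
      as.numeric(pROC::auc(pROC::roc(labels[te], p, quiet = TRUE,
                                     direction = "<", levels = c(0, 1))))
    c(auc = auc, accuracy = mean((p > threshold) == (labels[te] == 1L)))
  })
  per <- as.data.frame(do.call(rbind, per))
  list(auc = mean(per$auc, na.rm = TRUE),
       accuracy = mean(per$accuracy, na.rm = TRUE), perFold = per)
}

#' Feature-ablation cross-validation run
#'
#' Repeats the cross-validation of [crossValidateForest()] with the named
#' feature columns removed, using the same seeded fold assignment as the
#' unablated run so fold-wise accuracies are directly comparable.
#'
#' @param features feature table with the 12 columns.
#' @param labels 0-1 labels.
#' @param drop character vector of feature names to remove (empty vector
#'   reproduces the baseline run).
#' @param hp,folds,seed,threshold as in [crossValidateForest()].
#' @return list with `mean` accuracy, `auc`, `perFold`, and `dropped`.
#' @export
ablationRun <- function(features, labels = features$label,
                        drop = character(0),
                        hp = stackingHyperparameters(), folds = 10L,
                        seed = hp$seed, threshold = 0.5) {
  drop <- as.character(drop)
  unknown <- setdiff(drop, FEATURE_NAMES)
  if (length(unknown))
    stop("cannot drop unknown feature(s): ", paste(unknown, collapse = ", "))
  keep <- setdiff(FEATURE_NAMES, drop)
  if (!length(keep)) stop("cannot drop all features")
  x <- .checkFeatureFrame(features)[, keep, drop = FALSE]
  labels <- as.integer(labels)
  fold <- .stratifiedFolds(labels, folds, seed)
  per <- vapply(seq_len(folds), function(f) {
    tr <- fold != f; te <- fold == f
    fit <- .fitForest(x[tr, , drop = FALSE], labels[tr], hp,
                      seed = hp$seed + f)
    p <- predict(fit, data = x[te, , drop = FALSE],
                 num.threads = 1L)$predictions[, "1"]
    mean((p > threshold) == (labels[te] == 1L))
  }, numeric(1))
  list(mean = mean(per), perFold = per, dropped = drop)
}

#' Save / load a trained stacking model
#'
#' Single-file serialization of the model object (forest, hyperparameters,
#' threshold, feature order, parameter-set version and training-data
#' fingerprint). `readStackingModel` refuses files that do not contain a
#' [StackingModel-class] with the expected feature order.
#'
#' @param model a [StackingModel-class].
#' @param path file path.
#' @return `readStackingModel` returns the model; `saveStackingModel` the
#'   path, invisibly.
#' @export
saveStackingModel <- function(model, path) {
  stopifnot(is(model, "StackingModel"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname saveStackingModel
#' @export
readStackingModel <- function(path) {
  model <- readRDS(path)
  if (!is(model, "StackingModel"))
    stop("file does not contain a StackingModel")
  if (!identical(model@featureNames, FEATURE_NAMES))
    stop("incompatible feature order in serialized model")
  model
}
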