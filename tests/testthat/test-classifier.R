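# shared small synthetic corpus for the classifier tests (kept modest so
# the suite stays fast; the acceptance run uses the full settings)
classifierFixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- syntheticConfig(nJunctions = 350, seed = 2024)
      cache <<- generateDataset(cfg)
    }
    cache
  }
})

smallHp <- function(seed = 7L, ...)
  stackingHyperparameters(nTrees = 120L, seed = seed, ...)

test_that("training produces a deterministic, threshold-consistent model", {
  d <- classifierFixture()
  m <- trainStackingForest(d$features, hp = smallHp())
  expect_s4_class(m, "StackingModel")
  expect_length(featureNames(m), 12)
  expect_true(threshold(m) > 0 && threshold(m) < 1)

  p1 <- predictStacking(m, d$features)
  p2 <- predictStacking(m, d$features)
  expect_identical(p1, p2)
  # label/threshold consistency invariant
  expect_identical(p1$label, as.integer(p1$probability > threshold(m)))

  # retraining with the same seed reproduces the predictions bitwise
  m2 <- trainStackingForest(d$features, hp = smallHp())
  expect_identical(predictStacking(m2, d$features), p1)

  # planted stacked pairs score higher on average than unstacked ones
  expect_gt(mean(p1$probability[d$features$label == 1]),
            mean(p1$probability[d$features$label == 0]) + 0.2)

  expect_identical(nrow(predictStacking(m, d$features[0, ])), 0L)
  expect_error(predictStacking(m, d$features[, -which(names(d$features) == "L0")]),
               "feature-order mismatch")
  expect_error(trainStackingForest(d$features[, -3],
                                   labels = d$features$label, hp = smallHp()),
               "missing column")
  one <- d$features[d$features$label == 1, ]
  expect_error(trainStackingForest(one, hp = smallHp()), "both classes")
})

test_that("default hyperparameters are the tuned optimum and are validated", {
  hp <- stackingHyperparameters()
  expect_identical(hp[c("nTrees", "maxDepth", "minSplit", "minLeaf")],
                   list(nTrees = 703L, maxDepth = 43L, minSplit = 5L,
                        minLeaf = 1L))
  expect_equal(hp$featureFraction, 0.23)
  expect_equal(hp$positiveClassWeight, 4.8)
  expect_error(stackingHyperparameters(featureFraction = 0), "featureFraction")
})

test_that("the KDE threshold sits at the density crossing", {
  # well-separated classes: a single upward crossing strictly between them
  thr <- estimateThreshold(rep(0.9, 60), rep(0.1, 60))
  expect_true(thr > 0.1 && thr < 0.9)

  # dense-grid oracle: recompute both densities and count upward crossings
  bw <- function(x) {
    b <- tryCatch(stats::bw.nrd0(x), error = function(e) NA)
    if (!is.finite(b) || b <= 0) 0.05 else b
  }
  dp <- density(rep(0.9, 60), bw = bw(rep(0.9, 60)), from = 0, to = 1, n = 512)
  dn <- density(rep(0.1, 60), bw = bw(rep(0.1, 60)), from = 0, to = 1, n = 512)
  dd <- dp$y - dn$y
  ups <- which(dd[-1] > 0 & dd[-length(dd)] <= 0) + 1L
  expect_length(ups, 1)
  expect_equal(thr, dp$x[ups])

  # overlapping unimodal classes cross between the two modes
  set.seed(8)
  pos <- pmin(pmax(rnorm(300, 0.7, 0.12), 0), 1)
  neg <- pmin(pmax(rnorm(300, 0.3, 0.12), 0), 1)
  thr2 <- estimateThreshold(pos, neg)
  expect_true(thr2 > 0.3 && thr2 < 0.7)

  # identical distributions: no informative crossing, fallback 0.5
  expect_warning(thr3 <- estimateThreshold(rep(0.4, 30), rep(0.4, 30)),
                 "do not cross")
  expect_equal(thr3, 0.5)
  expect_error(estimateThreshold(numeric(0), c(0.1)), "nonempty")
})

test_that("feature importances are normalized and rank the planted drivers", {
  d <- classifierFixture()
  m <- trainStackingForest(d$features, hp = smallHp())
  for (crit in c("gini", "information_gain")) {
    imp <- featureImportances(m, crit, nTrees = 40L)
    expect_length(imp, 12)
    expect_equal(sum(imp), 1, tolerance = 1e-9)
    expect_true(all(diff(imp) <= 0))
    # the planted rule is driven by L0 and its energy surrogate
    expect_true(names(imp)[1] %in% c("L0", "dG_coax"))
  }

  # a feature that never varies gets zero importance: all two-way
  # junctions make N identically zero
  cfg2 <- syntheticConfig(nJunctions = 150, orderWeights = c("2" = 1),
                          seed = 31)
  d2 <- generateDataset(cfg2)
  expect_true(all(d2$features$N == 0))
  m2 <- trainStackingForest(d2$features, hp = smallHp())
  expect_equal(unname(featureImportances(m2, "gini")[["N"]]), 0)
})

test_that("ablation uses paired folds and degrades informative drops only", {
  d <- classifierFixture()
  base <- ablationRun(d$features, drop = character(0), hp = smallHp(),
                      folds = 5)
  cv <- crossValidateForest(d$features, hp = smallHp(), folds = 5)
  # dropping nothing reproduces the baseline fold accuracies exactly
  expect_equal(unname(base$perFold), cv$perFold$accuracy)

  informative <- ablationRun(d$features, drop = c("L0", "dG_coax", "A_L0"),
                             hp = smallHp(), folds = 5)
  noise <- ablationRun(d$features, drop = "A_L1", hp = smallHp(), folds = 5)
  expect_lt(informative$mean, base$mean - 0.02)
  expect_lt(abs(noise$mean - base$mean), 0.05)
  expect_error(ablationRun(d$features, drop = "nope", hp = smallHp()),
               "unknown feature")
  expect_error(ablationRun(d$features, drop = coaxStackR:::FEATURE_NAMES,
                           hp = smallHp()), "all features")
})

test_that("raising the positive class weight does not lower recall", {
  d <- classifierFixture()
  n <- nrow(d$features)
  set.seed(19)
  test <- sample.int(n, round(0.3 * n))
  train <- setdiff(seq_len(n), test)
  recalls <- vapply(c(0.5, 1, 4.8, 10), function(w) {
    hp <- smallHp(positiveClassWeight = w)
    m <- trainStackingForest(d$features[train, ], hp = hp, threshold = 0.5)
    p <- predictStacking(m, d$features[test, ])
    truth <- d$features$label[test]
    sum(p$label == 1 & truth == 1) / sum(truth == 1)
  }, numeric(1))
  expect_true(all(diff(recalls) >= -0.01))  # monotone up to bootstrap noise
})

test_that("higher L0 never raises the average predicted stacking probability", {
  d <- classifierFixture()
  params <- turnerParameters()
  probeRow <- function(L0) {
    data.frame(L0 = L0, L1 = 2, L2 = 2, A_L0 = 0, A_L1 = 0, A_L2 = 0,
               L_H1 = 4, L_H2 = 4, N = 0,
               dG_H1 = -5, dG_H2 = -5,
               dG_coax = coaxialStackEnergy(NULL, params,
                                            L0 = max(L0, 2)))
  }
  trend <- vapply(1:3, function(s) {
    m <- trainStackingForest(d$features,
                             hp = smallHp(seed = s))
    probs <- vapply(0:10, function(L) {
      row <- probeRow(L)
      if (L == 0) row$dG_coax <- -2.5
      if (L == 1) row$dG_coax <- 0
      predictStacking(m, row)$probability
    }, numeric(1))
    mean(probs[1:2]) - mean(probs[10:11])
  }, numeric(1))
  expect_true(all(trend >= 0))
})

test_that("models serialize to a single validated artifact", {
  d <- classifierFixture()
  m <- trainStackingForest(d$features, hp = smallHp())
  path <- withr::local_tempfile(fileext = ".rds")
  saveStackingModel(m, path)
  m2 <- readStackingModel(path)
  expect_identical(predictStacking(m2, d$features[1:20, ]),
                   predictStacking(m, d$features[1:20, ]))
  bad <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(1, 2), bad)
  expect_error(readStackingModel(bad), "StackingModel")
})

test_that("the hyperparameter search is seeded and finds better regions", {
  d <- classifierFixture()
  feats <- d$features[1:250, ]

  # collapsed space: the single point is returned unchanged
  res <- bayesOptimize(feats, space = list(nTrees = c(40, 40)),
                       nInit = 2, nIter = 1, folds = 3, seed = 5)
  expect_identical(res$best$nTrees, 40L)

  # determinism: the full trajectory repeats under the same seed
  sp <- list(minLeaf = c(1, 60), featureFraction = c(0.1, 0.9))
  r1 <- bayesOptimize(feats, space = sp, nInit = 3, nIter = 3, folds = 3,
                      seed = 11)
  r2 <- bayesOptimize(feats, space = sp, nInit = 3, nIter = 3, folds = 3,
                      seed = 11)
  expect_identical(r1$trace, r2$trace)

  # a grossly oversized leaf constraint scores worse than the optimum the
  # search returns (exhaustive check of the bad endpoint)
  badHp <- stackingHyperparameters(minLeaf = 60L, seed = 11)
  badCv <- crossValidateForest(feats, hp = badHp, folds = 3, seed = 11)
  expect_gte(r1$score, badCv$auc)
  expect_lt(r1$best$minLeaf, 60L)

  expect_error(bayesOptimize(feats, space = list(minLeaf = c(5, 1))),
               "degenerate")
  expect_error(bayesOptimize(feats, space = list(bogus = c(1, 2))),
               "unknown hyperparameter")
})
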