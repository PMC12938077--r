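#' @include classifier.R
NULL

# squared-exponential GP posterior on [0,1]^d inputs
.gpPosterior <- function(X, y, Xnew, lengthscale = 0.2, nugget = 1e-6) {
  kfun <- function(A, B) {
    d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
    exp(-0.5 * pmax(d2, 0) / lengthscale^2)
  }
  mu <- mean(y); sdy <- sd(y); if (!is.finite(sdy) || sdy == 0) sdy <- 1
  ys <- (y - mu) / sdy
  K <- kfun(X, X) + diag(nugget, nrow(X))
  Ks <- kfun(Xnew, X)
  alpha <- solve(K, ys)
  pm <- as.vector(Ks %*% alpha)
  pv <- pmax(1 + nugget - rowSums((Ks %*% solve(K)) * Ks), 1e-12)
  list(mean = pm * sdy + mu, sd = sqrt(pv) * sdy)
}

.expectedImprovement <- function(mean, sd, best) {
  z <- (mean - best) / sd
  (mean - best) * pnorm(z) + sd * dnorm(z)
}

#' Gaussian-process hyperparameter search for the stacking forest
#'
#' Sequential model-based optimization of the six forest hyperparameters
#' (number of trees, maximum depth, minimum split size, minimum leaf size,
#' feature sampling ratio, positive class weight): a seeded batch of
#' random initial configurations, then guided iterations in which a
#' Gaussian-process surrogate (squared-exponential kernel on the unit
#' cube) is fit to the cross-validated scores and the expected-improvement
#' acquisition is maximized over a random candidate pool. The objective is
#' the mean stratified 10-fold cross-validation AUC by default.
#'
#' @param features,labels labeled feature table as in
#'   [trainStackingForest()].
#' @param space named list of `c(lower, upper)` ranges for any subset of
#'   `nTrees`, `maxDepth`, `minSplit`, `minLeaf`, `featureFraction`,
#'   `positiveClassWeight`; unlisted parameters stay at their defaults.
#'   Integer-valued parameters are rounded.
#' @param nInit random initializations (default 5).
#' @param nIter guided iterations (default 10).
#' @param folds cross-validation folds (default 10).
#' @param seed RNG seed; the whole trajectory is deterministic given it.
#' @param metric `"auc"` (default) or `"accuracy"`.
#' @param candidatePool random candidates scored per guided iteration.
#' @return list: `best` ([stackingHyperparameters()] list), `score`, and
#'   the evaluation `trace` data.frame.
#' @export
bayesOptimize <- function(features, labels = features$label, space,
                          nInit = 5L, nIter = 10L, folds = 10L, seed = 1L,
                          metric = c("auc", "accuracy"),
                          candidatePool = 200L) {
  metric <- match.arg(metric)
  stopifnot(folds >= 2L, is.list(space), length(space) >= 1L)
  intPars <- c("nTrees", "maxDepth", "minSplit", "minLeaf")
  allowed <- c(intPars, "featureFraction", "positiveClassWeight")
  if (!all(names(space) %in% allowed))
    stop("unknown hyperparameter(s) in space: ",
         paste(setdiff(names(space), allowed), collapse = ", "))
  for (nm in names(space)) {
    r <- space[[nm]]
    if (length(r) != 2L || r[1] > r[2]) stop("degenerate range for ", nm)
  }
  pars <- names(space)
  lo <- vapply(space, `[`, numeric(1), 1)
  hi <- vapply(space, `[`, numeric(1), 2)
  span <- ifelse(hi > lo, hi - lo, 1)

  toHp <- function(u) {  # u in [0,1]^d
    vals <- lo + u * (hi - lo)
    args <- as.list(vals)
    names(args) <- pars
    for (nm in intersect(pars, intPars)) args[[nm]] <- round(args[[nm]])
    if ("minSplit" %in% pars) args$minSplit <- max(2, args$minSplit)
    do.call(stackingHyperparameters, c(args, list(seed = seed)))
  }
  score <- function(hp) {
    cv <- crossValidateForest(features, labels, hp = hp, folds = folds,
                              seed = seed)
    cv[[metric]]
  }

  set.seed(seed)
  d <- length(pars)
  U <- matrix(runif(nInit * d), ncol = d)
  evals <- lapply(seq_len(nInit), function(i) {
    hp <- toHp(U[i, ])
    list(u = U[i, ], hp = hp, y = score(hp))
  })
  for (it in seq_len(nIter)) {
    X <- do.call(rbind, lapply(evals, `[[`, "u"))
    y <- vapply(evals, `[[`, numeric(1), "y")
    cand <- matrix(runif(candidatePool * d), ncol = d)
    if (sd(y) == 0) {
      pick <- cand[1, ]
    } else {
      post <- .gpPosterior(X, y, cand)
      ei <- .expectedImprovement(post$mean, post$sd, max(y))
      pick <- cand[which.max(ei), ]
    }
    hp <- toHp(pick)
    evals[[length(evals) + 1L]] <- list(u = pick, hp = hp, y = score(hp))
  }
  ys <- vapply(evals, `[[`, numeric(1), "y")
  best <- evals[[which.max(ys)]]
  trace <- data.frame(eval = seq_along(ys), score = ys)
  for (k in seq_along(pars))
    trace[[pars[k]]] <- vapply(evals, function(e) e$hp[[pars[k]]], numeric(1))
  list(best = best$hp, score = best$y, trace = trace)
}
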