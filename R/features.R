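#' @include AllClasses.R
NULL

#' Consecutive-adenine statistic of a loop sequence
#'
#' Default (`"longest-run"`) returns the length of the longest run of
#' consecutive adenines, the reading used throughout the package (A-runs,
#' not isolated A's, are what stabilize loop geometry). Two alternative
#' interpretations are exposed: `"run-total"` counts adenines belonging to
#' runs of length >= 2, and `"count"` is the plain adenine count.
#'
#' @param loopSeq loop sequence over A/C/G/U (possibly empty).
#' @param mode interpretation, see above.
#' @return Integer count.
#' @examples
#' consecutiveAdenines("GAAUAAAC")  # 3
#' @export
consecutiveAdenines <- function(loopSeq,
                                mode = c("longest-run", "run-total", "count")) {
  mode <- match.arg(mode)
  stopifnot(is.character(loopSeq), length(loopSeq) == 1L)
  if (grepl("[^ACGU]", loopSeq))
    stop("loop sequence contains characters outside A/C/G/U")
  if (!nzchar(loopSeq)) return(0L)
  chars <- strsplit(loopSeq, "", fixed = TRUE)[[1]]
  r <- rle(chars == "A")
  runs <- r$lengths[r$values]
  switch(mode,
         "longest-run" = if (length(runs)) max(runs) else 0L,
         "run-total" = sum(runs[runs >= 2L]),
         "count" = sum(runs))
}

#' Extract the 12-dimensional feature vector of a pseudo two-way junction
#'
#' Features, in fixed serialization order: loop lengths `L0`, `L1`, `L2`
#' (nt); consecutive-adenine statistics `A_L0`, `A_L1`, `A_L2`; stem
#' lengths `L_H1`, `L_H2` (bp); intervening stem count `N` (= parent order
#' minus 2); helix free energies `dG_H1`, `dG_H2` and the coaxial interface
#' energy `dG_coax` (kcal/mol). The function is pure: identical input gives
#' identical output.
#'
#' @param pair a [PseudoTwoWayJunction-class].
#' @param params a [TurnerParameters-class].
#' @param adenineMode passed to [consecutiveAdenines()].
#' @return Named numeric vector of length 12.
#' @export
extractFeatures <- function(pair, params, adenineMode = "longest-run") {
  stopifnot(is(pair, "PseudoTwoWayJunction"), is(params, "TurnerParameters"))
  v <- c(L0 = nchar(pair@loop0),
         L1 = nchar(pair@loop1),
         L2 = nchar(pair@loop2),
         A_L0 = consecutiveAdenines(pair@loop0, adenineMode),
         A_L1 = consecutiveAdenines(pair@loop1, adenineMode),
         A_L2 = consecutiveAdenines(pair@loop2, adenineMode),
         L_H1 = nrow(pair@h1@pairs),
         L_H2 = nrow(pair@h2@pairs),
         N = pair@nIntervening,
         dG_H1 = unname(helixFreeEnergy(pair@h1, params)[["total"]]),
         dG_H2 = unname(helixFreeEnergy(pair@h2, params)[["total"]]),
         dG_coax = coaxialStackEnergy(pair, params))
  stopifnot(identical(names(v), FEATURE_NAMES))
  v
}

#' Build a feature table from pseudo two-way junctions
#'
#' @param pairs list of [PseudoTwoWayJunction-class] objects.
#' @param params a [TurnerParameters-class].
#' @param adenineMode passed to [consecutiveAdenines()].
#' @return A data.frame with `id`, `parent_order`, the 12 feature columns
#'   and `label` (NA where unknown).
#' @export
featureTable <- function(pairs, params, adenineMode = "longest-run") {
  if (!length(pairs)) {
    out <- as.data.frame(setNames(
      c(list(character(0), integer(0)),
        rep(list(numeric(0)), 12), list(integer(0))),
      c("id", "parent_order", FEATURE_NAMES, "label")))
    return(out)
  }
  mat <- t(vapply(pairs, extractFeatures, numeric(12),
                  params = params, adenineMode = adenineMode))
  out <- data.frame(id = vapply(pairs, function(p) p@id, character(1)),
                    parent_order = vapply(pairs, function(p) p@parentOrder,
                                          integer(1)),
                    mat,
                    label = vapply(pairs, function(p) p@label, integer(1)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Cosine similarity between two feature vectors
#'
#' Standard cosine of the two 12-vectors. Because the raw features mix
#' units (nucleotides, base pairs, kcal/mol), similarity searches against a
#' training set should standardize first; `center`/`scale` apply a z-score
#' with the supplied (training-set) statistics before the cosine.
#'
#' @param u,v numeric vectors of equal length.
#' @param center,scale optional numeric vectors of per-feature mean and
#'   standard deviation used to standardize both inputs.
#' @return Similarity in `[-1, 1]`.
#' @export
featureCosineSimilarity <- function(u, v, center = NULL, scale = NULL) {
  stopifnot(length(u) == length(v))
  u <- as.numeric(u); v <- as.numeric(v)
  if (!is.null(center)) { u <- u - center; v <- v - center }
  if (!is.null(scale)) {
    s <- ifelse(is.finite(scale) & scale > 0, scale, 1)
    u <- u / s; v <- v / s
  }
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("zero-norm feature vector")
  sum(u * v) / (nu * nv)
}

#' Rank training samples by feature similarity to a query
#'
#' Computes the cosine similarity (Fs) between a query feature vector and
#' every row of a training feature table after z-scoring both with the
#' training-set mean and standard deviation, and returns the top `k` in
#' descending similarity (ties broken by sample id for determinism).
#'
#' @param query named numeric feature vector (the 12 features).
#' @param trainingSet data.frame containing the 12 feature columns and an
#'   `id` column (as produced by [featureTable()]).
#' @param k number of neighbors to return; if larger than the training set
#'   all samples are returned with a warning.
#' @param standardize z-score with training statistics (default TRUE).
#' @return data.frame with `id` and `Fs`, ordered by decreasing `Fs`.
#' @export
rankSimilarTrainingSamples <- function(query, trainingSet, k = 5L,
                                       standardize = TRUE) {
  stopifnot(k >= 1L, nrow(trainingSet) >= 1L,
            all(FEATURE_NAMES %in% names(trainingSet)))
  X <- as.matrix(trainingSet[, FEATURE_NAMES])
  q <- as.numeric(query[FEATURE_NAMES])
  standardize <- standardize && nrow(X) >= 2L  # a 1-row set has no spread
  ctr <- if (standardize) colMeans(X) else NULL
  scl <- if (standardize) apply(X, 2, sd) else NULL
  fs <- vapply(seq_len(nrow(X)), function(i)
    featureCosineSimilarity(q, X[i, ], center = ctr, scale = scl), numeric(1))
  ids <- if ("id" %in% names(trainingSet)) trainingSet$id
         else as.character(seq_len(nrow(X)))
  if (k > nrow(X)) {
    warning("k exceeds training-set size; returning all samples")
    k <- nrow(X)
  }
  ord <- order(-fs, ids)
  data.frame(id = ids[ord][seq_len(k)], Fs = fs[ord][seq_len(k)],
             stringsAsFactors = FALSE)
}
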