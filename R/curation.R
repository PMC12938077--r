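#' @include dotbracket.R
NULL

# dot-bracket alphabet mapped to plain letters so a custom substitution
# matrix can drive the global alignment
.DB_MAP <- c("." = "L", "(" = "P", ")" = "Q")

.dbSubstitutionMatrix <- function(match, mismatch) {
  m <- matrix(mismatch, 3, 3, dimnames = list(.DB_MAP, .DB_MAP))
  diag(m) <- match
  m
}

#' Needleman-Wunsch similarity of two dot-bracket strings
#'
#' Globally aligns the two structures at the secondary-structure level
#' with the scoring +2 for matches, -1 for mismatches and -2 per gap
#' (linear), and returns the fraction of identical aligned positions. The
#' default denominator is the alignment length (gap columns count
#' against similarity); `denominator = "shorter"` divides by the shorter
#' input length instead.
#'
#' @param s1,s2 nonempty dot-bracket strings over `.`, `(`, `)`.
#' @param match,mismatch,gap alignment scores.
#' @param denominator `"alignment"` (default) or `"shorter"`.
#' @return list: `similarity` fraction in `[0, 1]`, raw NW `score`, and
#'   alignment `length`.
#' @examples
#' dotBracketSimilarity("((..))", "((..))")$similarity  # 1
#' @export
dotBracketSimilarity <- function(s1, s2, match = 2, mismatch = -1, gap = -2,
                                 denominator = c("alignment", "shorter")) {
  denominator <- match.arg(denominator)
  stopifnot(is.character(s1), is.character(s2), nzchar(s1), nzchar(s2))
  if (grepl("[^.()]", s1) || grepl("[^.()]", s2))
    stop("structures must be over '.', '(', ')'")
  t1 <- chartr(".()", "LPQ", s1)
  t2 <- chartr(".()", "LPQ", s2)
  aln <- Biostrings::pairwiseAlignment(
    t1, t2, type = "global",
    substitutionMatrix = .dbSubstitutionMatrix(match, mismatch),
    gapOpening = 0, gapExtension = -gap)
  p <- as.character(Biostrings::alignedPattern(aln))
  alnLen <- nchar(p)
  matches <- Biostrings::nmatch(aln)
  denom <- if (denominator == "alignment") alnLen
           else min(nchar(s1), nchar(s2))
  list(similarity = matches / denom, score = BiocGenerics::score(aln),
       length = alnLen)
}

#' Collapse structurally redundant junction records
#'
#' Greedy single-linkage grouping: records whose dot-bracket structures
#' share pairwise similarity strictly above the cutoff fall in one group,
#' and only one representative per group is retained (the lexicographically
#' smallest id, which makes the outcome independent of input order). Note
#' that under single linkage a chain A~B~C collapses to one representative
#' even when A and C are themselves dissimilar.
#'
#' @param records list of [DotBracketRecord-class] objects.
#' @param cutoff similarity threshold in (0, 1], default 0.90.
#' @param ... alignment scores passed to [dotBracketSimilarity()].
#' @return The retained sublist, in original input order.
#' @export
redundancyFilter <- function(records, cutoff = 0.90, ...) {
  stopifnot(cutoff > 0, cutoff <= 1)
  n <- length(records)
  if (n <= 1L) return(records)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    sim <- dotBracketSimilarity(records[[i]]@structure,
                                records[[j]]@structure, ...)$similarity
    if (sim > cutoff) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  groups <- vapply(seq_len(n), find, integer(1))
  ids <- vapply(records, function(r) r@id, character(1))
  keep <- vapply(split(seq_len(n), groups), function(members)
    members[which.min(rank(ids[members], ties.method = "first"))],
    integer(1))
  records[sort(keep)]
}

#' Stratified train/test split of junction records
#'
#' Splits records per junction order at the requested training fraction
#' (seeded, reproducible). Orders with at most `rareOrderMax` members are
#' routed wholly to the test set when `rareToTest` is on, so that scarce
#' complex topologies are used to probe generalization rather than being
#' memorized.
#'
#' @param records list (any type).
#' @param orders integer vector of junction orders, one per record.
#' @param fraction training fraction in (0, 1), default 0.85.
#' @param seed RNG seed.
#' @param rareToTest route rare orders wholly to test (default TRUE).
#' @param rareOrderMax maximum class size considered rare (default 3).
#' @return list with `train` and `test` index vectors (disjoint, covering
#'   all records).
#' @export
splitDataset <- function(records, orders, fraction = 0.85, seed = 1L,
                         rareToTest = TRUE, rareOrderMax = 3L) {
  stopifnot(length(records) > 0, length(orders) == length(records),
            fraction > 0, fraction < 1)
  set.seed(seed)
  train <- integer(0); test <- integer(0)
  for (o in sort(unique(orders))) {
    idx <- which(orders == o)
    if (rareToTest && length(idx) <= rareOrderMax) {
      test <- c(test, idx)
      next
    }
    nTrain <- round(fraction * length(idx))
    tr <- sort(sample(idx, nTrain))
    train <- c(train, tr)
    test <- c(test, setdiff(idx, tr))
  }
  list(train = sort(train), test = sort(test))
}
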