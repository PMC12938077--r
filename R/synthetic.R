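#' @include features.R
NULL

#' Configuration for the synthetic junction generator
#'
#' The generator emulates the composition of a PDB-derived junction
#' corpus: the default order distribution is proportional to the curated
#' counts of two- to seven-way junctions in such a corpus (960, 87, 91,
#' 15, 1, 3), stems are 2-8 bp random canonical duplexes with 10% GU
#' substitution, and connecting loops are short-heavy (geometrically
#' decaying lengths over 0-8 nt), so that all branches of the coaxial
#' energy function are exercised. Stacking labels follow a planted rule:
#' the log-odds of stacking decrease linearly with the connecting loop
#' length and with less favorable coaxial stacking energy,
#' `logit P(stack) = alpha - betaL0 * L0 - betaCoax * dG_coax`, optionally
#' corrupted by symmetric label noise. The intercept `alpha` is calibrated
#' by [generateDataset()] so that the planted per-pair label balance
#' meets `classBalanceTarget` (default 6 stacked : 1 unstacked, the
#' approximate imbalance of junction corpora).
#'
#' @param nJunctions number of junctions to generate.
#' @param orderWeights named nonnegative weights over orders 2..7.
#' @param stemLengthRange inclusive bp range for stems.
#' @param loopLengthRange inclusive nt range for junction loop segments.
#' @param loopLengthDecay geometric decay factor of loop-length weights.
#' @param betaL0,betaCoax planted-rule weights (per nt, per kcal/mol).
#' @param alpha planted-rule intercept used when a junction is generated
#'   standalone; [generateDataset()] recalibrates it.
#' @param labelNoise symmetric label-flip probability in `[0, 0.5)`.
#' @param classBalanceTarget target stacked:unstacked ratio.
#' @param gu probability that a stem pair is a GU/UG wobble.
#' @param seed mandatory integer seed.
#' @return A list of class `syntheticConfig`.
#' @export
syntheticConfig <- function(nJunctions = 100L,
                            orderWeights = c("2" = 960, "3" = 87, "4" = 91,
                                             "5" = 15, "6" = 1, "7" = 3),
                            stemLengthRange = c(2L, 8L),
                            loopLengthRange = c(0L, 8L),
                            loopLengthDecay = 0.55,
                            betaL0 = 2.0, betaCoax = 0.5, alpha = 2.5,
                            labelNoise = 0, classBalanceTarget = 6,
                            gu = 0.1, seed) {
  if (missing(seed)) stop("a seed is mandatory")
  stopifnot(nJunctions >= 0, all(orderWeights >= 0), sum(orderWeights) > 0,
            all(names(orderWeights) %in% as.character(2:7)),
            stemLengthRange[1] >= 1, stemLengthRange[1] <= stemLengthRange[2],
            loopLengthRange[1] >= 0, loopLengthRange[1] <= loopLengthRange[2],
            labelNoise >= 0, labelNoise < 0.5, classBalanceTarget > 0,
            gu >= 0, gu <= 1)
  structure(list(nJunctions = as.integer(nJunctions),
                 orderWeights = orderWeights,
                 stemLengthRange = as.integer(stemLengthRange),
                 loopLengthRange = as.integer(loopLengthRange),
                 loopLengthDecay = loopLengthDecay,
                 betaL0 = betaL0, betaCoax = betaCoax, alpha = alpha,
                 labelNoise = labelNoise,
                 classBalanceTarget = classBalanceTarget,
                 gu = gu, seed = as.integer(seed)),
            class = "syntheticConfig")
}

.sampleLoopLength <- function(config, n = 1L) {
  lens <- config$loopLengthRange[1]:config$loopLengthRange[2]
  w <- config$loopLengthDecay^(lens - lens[1])
  sample(lens, n, replace = TRUE, prob = w / sum(w))
}

.sampleStemStrands <- function(len, gu) {
  wc <- c("AU", "UA", "CG", "GC")
  wob <- c("GU", "UG")
  probs <- c(rep((1 - gu) / 4, 4), rep(gu / 2, 2))
  pairs <- sample(c(wc, wob), len, replace = TRUE, prob = probs)
  list(s5 = paste(substr(pairs, 1, 1), collapse = ""),
       s3 = paste(substr(pairs, 2, 2), collapse = ""))
}

.randomLoop <- function(len) {
  if (len == 0L) return("")
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}

# geometry of one order-n junction: an enclosing stem containing n-1
# hairpin stems, separated by n junction loop segments
.generateGeometry <- function(order, config, id) {
  sl <- config$stemLengthRange
  repeat {
    segLens <- .sampleLoopLength(config, order)
    if (order > 2L || sum(segLens) > 0L) break  # 0/0 internal loop is no loop
  }
  outer <- .sampleStemStrands(sample(sl[1]:sl[2], 1L), config$gu)
  seqParts <- c(outer$s5)
  dbParts <- c(strrep("(", nchar(outer$s5)))
  for (k in seq_len(order - 1L)) {
    seg <- .randomLoop(segLens[k])
    child <- .sampleStemStrands(sample(sl[1]:sl[2], 1L), config$gu)
    hp <- .randomLoop(sample(3:6, 1L))
    m <- nchar(child$s5)
    seqParts <- c(seqParts, seg, child$s5, hp,
                  paste(rev(strsplit(child$s3, "")[[1]]), collapse = ""))
    dbParts <- c(dbParts, strrep(".", nchar(seg)), strrep("(", m),
                 strrep(".", nchar(hp)), strrep(")", m))
  }
  lastSeg <- .randomLoop(segLens[order])
  seqParts <- c(seqParts, lastSeg,
                paste(rev(strsplit(outer$s3, "")[[1]]), collapse = ""))
  dbParts <- c(dbParts, strrep(".", nchar(lastSeg)),
               strrep(")", nchar(outer$s5)))
  record <- parseDotBracket(paste(seqParts, collapse = ""),
                            paste(dbParts, collapse = ""), id = id)
  junctions <- extractJunctions(record)
  stopifnot(length(junctions) == 1L, junctions[[1]]@order == order)
  list(record = record, junction = junctions[[1]])
}

.plantedLogit <- function(L0, dGcoax, config, alpha) {
  alpha - config$betaL0 * L0 - config$betaCoax * dGcoax
}

# project per-pair stacking labels onto a valid matching: keep candidate
# stacks in decreasing planted-odds order, dropping conflicting ones
.projectTruth <- function(junction, labels, odds) {
  n <- junction@order
  em <- .cycleEdges(n)
  cand <- which(labels == 1L)
  cand <- cand[order(-odds[cand], cand)]
  used <- logical(n)
  keep <- integer(0)
  for (e in cand) {
    v <- em[e, ]
    if (!any(used[v])) { keep <- c(keep, e); used[v] <- TRUE }
  }
  sp <- em[sort(keep), , drop = FALSE]
  if (!nrow(sp)) sp <- matrix(integer(0), ncol = 2)
  storage.mode(sp) <- "integer"
  cfg <- new("StackingConfiguration", junctionId = junction@sourceId,
             order = n, stackedPairs = sp, totalWeight = NA_real_)
  validObject(cfg)
  cfg
}

#' Generate one synthetic junction with planted stacking truth
#'
#' Emits a syntactically valid nested dot-bracket record realizing an
#' order-n junction (random canonical stems, random loops), parses it back
#' through the package's own structure pipeline, applies the planted
#' stacking rule to its adjacent stem pairs and projects the sampled
#' labels to a valid matching. Draws from the current RNG state; seed via
#' `set.seed()` or use [generateDataset()].
#'
#' @param order junction order in 2..7.
#' @param config a [syntheticConfig()].
#' @param params a [TurnerParameters-class].
#' @param id record identifier.
#' @param alpha planted-rule intercept (defaults to `config$alpha`).
#' @return list: `record`, `junction`, `truth`
#'   ([StackingConfiguration-class]), `pairs` (decomposition with planted
#'   labels attached), `plantedLabels`.
#' @export
generateJunction <- function(order, config, params = turnerParameters(),
                             id = "synthetic", alpha = config$alpha) {
  stopifnot(order >= 2L, order <= 7L)
  geo <- .generateGeometry(as.integer(order), config, id)
  pairs <- decomposeJunction(geo$junction)
  L0 <- vapply(pairs, function(p) nchar(p@loop0), numeric(1))
  dG <- vapply(pairs, coaxialStackEnergy, numeric(1), params = params)
  pr <- plogis(.plantedLogit(L0, dG, config, alpha))
  labels <- rbinom(length(pr), 1L, pr)
  if (config$labelNoise > 0) {
    flip <- runif(length(labels)) < config$labelNoise
    labels[flip] <- 1L - labels[flip]
  }
  truth <- .projectTruth(geo$junction, labels, pr)
  for (k in seq_along(pairs)) pairs[[k]]@label <- as.integer(labels[k])
  list(record = geo$record, junction = geo$junction, truth = truth,
       pairs = pairs, plantedLabels = as.integer(labels))
}

#' Generate a labeled synthetic junction dataset
#'
#' Generates `config$nJunctions` junctions with orders drawn from the
#' configured distribution, calibrates the planted-rule intercept so that
#' the expected planted stacked:unstacked ratio over all generated pairs
#' meets `classBalanceTarget`, samples per-pair labels (plus optional
#' noise), projects each junction's labels to a valid matching truth, and
#' assembles the feature table with the planted per-pair labels attached.
#' Fully deterministic given `config$seed`.
#'
#' @param config a [syntheticConfig()].
#' @param params a [TurnerParameters-class].
#' @return list: `features` (data.frame from [featureTable()] with
#'   labels), `records`, `junctions`, `truths`, `alpha` (calibrated
#'   intercept), and `balance` with the achieved planted and
#'   matching-projected stacked:unstacked ratios.
#' @export
generateDataset <- function(config, params = turnerParameters()) {
  stopifnot(inherits(config, "syntheticConfig"))
  set.seed(config$seed)
  if (config$nJunctions == 0L)
    return(list(features = featureTable(list(), params), records = list(),
                junctions = list(), truths = list(), alpha = config$alpha,
                balance = list(planted = NA_real_, matched = NA_real_)))
  ords <- as.integer(names(config$orderWeights))
  orders <- ords[sample.int(length(ords), config$nJunctions, replace = TRUE,
                            prob = config$orderWeights / sum(config$orderWeights))]
  geos <- lapply(seq_len(config$nJunctions), function(i)
    .generateGeometry(orders[i], config,
                      sprintf("syn%05d_%dway", i, orders[i])))
  pairsByJ <- lapply(geos, function(g) decomposeJunction(g$junction))
  allPairs <- unlist(pairsByJ, recursive = FALSE)
  L0 <- vapply(allPairs, function(p) nchar(p@loop0), numeric(1))
  dG <- vapply(allPairs, coaxialStackEnergy, numeric(1), params = params)
  targetFrac <- config$classBalanceTarget / (config$classBalanceTarget + 1)
  balanceGap <- function(a)
    mean(plogis(.plantedLogit(L0, dG, config, a))) - targetFrac
  alpha <- if (balanceGap(-30) > 0 || balanceGap(30) < 0) {
    warning("class balance target unattainable; using config alpha")
    config$alpha
  } else uniroot(balanceGap, c(-30, 30), tol = 1e-6)$root
  pr <- plogis(.plantedLogit(L0, dG, config, alpha))
  labels <- rbinom(length(pr), 1L, pr)
  if (config$labelNoise > 0) {
    flip <- runif(length(labels)) < config$labelNoise
    labels[flip] <- 1L - labels[flip]
  }
  idx <- split(seq_along(allPairs),
               rep(seq_along(pairsByJ), lengths(pairsByJ)))
  truths <- lapply(seq_along(geos), function(i)
    .projectTruth(geos[[i]]$junction, labels[idx[[i]]], pr[idx[[i]]]))
  for (k in seq_along(allPairs))
    allPairs[[k]]@label <- as.integer(labels[k])
  feats <- featureTable(allPairs, params)
  matchedPos <- sum(vapply(truths, function(t) nrow(t@stackedPairs),
                           integer(1)))
  ratioOf <- function(pos, tot) if (tot > pos) pos / (tot - pos) else Inf
  list(features = feats,
       records = lapply(geos, `[[`, "record"),
       junctions = lapply(geos, `[[`, "junction"),
       truths = truths, alpha = alpha,
       balance = list(planted = ratioOf(sum(labels), length(labels)),
                      matched = ratioOf(matchedPos, length(labels))))
}
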