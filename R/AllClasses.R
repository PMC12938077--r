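#' @include coaxStackR-package.R
NULL

FEATURE_NAMES <- c("L0", "L1", "L2", "A_L0", "A_L1", "A_L2",
                   "L_H1", "L_H2", "N", "dG_H1", "dG_H2", "dG_coax")

CANONICAL_PAIRS <- c("AU", "UA", "GC", "CG", "GU", "UG")

#' DotBracketRecord: a sequence plus nested dot-bracket structure
#'
#' Validated container for one Vienna-style record: an identifier, an RNA
#' sequence over A/C/G/U and a balanced, fully nested dot-bracket string of
#' the same length. Pseudoknotted bracket alphabets (`[`, `{`, `<`) are
#' rejected at construction: the decomposition and the loop-length features
#' assume a nested structure, and silently dropping crossing pairs would
#' corrupt them.
#'
#' @slot id character identifier.
#' @slot sequence RNA sequence (uppercase, T already mapped to U).
#' @slot structure dot-bracket string over `.`, `(`, `)`.
#' @seealso [parseDotBracket()], [readDotBracket()]
#' @exportClass DotBracketRecord
setClass("DotBracketRecord",
  representation(id = "character", sequence = "character",
                 structure = "character"))

setValidity("DotBracketRecord", function(object) {
  msg <- character(0)
  if (length(object@id) != 1L) msg <- c(msg, "'id' must be length 1")
  if (nchar(object@sequence) != nchar(object@structure))
    msg <- c(msg, "sequence and structure lengths differ")
  if (grepl("[^ACGU]", object@sequence))
    msg <- c(msg, "sequence contains characters outside A/C/G/U")
  bad <- gsub("[.()]", "", object@structure)
  if (nzchar(bad)) {
    if (grepl("[][{}<>]", object@structure))
      msg <- c(msg, "pseudoknot brackets are not supported (nested () only)")
    else
      msg <- c(msg, "structure contains characters outside '.', '(', ')'")
  }
  if (length(msg) == 0 && !.isBalanced(object@structure))
    msg <- c(msg, "unbalanced dot-bracket structure")
  if (length(msg)) msg else TRUE
})

#' Stem: a maximal helix of consecutively stacked base pairs
#'
#' @slot pairs integer matrix (k x 2) of 1-based pair positions (i, j),
#'   i < j, ordered outermost to innermost; pair k+1 is (i_k + 1, j_k - 1).
#' @slot seq5 the 5' strand, read 5' to 3' (residues at the i positions).
#' @slot seq3 the 3' strand aligned under `seq5`, read 3' to 5' (residues at
#'   the j positions); `substr(seq5, k, k)` pairs with `substr(seq3, k, k)`.
#' @exportClass Stem
setClass("Stem",
  representation(pairs = "matrix", seq5 = "character", seq3 = "character"))

setValidity("Stem", function(object) {
  p <- object@pairs
  if (!is.numeric(p) || ncol(p) != 2L || nrow(p) < 1L)
    return("'pairs' must be a k x 2 matrix with k >= 1")
  if (any(p[, 1] >= p[, 2])) return("each pair must satisfy i < j")
  if (nrow(p) > 1L) {
    di <- diff(p[, 1]); dj <- diff(p[, 2])
    if (any(di != 1L) || any(dj != -1L))
      return("pairs must be a consecutively stacked run (i+1, j-1)")
  }
  if (nchar(object@seq5) != nrow(p) || nchar(object@seq3) != nrow(p))
    return("strand sequences must match the number of pairs")
  TRUE
})

#' Junction: an n-way junction loop and its bounding stems
#'
#' A loop closed on all sides by `order` stems, in cyclic 5'-to-3' order
#' (the enclosing stem first, then enclosed stems by 5' position). Loop
#' segment `i` is the unpaired stretch between stem `i` and stem `i + 1`
#' (cyclically). `proximalEntry`/`proximalExit` give, per stem, the two
#' residues of its junction-proximal closing pair: traversal of the loop
#' enters the stem at `entry` and leaves it at `exit`. `interfaceSteps[i]`
#' is the nearest-neighbor step formed at the interface between stems `i`
#' and `i + 1`, written `XY/WZ` (top strand 5'-XY-3' over bottom 3'-WZ-5'),
#' as used for coaxial stacking lookups.
#'
#' @slot sourceId identifier, typically `<record>_junction_<k>`.
#' @slot order integer number of stems (>= 2).
#' @slot stems list of [Stem-class] objects.
#' @slot loopSegments character vector of length `order`.
#' @slot proximalEntry,proximalExit integer vectors of length `order`.
#' @slot interfaceSteps character vector of length `order`.
#' @exportClass Junction
setClass("Junction",
  representation(sourceId = "character", order = "integer", stems = "list",
                 loopSegments = "character", proximalEntry = "integer",
                 proximalExit = "integer", interfaceSteps = "character"))

setValidity("Junction", function(object) {
  n <- object@order
  if (n < 2L) return("junction order must be >= 2")
  if (length(object@stems) != n) return("number of stems must equal order")
  if (length(object@loopSegments) != n)
    return("number of loop segments must equal order")
  if (length(object@proximalEntry) != n || length(object@proximalExit) != n ||
      length(object@interfaceSteps) != n)
    return("proximal/interface annotations must have length 'order'")
  if (!all(vapply(object@stems, is, logical(1), "Stem")))
    return("'stems' must contain Stem objects")
  TRUE
})

#' PseudoTwoWayJunction: an adjacent stem pair, the unit sample
#'
#' A cyclically adjacent pair of stems (H1, H2) from an n-way junction
#' together with its connecting loops: `loop0` directly connects H1 to H2
#' along the short arc; `loop1` and `loop2` are the far-arc segments
#' flanking H1's entry side and H2's exit side. For a true two-way junction
#' `loop1` equals `loop2` (both are the 3'-side loop). `nIntervening` is the
#' number of stems between H1 and H2 along the far arc (= parent order - 2
#' for adjacent pairs).
#'
#' @slot id sample identifier.
#' @slot h1,h2 [Stem-class] objects.
#' @slot loop0,loop1,loop2 connecting loop sequences (possibly empty).
#' @slot nIntervening integer >= 0.
#' @slot parentOrder order of the originating junction.
#' @slot interfaceStep nearest-neighbor step `XY/WZ` at the H1-H2 interface.
#' @slot label integer stacking label (0/1) or `NA` when unknown.
#' @exportClass PseudoTwoWayJunction
setClass("PseudoTwoWayJunction",
  representation(id = "character", h1 = "Stem", h2 = "Stem",
                 loop0 = "character", loop1 = "character", loop2 = "character",
                 nIntervening = "integer", parentOrder = "integer",
                 interfaceStep = "character", label = "integer"))

setValidity("PseudoTwoWayJunction", function(object) {
  if (object@parentOrder < 2L) return("parent order must be >= 2")
  if (object@nIntervening != object@parentOrder - 2L)
    return("nIntervening must equal parentOrder - 2 for adjacent pairs")
  if (object@parentOrder == 2L && !identical(object@loop1, object@loop2))
    return("for a two-way junction loop1 must equal loop2")
  if (!is.na(object@label) && !object@label %in% c(0L, 1L))
    return("label must be 0, 1 or NA")
  TRUE
})

#' TurnerParameters: a versioned nearest-neighbor parameter set
#'
#' Free-energy tables (kcal/mol at 37 C) backing the helix stability and
#' coaxial stacking energy functions: Watson-Crick-Franklin stack table,
#' duplex initiation, AU/GU terminal end penalty, self-complementary
#' symmetry correction, flush and mismatch-mediated coaxial interface
#' tables, the fixed terminal-mismatch penalty, and the empirical
#' loop-length penalty constants a, b, c.
#'
#' @slot version parameter-set version string (e.g. "turner2004").
#' @slot general named numeric: init, au_end, sym, mismatch_penalty,
#'   coax_a, coax_b, coax_c.
#' @slot stack,flushCoax,mismatchCoax named numeric tables keyed by
#'   nearest-neighbor step `XY/WZ`.
#' @seealso [turnerParameters()]
#' @exportClass TurnerParameters
setClass("TurnerParameters",
  representation(version = "character", general = "numeric",
                 stack = "numeric", flushCoax = "numeric",
                 mismatchCoax = "numeric"))

setValidity("TurnerParameters", function(object) {
  need <- c("init", "au_end", "sym", "mismatch_penalty",
            "coax_a", "coax_b", "coax_c")
  if (!all(need %in% names(object@general)))
    return(paste("missing general constants:",
                 paste(setdiff(need, names(object@general)), collapse = ", ")))
  keys <- as.vector(outer(CANONICAL_PAIRS, CANONICAL_PAIRS, function(a, b)
    paste0(substr(a, 1, 1), substr(b, 1, 1), "/",
           substr(a, 2, 2), substr(b, 2, 2))))
  for (tab in c("stack", "flushCoax", "mismatchCoax")) {
    v <- slot(object, tab)
    if (!all(keys %in% names(v)))
      return(paste0("'", tab, "' table is incomplete"))
  }
  TRUE
})

#' StackingModel: a trained pairwise stacking classifier
#'
#' @slot forest fitted probability forest (opaque).
#' @slot hyperparameters list as returned by [stackingHyperparameters()].
#' @slot threshold decision probability in (0, 1).
#' @slot featureNames the 12 feature columns, in training order.
#' @slot trainingData list with elements `x` (feature data.frame) and `y`
#'   (integer labels), retained for criterion-specific importances and
#'   similarity ranking.
#' @slot metadata list: sample counts, seed, parameter-set version,
#'   training-data fingerprint.
#' @exportClass StackingModel
setClass("StackingModel",
  representation(forest = "ANY", hyperparameters = "list",
                 threshold = "numeric", featureNames = "character",
                 trainingData = "list", metadata = "list"))

setValidity("StackingModel", function(object) {
  if (length(object@featureNames) != 12L)
    return("a stacking model must use exactly 12 features")
  if (object@threshold <= 0 || object@threshold >= 1)
    return("threshold must lie strictly inside (0, 1)")
  TRUE
})

#' CycleGraph: stems as vertices, adjacent-pair predictions as edges
#'
#' Edge `i` joins stems `i` and `i + 1` (cyclically) and is weighted by the
#' predicted stacking probability; `retained[i]` flags weights strictly
#' above the decision threshold. A two-way junction degenerates to a single
#' candidate edge.
#'
#' @slot junctionId identifier.
#' @slot order integer number of stems.
#' @slot weights numeric edge weights in `[0, 1]` (length `order` for
#'   order >= 3, length 1 for order 2).
#' @slot retained logical, same length as `weights`.
#' @slot threshold the strict retention threshold applied.
#' @exportClass CycleGraph
setClass("CycleGraph",
  representation(junctionId = "character", order = "integer",
                 weights = "numeric", retained = "logical",
                 threshold = "numeric"))

setValidity("CycleGraph", function(object) {
  nedge <- if (object@order == 2L) 1L else object@order
  if (object@order < 2L) return("order must be >= 2")
  if (length(object@weights) != nedge)
    return("wrong number of candidate edges for this order")
  if (length(object@retained) != nedge)
    return("'retained' must match the number of edges")
  if (any(object@weights < 0 | object@weights > 1))
    return("edge weights must lie in [0, 1]")
  TRUE
})

#' StackingConfiguration: a junction-level stacking assignment
#'
#' A set of stacked stem pairs forming a matching on the junction's cycle:
#' no stem participates in more than one stack. Used both for predictions
#' and ground truth; configurations compare by set equality of their pairs.
#'
#' @slot junctionId identifier.
#' @slot order integer junction order.
#' @slot stackedPairs integer matrix (k x 2) of stem indices, each row
#'   sorted, rows ordered lexicographically; zero rows mean no stacking.
#' @slot totalWeight summed edge weight for predicted matchings (`NA` for
#'   ground truth).
#' @exportClass StackingConfiguration
setClass("StackingConfiguration",
  representation(junctionId = "character", order = "integer",
                 stackedPairs = "matrix", totalWeight = "numeric"))

setValidity("StackingConfiguration", function(object) {
  sp <- object@stackedPairs
  if (ncol(sp) != 2L) return("'stackedPairs' must have two columns")
  if (nrow(sp)) {
    if (any(sp < 1L | sp > object@order))
      return("stem indices out of range")
    if (anyDuplicated(as.vector(sp)))
      return("not a matching: a stem appears in more than one stack")
    adj <- abs(sp[, 1] - sp[, 2]) == 1L |
           abs(sp[, 1] - sp[, 2]) == object@order - 1L
    if (object@order > 2L && !all(adj))
      return("stacked pairs must be cyclically adjacent stems")
  }
  TRUE
})
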