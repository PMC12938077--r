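#' @include AllClasses.R
NULL

.cycleEdges <- function(order) {
  if (order == 2L) return(matrix(c(1L, 2L), ncol = 2))
  cbind(seq_len(order), c(seq_len(order)[-1], 1L))
}

# comparator encoding the deterministic tie-break: maximum weight, then
# fewest edges, then lexicographically smallest edge-index vector
.betterMatching <- function(a, b, tol = 1e-12) {
  if (is.null(b)) return(TRUE)
  if (a$weight > b$weight + tol) return(TRUE)
  if (a$weight < b$weight - tol) return(FALSE)
  if (length(a$edges) != length(b$edges))
    return(length(a$edges) < length(b$edges))
  if (!length(a$edges)) return(FALSE)
  for (k in seq_along(a$edges)) {
    if (a$edges[k] != b$edges[k]) return(a$edges[k] < b$edges[k])
  }
  FALSE
}

#' Build the cycle graph of a junction from pairwise predictions
#'
#' Stems are vertices; edge `i` joins stems `i` and `i + 1` (cyclically)
#' with the predicted stacking probability as weight. Edges are retained
#' only when strictly above the threshold (a probability exactly equal to
#' the threshold is excluded). A two-way junction contributes a single
#' candidate edge.
#'
#' @param probabilities numeric vector of per-adjacent-pair probabilities
#'   in cyclic order (length n for an n-way junction with n >= 3, length 1
#'   for a two-way), or the data.frame returned by [predictStacking()] for
#'   exactly one junction, in which case its `probability` column is used.
#' @param threshold strict retention threshold (default 0.42, the KDE
#'   crossing point of the reference training distribution).
#' @param junctionId identifier stored in the graph.
#' @return A [CycleGraph-class].
#' @export
buildCycleGraph <- function(probabilities, threshold = 0.42,
                            junctionId = "junction") {
  if (is.data.frame(probabilities)) {
    if (anyDuplicated(probabilities$pair_id))
      stop("duplicate pair predictions for one junction")
    probabilities <- probabilities$probability
  }
  p <- as.numeric(probabilities)
  if (!length(p)) stop("no pair predictions supplied")
  if (length(p) == 2L)
    stop("two adjacent-pair predictions are inconsistent: a two-way ",
         "junction has one pair, an n-way junction n >= 3")
  if (anyNA(p)) stop("missing probabilities")
  order <- if (length(p) == 1L) 2L else length(p)
  g <- new("CycleGraph", junctionId = as.character(junctionId),
           order = as.integer(order), weights = p,
           retained = p > threshold, threshold = threshold)
  validObject(g)
  g
}

.matchingToConfiguration <- function(g, edges) {
  em <- .cycleEdges(g@order)
  sp <- em[edges, , drop = FALSE]
  if (nrow(sp)) {
    sp <- t(apply(sp, 1, sort))
    sp <- sp[order(sp[, 1], sp[, 2]), , drop = FALSE]
  } else {
    sp <- matrix(integer(0), ncol = 2)
  }
  storage.mode(sp) <- "integer"
  cfg <- new("StackingConfiguration", junctionId = g@junctionId,
             order = g@order, stackedPairs = sp,
             totalWeight = sum(g@weights[edges]))
  validObject(cfg)
  cfg
}

#' Maximum-weight matching on the junction cycle graph
#'
#' Selects the vertex-disjoint subset of retained edges with maximum total
#' weight — the physically consistent set of stem-stem stacks (each stem
#' stacks with at most one partner) that maximizes the summed predicted
#' probability. Solved exactly by dynamic programming on the cycle: the
#' closing edge (n, 1) is either excluded (a path DP over edges 1..n-1) or
#' included (forcing out its neighbors, a path DP over edges 2..n-2). Ties
#' are broken deterministically: fewer edges, then lexicographically
#' smallest edge indices. An empty retained set yields the no-stacking
#' configuration.
#'
#' @param g a [CycleGraph-class].
#' @return A [StackingConfiguration-class] with `totalWeight` set.
#' @seealso [bruteForceMatching()] for the exhaustive oracle.
#' @export
maxWeightMatchingCycle <- function(g) {
  stopifnot(is(g, "CycleGraph"))
  n <- g@order
  w <- ifelse(g@retained, g@weights, NA_real_)
  if (n == 2L) {
    edges <- if (g@retained[1]) 1L else integer(0)
    return(.matchingToConfiguration(g, edges))
  }
  # path DP over a consecutive run of cycle edges; adjacent edges conflict
  pathDP <- function(edgeIdx) {
    best <- list(weight = 0, edges = integer(0))   # empty matching
    prevBest <- list(weight = 0, edges = integer(0))
    for (k in seq_along(edgeIdx)) {
      e <- edgeIdx[k]
      cur <- best
      if (!is.na(w[e])) {
        cand <- list(weight = prevBest$weight + w[e],
                     edges = sort(c(prevBest$edges, e)))
        if (.betterMatching(cand, cur)) cur <- cand
      }
      prevBest <- best
      best <- cur
    }
    best
  }
  best <- pathDP(seq_len(n - 1L))
  if (!is.na(w[n])) {
    inner <- if (n >= 4L) seq.int(2L, n - 2L) else integer(0)
    sub <- pathDP(inner)
    cand <- list(weight = sub$weight + w[n], edges = sort(c(sub$edges, n)))
    if (.betterMatching(cand, best)) best <- cand
  }
  .matchingToConfiguration(g, best$edges)
}

#' Exhaustive matching oracle
#'
#' Enumerates every subset of the retained edges, keeps those that are
#' matchings (no shared stem) and returns the best under the same
#' deterministic tie-break as [maxWeightMatchingCycle()]. Exponential in
#' the junction order; intended as an independent correctness oracle for
#' small cycles.
#'
#' @param g a [CycleGraph-class] with order <= 20.
#' @return A [StackingConfiguration-class].
#' @export
bruteForceMatching <- function(g) {
  stopifnot(is(g, "CycleGraph"))
  if (g@order > 20L) stop("brute force limited to order <= 20")
  em <- .cycleEdges(g@order)
  retained <- which(g@retained)
  best <- list(weight = 0, edges = integer(0))
  m <- length(retained)
  if (m) {
    for (mask in seq_len(2^m) - 1L) {
      sel <- retained[bitwAnd(mask, 2^(seq_len(m) - 1L)) > 0]
      verts <- as.vector(em[sel, , drop = FALSE])
      if (anyDuplicated(verts)) next
      cand <- list(weight = sum(g@weights[sel]), edges = sel)
      if (.betterMatching(cand, best)) best <- cand
    }
  }
  .matchingToConfiguration(g, best$edges)
}

#' Enumerate all stacking configurations of an n-way junction
#'
#' Every matching of the full cycle (including the empty, no-stacking one)
#' is a distinct configuration. A two-way junction has 2 (stacked or not),
#' a three-way 4 (H1-H2, H2-H3, H3-H1, none), a four-way 7 (four single
#' stacks, two disjoint double stacks, none); in general the counts follow
#' the cycle-matching recurrence (Lucas numbers for n >= 3).
#'
#' @param order junction order, 2 to 12.
#' @return A list of [StackingConfiguration-class] objects, empty
#'   configuration first, then by increasing stack count and
#'   lexicographic edge order.
#' @export
enumerateConfigurations <- function(order) {
  n <- as.integer(order)
  if (n < 2L || n > 12L) stop("order must be between 2 and 12")
  g <- new("CycleGraph", junctionId = paste0("cycle_", n),
           order = n,
           weights = rep(1, if (n == 2L) 1L else n),
           retained = rep(TRUE, if (n == 2L) 1L else n),
           threshold = 0)
  em <- .cycleEdges(n)
  m <- nrow(em)
  configs <- list()
  for (mask in seq_len(2^m) - 1L) {
    sel <- which(bitwAnd(mask, 2^(seq_len(m) - 1L)) > 0)
    verts <- as.vector(em[sel, , drop = FALSE])
    if (anyDuplicated(verts)) next
    configs[[length(configs) + 1L]] <- .matchingToConfiguration(g, sel)
  }
  key <- vapply(configs, function(cfg)
    sprintf("%02d_%s", nrow(cfg@stackedPairs),
            paste(sprintf("%02d%02d", cfg@stackedPairs[, 1],
                          cfg@stackedPairs[, 2]), collapse = "_")),
    character(1))
  configs[order(key)]
}

#' Human-readable configuration label in H_i-H_j notation
#'
#' @param config a [StackingConfiguration-class].
#' @return A string such as `"H1-H2 & H3-H4"`, or `"no stacking"`.
#' @export
configurationLabel <- function(config) {
  sp <- config@stackedPairs
  if (!nrow(sp)) return("no stacking")
  paste(sprintf("H%d-H%d", sp[, 1], sp[, 2]), collapse = " & ")
}

#' End-to-end junction prediction
#'
#' Decomposes a junction into its adjacent stem pairs, extracts features,
#' applies the trained classifier, builds the thresholded cycle graph and
#' returns the maximum-weight matching configuration.
#'
#' @param model a [StackingModel-class].
#' @param junction a [Junction-class].
#' @param params a [TurnerParameters-class].
#' @param threshold edge-retention threshold; defaults to the model's.
#' @return list: `configuration` ([StackingConfiguration-class]),
#'   `predictions` (per-pair data.frame), `graph` ([CycleGraph-class]).
#' @export
predictJunctionStacking <- function(model, junction,
                                    params = turnerParameters(),
                                    threshold = model@threshold) {
  pairs <- decomposeJunction(junction)
  feats <- featureTable(pairs, params)
  preds <- predictStacking(model, feats)
  g <- buildCycleGraph(preds$probability, threshold = threshold,
                       junctionId = junction@sourceId)
  list(configuration = maxWeightMatchingCycle(g), predictions = preds,
       graph = g)
}

#' Write per-junction stacking reports as JSON
#'
#' One object per junction: order, per-pair probabilities, retained edges
#' and the selected configuration in H_i-H_j notation.
#'
#' @param results list of results from [predictJunctionStacking()].
#' @param path output file, or `NULL` to return the JSON string.
#' @export
writeStackingJSON <- function(results, path = NULL) {
  payload <- lapply(results, function(r) {
    g <- r$graph
    list(id = g@junctionId, order = g@order,
         probabilities = as.numeric(g@weights),
         retained = which(g@retained),
         threshold = g@threshold,
         configuration = configurationLabel(r$configuration),
         stacked_pairs = apply(r$configuration@stackedPairs, 1, function(p)
           sprintf("H%d-H%d", p[1], p[2])))
  })
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, pretty = TRUE)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}
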