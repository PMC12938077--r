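#' @include AllClasses.R
NULL

#' Accessors for coaxStackR classes
#'
#' Small accessor generics: `dotBracket()` returns the structure string,
#' `junctionOrder()` the number of stems, `stems()` the stem list,
#' `loopSegments()` the per-adjacency unpaired segments, `stemLength()` the
#' number of base pairs in a stem, `stackedPairs()` the stacked stem-index
#' matrix of a configuration, `threshold()` a model's or graph's decision
#' threshold, and `featureNames()` the feature order of a trained model.
#'
#' @param x an object of the documented class.
#' @return See details per generic.
#' @name accessors
#' @aliases dotBracket junctionOrder stems loopSegments stemLength
#'   stackedPairs threshold featureNames
NULL

#' @rdname accessors
#' @export
setGeneric("dotBracket", function(x) standardGeneric("dotBracket"))
#' @rdname accessors
#' @export
setGeneric("junctionOrder", function(x) standardGeneric("junctionOrder"))
#' @rdname accessors
#' @export
setGeneric("stems", function(x) standardGeneric("stems"))
#' @rdname accessors
#' @export
setGeneric("loopSegments", function(x) standardGeneric("loopSegments"))
#' @rdname accessors
#' @export
setGeneric("stemLength", function(x) standardGeneric("stemLength"))
#' @rdname accessors
#' @export
setGeneric("stackedPairs", function(x) standardGeneric("stackedPairs"))
#' @rdname accessors
#' @export
setGeneric("threshold", function(x) standardGeneric("threshold"))
#' @rdname accessors
#' @export
setGeneric("featureNames", function(x) standardGeneric("featureNames"))

#' @rdname accessors
setMethod("dotBracket", "DotBracketRecord", function(x) x@structure)
#' @rdname accessors
setMethod("junctionOrder", "Junction", function(x) x@order)
#' @rdname accessors
setMethod("junctionOrder", "StackingConfiguration", function(x) x@order)
#' @rdname accessors
setMethod("junctionOrder", "CycleGraph", function(x) x@order)
#' @rdname accessors
setMethod("stems", "Junction", function(x) x@stems)
#' @rdname accessors
setMethod("loopSegments", "Junction", function(x) x@loopSegments)
#' @rdname accessors
setMethod("stemLength", "Stem", function(x) nrow(x@pairs))
#' @rdname accessors
setMethod("stackedPairs", "StackingConfiguration", function(x) x@stackedPairs)
#' @rdname accessors
setMethod("threshold", "StackingModel", function(x) x@threshold)
#' @rdname accessors
setMethod("threshold", "CycleGraph", function(x) x@threshold)
#' @rdname accessors
setMethod("featureNames", "StackingModel", function(x) x@featureNames)

setMethod("show", "DotBracketRecord", function(object) {
  cat("DotBracketRecord '", object@id, "' (", nchar(object@sequence),
      " nt)\n", sep = "")
  cat(" ", object@sequence, "\n ", object@structure, "\n", sep = "")
})

setMethod("show", "Stem", function(object) {
  p <- object@pairs
  cat("Stem of ", nrow(p), " bp: 5'-", object@seq5, "-3' / 3'-",
      object@seq3, "-5'  [", p[1, 1], "-", p[nrow(p), 1], " : ",
      p[nrow(p), 2], "-", p[1, 2], "]\n", sep = "")
})

setMethod("show", "Junction", function(object) {
  cat(object@order, "-way junction '", object@sourceId, "'\n", sep = "")
  for (i in seq_len(object@order)) {
    s <- object@stems[[i]]
    cat("  H", i, ": ", nrow(s@pairs), " bp; loop to next: \"",
        object@loopSegments[i], "\" (", nchar(object@loopSegments[i]),
        " nt)\n", sep = "")
  }
})

setMethod("show", "PseudoTwoWayJunction", function(object) {
  cat("PseudoTwoWayJunction '", object@id, "' (parent order ",
      object@parentOrder, ")\n", sep = "")
  cat("  H1: ", nrow(object@h1@pairs), " bp, H2: ", nrow(object@h2@pairs),
      " bp; L0=", nchar(object@loop0), " L1=", nchar(object@loop1),
      " L2=", nchar(object@loop2), "; interface ", object@interfaceStep,
      "; label=", ifelse(is.na(object@label), "NA", object@label),
      "\n", sep = "")
})

setMethod("show", "TurnerParameters", function(object) {
  cat("TurnerParameters '", object@version, "': ",
      length(object@stack), " stack steps, init=",
      object@general[["init"]], ", AU end=", object@general[["au_end"]],
      ", sym=", object@general[["sym"]], "\n", sep = "")
})

setMethod("show", "StackingModel", function(object) {
  hp <- object@hyperparameters
  cat("StackingModel: ", hp$nTrees, " trees, depth ", hp$maxDepth,
      ", threshold ", signif(object@threshold, 3), "\n", sep = "")
  cat("  trained on ", object@metadata$nSamples, " pairs (",
      object@metadata$nPositive, " stacked), parameters '",
      object@metadata$parameterVersion, "'\n", sep = "")
})

setMethod("show", "CycleGraph", function(object) {
  cat("CycleGraph '", object@junctionId, "' order ", object@order,
      ": weights ", paste(signif(object@weights, 3), collapse = ", "),
      " (", sum(object@retained), " retained > ", object@threshold,
      ")\n", sep = "")
})

setMethod("show", "StackingConfiguration", function(object) {
  lab <- configurationLabel(object)
  cat("StackingConfiguration '", object@junctionId, "' (order ",
      object@order, "): ", lab, "\n", sep = "")
})
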