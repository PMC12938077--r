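#' @include AllClasses.R
NULL

#' Load a nearest-neighbor parameter set
#'
#' Reads the plain-text parameter table shipped with the package (or a
#' user-supplied file in the same format): a `# version:` header, then
#' tab-separated `section / key / value` rows for the general constants and
#' the three interface tables (helical stacks, flush coaxial, mismatch
#' coaxial), all in kcal/mol at 37 C. The loader validates that every
#' canonical nearest-neighbor step over the six pair types (AU, UA, GC, CG,
#' GU, UG) is present in each table.
#'
#' @param path path to a parameter file; default is the embedded
#'   "turner2004" set.
#' @return A [TurnerParameters-class].
#' @examples
#' params <- turnerParameters()
#' params@general[["init"]]
#' @export
turnerParameters <- function(path = system.file("extdata", "turner2004.tsv",
                                                package = "coaxStackR")) {
  lines <- readLines(path)
  vline <- grep("^# version:", lines, value = TRUE)
  version <- if (length(vline)) trimws(sub("^# version:", "", vline[1])) else "unknown"
  tab <- read.delim(text = lines[!startsWith(lines, "#")],
                    stringsAsFactors = FALSE)
  pick <- function(section) {
    rows <- tab[tab$section == section, ]
    setNames(as.numeric(rows$value), rows$key)
  }
  obj <- new("TurnerParameters", version = version, general = pick("general"),
             stack = pick("stack"), flushCoax = pick("flush_coax"),
             mismatchCoax = pick("mismatch_coax"))
  validObject(obj)
  obj
}

.checkCanonical <- function(seq5, seq3) {
  p5 <- strsplit(seq5, "", fixed = TRUE)[[1]]
  p3 <- strsplit(seq3, "", fixed = TRUE)[[1]]
  pairs <- paste0(p5, p3)
  bad <- !pairs %in% CANONICAL_PAIRS
  if (any(bad))
    stop("non-canonical base pair(s) in helix: ",
         paste(unique(pairs[bad]), collapse = ", "))
  pairs
}

#' Helix free energy under the Watson-Crick-Franklin model
#'
#' Computes the 37 C folding free energy of a helix as the linear
#' combination of duplex initiation, AU/GU terminal end penalties (one per
#' helix end closed by an AU, UA, GU or UG pair; a 1-bp helix has two ends
#' on its single pair), a symmetry correction for self-complementary
#' duplexes, and the sum of nearest-neighbor stack terms over the
#' `stemLength - 1` steps.
#'
#' @param stem a [Stem-class] with canonical pairs only (AU/GC/GU and
#'   reverses); non-canonical pairs are an error.
#' @param params a [TurnerParameters-class].
#' @return Named numeric vector: `total`, `init`, `au_end`, `sym`,
#'   `stacking` (kcal/mol); `total` is the exact sum of the components.
#' @examples
#' s <- findStems(parseDotBracket("GGACAAAGUCC", "((((...))))"))[[1]]
#' helixFreeEnergy(s, turnerParameters())
#' @export
helixFreeEnergy <- function(stem, params) {
  stopifnot(is(stem, "Stem"), is(params, "TurnerParameters"))
  n <- nrow(stem@pairs)
  pairs <- .checkCanonical(stem@seq5, stem@seq3)
  wobble <- c("AU", "UA", "GU", "UG")
  auEnds <- sum(pairs[c(1L, n)] %in% wobble)  # n == 1: both ends, same pair
  p5 <- strsplit(stem@seq5, "", fixed = TRUE)[[1]]
  p3 <- strsplit(stem@seq3, "", fixed = TRUE)[[1]]
  stackSum <- 0
  if (n > 1L) {
    keys <- paste0(p5[-n], p5[-1], "/", p3[-n], p3[-1])
    miss <- keys[!keys %in% names(params@stack)]
    if (length(miss))
      stop("unknown nearest-neighbor step(s): ", paste(miss, collapse = ", "))
    stackSum <- sum(params@stack[keys])
  }
  # self-complementary: 5' strand read 5'->3' equals 3' strand read 5'->3'
  selfComp <- identical(stem@seq5, paste(rev(p3), collapse = ""))
  comps <- c(init = unname(params@general[["init"]]),
             au_end = unname(params@general[["au_end"]]) * auEnds,
             sym = if (selfComp) unname(params@general[["sym"]]) else 0,
             stacking = stackSum)
  c(total = sum(comps), comps)
}

#' Coaxial stacking free energy between two adjacent stems
#'
#' Empirical interface energy as a piecewise function of the direct
#' connecting loop length L0 (nucleotides):
#' \itemize{
#'   \item L0 = 0: flush coaxial table lookup at the interface step;
#'   \item L0 = 1: mismatch-mediated table lookup plus the fixed
#'     2.1 kcal/mol terminal-mismatch penalty;
#'   \item 2 <= L0 <= 6: `a + b*L0 + 2c` with a = 9.3, b = 0, c = -0.6;
#'   \item L0 > 6: `a + 6b + 1.1*log(L0/6) + 2c`, a logarithmic loop
#'     entropy penalty continuous at L0 = 6 and increasing beyond it.
#' }
#' Short connecting loops favor stacking (negative energies); from two
#' unpaired nucleotides on, the value is a flat then slowly growing
#' penalty, matching the sharp drop in stacking propensity with loop
#' length.
#'
#' @param pair a [PseudoTwoWayJunction-class] (its `interfaceStep` and
#'   `loop0` are used), or `NULL` when `L0 >= 2` and only `L0` is given.
#' @param params a [TurnerParameters-class].
#' @param L0 optional override of the connecting loop length.
#' @return Free energy in kcal/mol.
#' @examples
#' coaxialStackEnergy(NULL, turnerParameters(), L0 = 4)  # 8.1
#' @export
coaxialStackEnergy <- function(pair, params, L0 = NULL) {
  stopifnot(is(params, "TurnerParameters"))
  if (is.null(L0)) {
    stopifnot(is(pair, "PseudoTwoWayJunction"))
    L0 <- nchar(pair@loop0)
  }
  if (L0 < 0) stop("negative connecting loop length")
  g <- params@general
  if (L0 >= 2) {
    if (L0 <= 6)
      return(unname(g[["coax_a"]] + g[["coax_b"]] * L0 + 2 * g[["coax_c"]]))
    return(unname(g[["coax_a"]] + 6 * g[["coax_b"]] +
                  1.1 * log(L0 / 6) + 2 * g[["coax_c"]]))
  }
  stopifnot(is(pair, "PseudoTwoWayJunction"))
  step <- pair@interfaceStep
  tab <- if (L0 == 0) params@flushCoax else params@mismatchCoax
  if (!step %in% names(tab))
    stop("unknown interface step '", step, "'")
  val <- unname(tab[[step]])
  if (L0 == 1) val <- val + unname(g[["mismatch_penalty"]])
  val
}
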