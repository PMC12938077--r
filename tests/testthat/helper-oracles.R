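# Independent oracles and small constructors used across the test files.

# Full Needleman-Wunsch DP with linear gaps, plus a deterministic traceback
# (diagonal preferred, then up, then left). Returns the optimal score and
# the similarity = identical aligned positions / alignment length.
nwOracle <- function(s1, s2, match = 2, mismatch = -1, gap = -2) {
  a <- strsplit(s1, "", fixed = TRUE)[[1]]
  b <- strsplit(s2, "", fixed = TRUE)[[1]]
  n <- length(a); m <- length(b)
  S <- matrix(0, n + 1, m + 1)
  S[, 1] <- gap * (0:n)
  S[1, ] <- gap * (0:m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    d <- S[i, j] + if (a[i] == b[j]) match else mismatch
    S[i + 1, j + 1] <- max(d, S[i, j + 1] + gap, S[i + 1, j] + gap)
  }
  i <- n; j <- m; matches <- 0L; len <- 0L
  while (i > 0 || j > 0) {
    len <- len + 1L
    if (i > 0 && j > 0 &&
        S[i + 1, j + 1] == S[i, j] + (if (a[i] == b[j]) match else mismatch)) {
      if (a[i] == b[j]) matches <- matches + 1L
      i <- i - 1L; j <- j - 1L
    } else if (i > 0 && S[i + 1, j + 1] == S[i, j + 1] + gap) {
      i <- i - 1L
    } else {
      j <- j - 1L
    }
  }
  list(score = S[n + 1, m + 1], similarity = matches / len, length = len)
}

# AUC as the rank statistic (probability that a random positive scores
# above a random negative, ties counted half).
aucRankOracle <- function(labels, probs) {
  pos <- probs[labels == 1]; neg <- probs[labels == 0]
  grid <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(grid)
}

# matchings of a cycle graph C_n counted by the Lucas recurrence
# f(n) = f(n-1) + f(n-2) with f(3) = 4, f(4) = 7; n = 2 degenerates to 2.
cycleMatchingCountOracle <- function(n) {
  if (n == 2) return(2)
  f <- c(NA, NA, 4, 7)
  while (length(f) < n) f <- c(f, f[length(f)] + f[length(f) - 1])
  f[n]
}

# direct constructors bypassing the parser, for thermodynamic unit tests
makeStem <- function(seq5, seq3, start = 1L) {
  m <- nchar(seq5)
  end <- start + 2L * m + 3L  # arbitrary consistent j side
  new("Stem", pairs = cbind(start:(start + m - 1L), end:(end - m + 1L)),
      seq5 = seq5, seq3 = seq3)
}

makePair <- function(h1, h2, loop0 = "", loop1 = "", loop2 = "",
                     parentOrder = 2L, interfaceStep = "GC/CG",
                     id = "pair", label = NA_integer_) {
  new("PseudoTwoWayJunction", id = id, h1 = h1, h2 = h2,
      loop0 = loop0, loop1 = loop1, loop2 = loop2,
      nIntervening = as.integer(parentOrder) - 2L,
      parentOrder = as.integer(parentOrder),
      interfaceStep = interfaceStep, label = label)
}

# read the embedded parameter table directly (independent of the loader's
# internal representation) as a named list of sections
readParamsOracle <- function() {
  path <- system.file("extdata", "turner2004.tsv", package = "coaxStackR")
  lines <- readLines(path)
  tab <- read.delim(text = lines[!startsWith(lines, "#")])
  lapply(split(tab, tab$section), function(d) setNames(d$value, d$key))
}

randomCycleGraph <- function(n, threshold = 0.42) {
  w <- runif(if (n == 2) 1 else n)
  buildCycleGraph(w, threshold = threshold, junctionId = paste0("rand", n))
}

makeConfig <- function(order, pairs, id = "j") {
  sp <- if (length(pairs)) do.call(rbind, pairs) else matrix(integer(0), ncol = 2)
  storage.mode(sp) <- "integer"
  new("StackingConfiguration", junctionId = id, order = as.integer(order),
      stackedPairs = sp, totalWeight = NA_real_)
}
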