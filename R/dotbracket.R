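#' @include AllClasses.R
NULL

# balanced, fully nested check for a ()-only string
.isBalanced <- function(structure) {
  chars <- strsplit(structure, "", fixed = TRUE)[[1]]
  depth <- 0L
  for (ch in chars) {
    if (ch == "(") depth <- depth + 1L
    else if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L) return(FALSE)
    }
  }
  depth == 0L
}

# stack-based pair table: integer vector, partner index or NA
.pairTable <- function(structure) {
  chars <- strsplit(structure, "", fixed = TRUE)[[1]]
  partner <- rep(NA_integer_, length(chars))
  stack <- integer(0)
  for (k in seq_along(chars)) {
    if (chars[k] == "(") stack <- c(stack, k)
    else if (chars[k] == ")") {
      i <- stack[length(stack)]
      stack <- stack[-length(stack)]
      partner[i] <- k
      partner[k] <- i
    }
  }
  partner
}

#' Parse a sequence and dot-bracket structure into a validated record
#'
#' Uppercases the sequence, maps T to U, and validates: equal lengths,
#' sequence alphabet A/C/G/U, structure alphabet `.()`, balanced and fully
#' nested brackets. Structures using pseudoknot bracket alphabets
#' (`[ ] { } < >`) are rejected with an explicit error rather than having
#' their crossing pairs dropped.
#'
#' @param sequence RNA (or DNA) sequence string.
#' @param structure dot-bracket string of the same length.
#' @param id record identifier.
#' @return A [DotBracketRecord-class].
#' @examples
#' parseDotBracket("GGGAAACCC", "(((...)))")
#' @export
parseDotBracket <- function(sequence, structure, id = "record") {
  stopifnot(is.character(sequence), is.character(structure),
            length(sequence) == 1L, length(structure) == 1L)
  seq <- chartr("tT", "uU", sequence)
  seq <- toupper(seq)
  rec <- new("DotBracketRecord", id = as.character(id), sequence = seq,
             structure = structure)
  validObject(rec)
  rec
}

#' Read a multi-record Vienna dot-bracket (.dbn) file
#'
#' Records are `>id` header lines followed by one sequence line and one
#' structure line; headerless files with alternating sequence/structure
#' lines are also accepted.
#'
#' @param path file path, or a character vector of lines via `text`.
#' @param text optional character vector of lines (overrides `path`).
#' @return A list of [DotBracketRecord-class] objects.
#' @export
readDotBracket <- function(path, text = NULL) {
  lines <- if (is.null(text)) readLines(path) else text
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  records <- list()
  k <- 1L
  counter <- 0L
  while (k <= length(lines)) {
    if (startsWith(lines[k], ">")) {
      id <- sub("^>\\s*", "", lines[k])
      if (k + 2L > length(lines))
        stop("truncated record '", id, "'")
      records[[length(records) + 1L]] <-
        parseDotBracket(lines[k + 1L], lines[k + 2L], id = id)
      k <- k + 3L
    } else {
      counter <- counter + 1L
      if (k + 1L > length(lines)) stop("dangling sequence line at end of file")
      records[[length(records) + 1L]] <-
        parseDotBracket(lines[k], lines[k + 1L],
                        id = paste0("record_", counter))
      k <- k + 2L
    }
  }
  records
}

#' Serialize records back to .dbn text
#'
#' @param records a [DotBracketRecord-class] or list of them.
#' @param path optional output file; when `NULL` the lines are returned.
#' @return Invisibly (or visibly when `path` is `NULL`) the text lines.
#' @export
writeDotBracket <- function(records, path = NULL) {
  if (is(records, "DotBracketRecord")) records <- list(records)
  lines <- unlist(lapply(records, function(r)
    c(paste0(">", r@id), r@sequence, r@structure)))
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

#' Identify all stems (maximal stacked helices) in a record
#'
#' A stem is a maximal run of consecutively stacked base pairs: pair
#' (i, j) is followed by (i + 1, j - 1). Every base pair belongs to exactly
#' one stem; a bulge or internal loop of any size breaks the run.
#'
#' @param record a [DotBracketRecord-class].
#' @return A list of [Stem-class] objects ordered by 5'-most residue.
#' @examples
#' findStems(parseDotBracket("GGAACC", "((..))"))
#' @export
findStems <- function(record) {
  stopifnot(is(record, "DotBracketRecord"))
  partner <- .pairTable(record@structure)
  opens <- which(!is.na(partner) & partner > seq_along(partner))
  stems <- list()
  used <- rep(FALSE, length(partner))
  for (i in opens) {
    if (used[i]) next
    j <- partner[i]
    run <- matrix(c(i, j), ncol = 2)
    while (TRUE) {
      ni <- run[nrow(run), 1] + 1L
      nj <- run[nrow(run), 2] - 1L
      if (ni < nj && !is.na(partner[ni]) && partner[ni] == nj) {
        run <- rbind(run, c(ni, nj))
      } else break
    }
    used[run[, 1]] <- TRUE
    chars <- strsplit(record@sequence, "", fixed = TRUE)[[1]]
    stems[[length(stems) + 1L]] <- new("Stem", pairs = run,
      seq5 = paste(chars[run[, 1]], collapse = ""),
      seq3 = paste(chars[run[, 2]], collapse = ""))
  }
  stems[order(vapply(stems, function(s) s@pairs[1, 1], numeric(1)))]
}

#' Extract every n-way junction from a record
#'
#' A junction is a loop closed on all sides by stems: an enclosing stem
#' whose innermost pair directly contains one or more enclosed stems, plus
#' the unpaired segments between them. Hairpin loops (no enclosed stem) and
#' the exterior loop (stems meeting at the molecule termini, where dangling
#' ends dominate the energetics) are not junctions and are excluded.
#' Internal loops and bulges are two-way junctions.
#'
#' @param record a [DotBracketRecord-class].
#' @return A list of [Junction-class] objects (possibly empty), identified
#'   as `<record id>_junction_<k>` in 5' order.
#' @examples
#' extractJunctions(parseDotBracket("GGAAGGAAACCAAGGAAACCAACC",
#'                                  "((..((...))..((...))..))"))
#' @export
extractJunctions <- function(record) {
  stopifnot(is(record, "DotBracketRecord"))
  stemList <- findStems(record)
  if (length(stemList) < 2L) return(list())
  chars <- strsplit(record@sequence, "", fixed = TRUE)[[1]]
  outermost <- t(vapply(stemList, function(s)
    c(s@pairs[1, 1], s@pairs[1, 2]), numeric(2)))
  innermost <- t(vapply(stemList, function(s)
    c(s@pairs[nrow(s@pairs), 1], s@pairs[nrow(s@pairs), 2]), numeric(2)))
  junctions <- list()
  for (s in seq_along(stemList)) {
    a <- innermost[s, 1]; b <- innermost[s, 2]
    inside <- which(outermost[, 1] > a & outermost[, 2] < b)
    if (!length(inside)) next  # hairpin loop
    # direct children: not nested inside another candidate
    direct <- inside[vapply(inside, function(t) {
      !any(outermost[inside, 1] < outermost[t, 1] &
           outermost[inside, 2] > outermost[t, 2])
    }, logical(1))]
    direct <- direct[order(outermost[direct, 1])]
    n <- 1L + length(direct)
    # loop segments: after outer's 5' half, between children, before 3' half
    bounds5 <- c(a, outermost[direct, 2])        # residue preceding each segment
    bounds3 <- c(outermost[direct, 1], b)        # residue following each segment
    segs <- vapply(seq_len(n), function(k) {
      lo <- bounds5[k] + 1L; hi <- bounds3[k] - 1L
      if (lo > hi) "" else paste(chars[lo:hi], collapse = "")
    }, character(1))
    entry <- c(b, outermost[direct, 1])
    exit <- c(a, outermost[direct, 2])
    # interface step between stem k and stem k+1 (cyclic):
    # top strand = exit residue of k then entry residue of k+1;
    # bottom strand = partners (entry of k, exit of k+1)
    nxt <- c(seq_len(n)[-1], 1L)
    steps <- vapply(seq_len(n), function(k) {
      paste0(chars[exit[k]], chars[entry[nxt[k]]], "/",
             chars[entry[k]], chars[exit[nxt[k]]])
    }, character(1))
    junctions[[length(junctions) + 1L]] <- new("Junction",
      sourceId = paste0(record@id, "_junction_", length(junctions) + 1L),
      order = n, stems = stemList[c(s, direct)], loopSegments = segs,
      proximalEntry = as.integer(entry), proximalExit = as.integer(exit),
      interfaceSteps = steps)
  }
  junctions
}

#' Decompose a junction into pseudo two-way junction samples
#'
#' An n-way junction (n >= 3) yields exactly n cyclically adjacent stem
#' pairs (H1-H2, H2-H3, ..., Hn-H1); a two-way junction yields its single
#' pair. Each pair carries its direct connecting loop (`loop0`), the
#' far-arc flanking segments (`loop1`, `loop2`), the interface
#' nearest-neighbor step, and the count of intervening stems (n - 2).
#'
#' @param junction a [Junction-class].
#' @return A list of [PseudoTwoWayJunction-class] objects.
#' @export
decomposeJunction <- function(junction) {
  stopifnot(is(junction, "Junction"))
  n <- junction@order
  npairs <- if (n == 2L) 1L else n
  prev <- function(i) if (i == 1L) n else i - 1L
  nxt <- function(i) if (i == n) 1L else i + 1L
  lapply(seq_len(npairs), function(i) {
    j <- nxt(i)
    new("PseudoTwoWayJunction",
        id = paste0(junction@sourceId, "_H", i, "-H", j),
        h1 = junction@stems[[i]], h2 = junction@stems[[j]],
        loop0 = junction@loopSegments[i],
        loop1 = junction@loopSegments[prev(i)],
        loop2 = junction@loopSegments[j],
        nIntervening = n - 2L, parentOrder = n,
        interfaceStep = junction@interfaceSteps[i],
        label = NA_integer_)
  })
}

#' Write junction descriptions as JSON
#'
#' Emits one object per junction: id, order, 1-based inclusive stem ranges
#' for both strands, and the loop segments.
#'
#' @param junctions list of [Junction-class] objects.
#' @param path output file, or `NULL` to return the JSON string.
#' @export
writeJunctionsJSON <- function(junctions, path = NULL) {
  payload <- lapply(junctions, function(j) {
    list(id = j@sourceId, order = j@order,
         stems = lapply(j@stems, function(s) {
           p <- s@pairs
           list(length_bp = nrow(p),
                five_prime_range = c(p[1, 1], p[nrow(p), 1]),
                three_prime_range = c(p[nrow(p), 2], p[1, 2]))
         }),
         loop_segments = as.list(j@loopSegments))
  })
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, pretty = TRUE)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}
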