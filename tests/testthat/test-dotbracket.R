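test_that("parsing validates and normalizes records", {
  r <- parseDotBracket("GGGAAACCC", "(((...)))")
  expect_s4_class(r, "DotBracketRecord")
  expect_identical(r@sequence, "GGGAAACCC")

  # T/lowercase are normalized to uppercase RNA
  r2 <- parseDotBracket("ggaatt", "((..))")
  expect_identical(r2@sequence, "GGAAUU")

  expect_error(parseDotBracket("GGAACC", "((..)"), "length")
  expect_error(parseDotBracket("GGAACC", "((..)."), "unbalanced")
  expect_error(parseDotBracket("GGAACC", ")(..()"), "unbalanced")
  expect_error(parseDotBracket("GGXACC", "((..))"), "A/C/G/U")
  expect_error(parseDotBracket("GGAACCAA", "((..))[]"), "pseudoknot")
})

test_that("dbn files round-trip byte-for-byte", {
  lines <- c(">hairpin", "GGGAAACCC", "(((...)))",
             ">twoway", "GGAAGGAAACCAACC", "((..((...))..))")
  recs <- readDotBracket(text = lines)
  expect_length(recs, 2)
  expect_identical(writeDotBracket(recs), lines)

  path <- withr::local_tempfile(fileext = ".dbn")
  writeDotBracket(recs, path)
  expect_identical(readLines(path), lines)
  expect_identical(writeDotBracket(readDotBracket(path)), lines)
})

test_that("stems are maximal stacked runs covering every pair once", {
  expect_length(findStems(parseDotBracket("GGAACC", "((..))")), 1)
  expect_equal(stemLength(findStems(parseDotBracket("GGAACC", "((..))"))[[1]]), 2)

  # manual enumeration: outer 2 bp + two inner 2 bp hairpin stems
  s3 <- findStems(parseDotBracket("GGAAGGAAACCAAGGAAACCAACC",
                                  "((..((...))..((...))..))"))
  expect_length(s3, 3)
  expect_equal(vapply(s3, stemLength, integer(1)), c(2L, 2L, 2L))

  # a bulge breaks the run: manual enumeration gives 2 stems
  s2 <- findStems(parseDotBracket("GAGGAAACCAC", "(.((...)).)"))
  expect_length(s2, 2)
  expect_equal(vapply(s2, stemLength, integer(1)), c(1L, 2L))

  # strand sequences follow the pair positions
  st <- findStems(parseDotBracket("GGACAAAGUCC", "((((...))))"))[[1]]
  expect_identical(st@seq5, "GGAC")
  expect_identical(st@seq3, "CCUG")
})

test_that("junction extraction finds closed loops only", {
  # internal loop = one two-way junction
  j2 <- extractJunctions(parseDotBracket("GGAAGGAAACCAACC", "((..((...))..))"))
  expect_length(j2, 1)
  expect_equal(junctionOrder(j2[[1]]), 2)
  expect_identical(loopSegments(j2[[1]]), c("AA", "AA"))

  # three-way junction from the two-hairpin layout
  j3 <- extractJunctions(parseDotBracket("GGAAGGAAACCAAGGAAACCAACC",
                                         "((..((...))..((...))..))"))
  expect_length(j3, 1)
  expect_equal(junctionOrder(j3[[1]]), 3)

  # hairpin-only and exterior-loop stems yield no junctions
  expect_length(extractJunctions(parseDotBracket("GGGAAACCC", "(((...)))")), 0)
  expect_length(extractJunctions(
    parseDotBracket("GGAAACCAAGGAAACC", "((...))..((...))")), 0)
})

test_that("bulge two-way junctions have one empty loop segment", {
  j <- extractJunctions(parseDotBracket("GAGGAAACCC", "(.((...)))"))
  expect_length(j, 1)
  expect_equal(junctionOrder(j[[1]]), 2)
  expect_identical(loopSegments(j[[1]]), c("A", ""))
})

test_that("decomposition yields n cyclically adjacent pairs (1 for n = 2)", {
  j3 <- extractJunctions(parseDotBracket("GGAAGGAAACCAAGGAAACCAACC",
                                         "((..((...))..((...))..))"))[[1]]
  p3 <- decomposeJunction(j3)
  expect_length(p3, 3)
  expect_identical(vapply(p3, function(p) p@id, character(1)),
                   paste0(j3@sourceId, c("_H1-H2", "_H2-H3", "_H3-H1")))
  expect_true(all(vapply(p3, function(p) p@nIntervening, integer(1)) == 1L))

  # two-way: a single pair whose far-arc segments coincide (L1 = L2 loop)
  j2 <- extractJunctions(parseDotBracket("GGAAGGAAACCAUCC",
                                         "((..((...))..))"))[[1]]
  p2 <- decomposeJunction(j2)
  expect_length(p2, 1)
  expect_identical(p2[[1]]@loop0, "AA")
  expect_identical(p2[[1]]@loop1, p2[[1]]@loop2)
  expect_identical(p2[[1]]@loop1, "AU")

  # four-way: 4 pairs, each with two intervening stems on the far arc
  rec4 <- parseDotBracket("GGAAGGAAACCAAGGAAACCAAGGAAACCAACC",
                          "((..((...))..((...))..((...))..))")
  j4 <- extractJunctions(rec4)[[1]]
  expect_equal(junctionOrder(j4), 4)
  p4 <- decomposeJunction(j4)
  expect_length(p4, 4)
  expect_true(all(vapply(p4, function(p) p@nIntervening, integer(1)) == 2L))
})

test_that("interface steps read the closing pairs along the loop", {
  # ((..((...))..)) : outer proximal pair G2-C14, inner proximal G5-C11
  j <- extractJunctions(parseDotBracket("GGAAGGAAACCAUCC",
                                        "((..((...))..))"))[[1]]
  # step H1->H2: top = exit(outer)=G2, entry(inner)=G5; bottom = C14, C11
  expect_identical(j@interfaceSteps[1], "GG/CC")
})

test_that("residue conservation and disjointness hold on generated records", {
  cfg <- syntheticConfig(nJunctions = 25, seed = 421)
  d <- generateDataset(cfg)
  for (rec in d$records) {
    stems <- findStems(rec)
    bp <- sum(vapply(stems, stemLength, integer(1)))
    unpaired <- sum(strsplit(rec@structure, "")[[1]] == ".")
    expect_equal(2 * bp + unpaired, nchar(rec@sequence))
    # every paired residue belongs to exactly one stem
    resid <- unlist(lapply(stems, function(s) as.vector(s@pairs)))
    expect_false(anyDuplicated(resid) > 0)
  }
  for (j in d$junctions) {
    n <- junctionOrder(j)
    expect_length(decomposeJunction(j), if (n == 2) 1L else n)
    # loop segments and stem residues are disjoint
    stemRes <- unlist(lapply(stems(j), function(s) as.vector(s@pairs)))
    loopLen <- sum(nchar(loopSegments(j)))
    expect_true(loopLen >= 0)
    expect_false(anyDuplicated(stemRes) > 0)
  }
})
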