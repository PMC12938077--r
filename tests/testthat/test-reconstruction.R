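test_that("cycle graphs apply the strict retention filter", {
  g <- buildCycleGraph(c(0.9, 0.5, 0.43), threshold = 0.42)
  expect_equal(junctionOrder(g), 3)
  expect_true(all(g@retained))

  g4 <- buildCycleGraph(c(0.9, 0.8, 0.85, 0.10), threshold = 0.42)
  expect_equal(sum(g4@retained), 3)

  # a probability exactly at the threshold is excluded (strict inequality)
  gx <- buildCycleGraph(c(0.42, 0.9, 0.1), threshold = 0.42)
  expect_identical(gx@retained, c(FALSE, TRUE, FALSE))
  # exactly two pair predictions cannot arise from any junction order
  expect_error(buildCycleGraph(c(0.5, 0.6)), "inconsistent")

  # two-way junction: a single candidate edge
  g2 <- buildCycleGraph(0.7)
  expect_equal(junctionOrder(g2), 2)
  expect_length(g2@weights, 1)

  expect_error(buildCycleGraph(numeric(0)), "no pair predictions")
  expect_error(buildCycleGraph(c(0.5, NA, 0.2)), "missing")
  dup <- data.frame(pair_id = c("a", "a"), probability = c(0.5, 0.6))
  expect_error(buildCycleGraph(dup), "duplicate")
})

test_that("matching solves the printed examples exactly", {
  # triangle: any two edges share a stem, so the best single edge wins
  m3 <- maxWeightMatchingCycle(buildCycleGraph(c(0.9, 0.5, 0.43)))
  expect_equal(stackedPairs(m3), rbind(c(1L, 2L)))
  expect_equal(m3@totalWeight, 0.9)

  # 4-cycle with e41 filtered out: the two disjoint edges e12 + e34 win
  m4 <- maxWeightMatchingCycle(buildCycleGraph(c(0.9, 0.8, 0.85, 0.10)))
  expect_equal(stackedPairs(m4), rbind(c(1L, 2L), c(3L, 4L)))
  expect_equal(m4@totalWeight, 1.75)

  # nothing retained: the explicit no-stacking configuration
  m0 <- maxWeightMatchingCycle(buildCycleGraph(c(0.1, 0.2, 0.3)))
  expect_equal(nrow(stackedPairs(m0)), 0)
  expect_equal(m0@totalWeight, 0)
  expect_identical(configurationLabel(m0), "no stacking")

  # two-way: the single edge iff retained
  expect_equal(nrow(stackedPairs(maxWeightMatchingCycle(buildCycleGraph(0.9)))), 1)
  expect_equal(nrow(stackedPairs(maxWeightMatchingCycle(buildCycleGraph(0.3)))), 0)
})

test_that("the cycle DP agrees with the exhaustive oracle", {
  set.seed(1234)
  for (trial in 1:400) {
    n <- sample(2:10, 1)
    g <- randomCycleGraph(n, threshold = runif(1, 0, 0.9))
    a <- maxWeightMatchingCycle(g)
    b <- bruteForceMatching(g)
    expect_equal(a@totalWeight, b@totalWeight)
    expect_identical(stackedPairs(a), stackedPairs(b))
    # vertex-disjointness of the result (validity invariant)
    expect_true(validObject(a))
  }
})

test_that("equal-weight ties break to fewer edges, then lexicographic", {
  # all weights equal on a 5-cycle: a single edge beats none (weight), and
  # among single-edge optima e1 is lexicographically first; among the
  # equal-weight two-edge matchings {e1,e3} is preferred over {e1,e4}
  g <- buildCycleGraph(rep(0.5, 5), threshold = 0.1)
  m <- maxWeightMatchingCycle(g)
  b <- bruteForceMatching(g)
  expect_identical(stackedPairs(m), stackedPairs(b))
  expect_equal(m@totalWeight, 1.0)
  expect_equal(stackedPairs(m), rbind(c(1L, 2L), c(3L, 4L)))

  # a single retained edge is simply returned
  g1 <- buildCycleGraph(c(0.9, 0.1, 0.1), threshold = 0.42)
  expect_equal(stackedPairs(bruteForceMatching(g1)), rbind(c(1L, 2L)))
})

test_that("configuration spaces have the printed sizes and follow the recurrence", {
  expect_length(enumerateConfigurations(2), 2)
  expect_length(enumerateConfigurations(3), 4)
  expect_length(enumerateConfigurations(4), 7)

  # three-way: the three single stacks plus no stacking
  labs3 <- sort(vapply(enumerateConfigurations(3), configurationLabel,
                       character(1)))
  expect_identical(labs3, sort(c("H1-H2", "H2-H3", "H1-H3", "no stacking")))

  # four-way: four single stacks, two disjoint double stacks, none
  cfg4 <- enumerateConfigurations(4)
  sizes <- vapply(cfg4, function(cf) nrow(stackedPairs(cf)), integer(1))
  expect_identical(as.integer(table(sizes)), c(1L, 4L, 2L))
  labs4 <- vapply(cfg4, configurationLabel, character(1))
  expect_true(all(c("H1-H2 & H3-H4", "H1-H4 & H2-H3") %in% labs4))

  # counts up to order 10 match the cycle-matching recurrence
  for (n in 2:10)
    expect_length(enumerateConfigurations(n), cycleMatchingCountOracle(n))

  expect_error(enumerateConfigurations(1), "between 2 and 12")
  expect_error(enumerateConfigurations(13), "between 2 and 12")
})

test_that("raising the threshold never adds retained or selected edges", {
  set.seed(55)
  for (trial in 1:50) {
    n <- sample(3:8, 1)
    w <- runif(n)
    thresholds <- sort(runif(5))
    retained <- selected <- integer(0)
    for (t in thresholds) {
      g <- buildCycleGraph(w, threshold = t)
      retained <- c(retained, sum(g@retained))
      selected <- c(selected, nrow(stackedPairs(maxWeightMatchingCycle(g))))
    }
    expect_true(all(diff(retained) <= 0))
    expect_true(all(diff(selected) <= 0))
  }
})

test_that("the junction pipeline produces a coherent JSON report", {
  cfg <- syntheticConfig(nJunctions = 30, seed = 3)
  d <- generateDataset(cfg)
  m <- trainStackingForest(d$features,
                           hp = stackingHyperparameters(nTrees = 80, seed = 2))
  res <- lapply(d$junctions[1:5], function(j)
    predictJunctionStacking(m, j))
  for (k in seq_along(res)) {
    expect_s4_class(res[[k]]$configuration, "StackingConfiguration")
    expect_equal(res[[k]]$configuration@order,
                 junctionOrder(d$junctions[[k]]))
    expect_equal(nrow(res[[k]]$predictions),
                 length(decomposeJunction(d$junctions[[k]])))
  }
  js <- jsonlite::fromJSON(writeStackingJSON(res), simplifyVector = FALSE)
  expect_length(js, 5)
  expect_identical(js[[1]]$id, d$junctions[[1]]@sourceId)
})
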