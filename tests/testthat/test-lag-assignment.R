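test_that("default maximum lag is a quarter of the timepoints, capped for overlap", {
  expect_equal(defaultMaxLag(10), 2L)
  expect_equal(defaultMaxLag(13), 3L)
  expect_equal(defaultMaxLag(4), 1L)
  expect_equal(defaultMaxLag(3), 0L)  # no lag possible below four timepoints
  expect_equal(defaultMaxLag(9, minOverlap = 6), 1L)  # overlap cap binds
})

test_that("identical profiles prefer lag 0 with score 1", {
  y <- rbind(a = c(1, 5, 2, 8, 3, 9, 4, 1), b = c(1, 5, 2, 8, 3, 9, 4, 1))
  tss <- TimeSeriesSet(y, 0:7)
  best <- pairwiseBestLag(tss, "a", "b", C = 50, maxLag = 2)
  expect_equal(best$lag, 0L)
  expect_equal(best$score, 1, tolerance = 1e-12)
})

test_that("a one-index shift is recovered as a unit lag", {
  # gene b equals gene a shifted one index later: lagging a by +1 aligns them
  base <- c(0, 0, 6, 0, 0, 0, 0, 0)
  y <- rbind(a = base, b = c(0, base[-8]))
  tss <- TimeSeriesSet(y + 0.01 * sin(1:8), 0:7)  # break exact constancy
  best <- pairwiseBestLag(tss, "a", "b", C = 500, maxLag = 2)
  expect_equal(best$lag, 1L)
  # returned score equals an explicit enumeration over all candidate lags
  scores <- vapply(-2:2, function(k)
    lpwcCorrelation(tss, "a", "b", k, 0, C = 500), numeric(1))
  expect_equal(best$score, max(scores), tolerance = 1e-12)
})

test_that("neighbors voting for a lag with positive scores carry the argmax", {
  # genes b and c are copies of gene a shifted one index later on a uniform
  # grid; both vote lag +1 for gene a, so the indicator-weighted sum selects +1
  spike <- c(0, 5, 0, 0, 0, 0, 0, 0)
  shifted <- c(0, 0, 5, 0, 0, 0, 0, 0)
  y <- rbind(a = spike, b = shifted, c = shifted)
  set.seed(31)
  y <- y + matrix(rnorm(24, sd = 0.01), 3)
  tss <- TimeSeriesSet(y, 0:7)
  lagsOut <- assignLagsHeuristic(tss, C = 500, maxLag = 2)
  expect_equal(lagsOut[1], 1L)
  expect_equal(lagsOut[2], 0L)
  expect_equal(lagsOut[3], 0L)
})

test_that("identical genes all receive lag 0", {
  y <- matrix(rep(c(1, 4, 2, 8, 3, 7, 5, 6), times = 4), 4, byrow = TRUE)
  tss <- TimeSeriesSet(y, 0:7)
  expect_equal(assignLagsHeuristic(tss, C = 100, maxLag = 2), rep(0L, 4))
})

test_that("lag assignment is deterministic", {
  tss <- randomTimeSeries(12, seed = 32)
  C <- solveHighPenaltyC(timepoints(tss), 2)
  expect_identical(assignLagsHeuristic(tss, C),
                   assignLagsHeuristic(tss, C))
})

test_that("with all lags zero the similarity matrix is the Pearson matrix", {
  tss <- randomTimeSeries(9, seed = 33)
  S <- lpwcSimilarityMatrix(tss, rep(0L, 9), C = 306)
  expect_equal(unname(S), unname(cor(t(exprMatrix(tss)))), tolerance = 1e-12)
})

test_that("pairs with insufficient overlap fall back to zero-lag similarity", {
  tss <- randomTimeSeries(4, timepoints = c(0, 1, 3, 8), seed = 34)
  # lags (-1, +1) on 4 timepoints leave 2 points; force minOverlap = 3
  expect_warning(
    S <- lpwcSimilarityMatrix(tss, c(-1L, 1L, 0L, 0L), C = 20, minOverlap = 3),
    "insufficient overlap")
  y <- exprMatrix(tss)
  expect_equal(S[1, 2], cor(y[1, ], y[2, ]), tolerance = 1e-12)
})

test_that("the heuristic never beats the exact optimum on small problems", {
  for (seed in 41:46) {
    tss <- randomTimeSeries(4, timepoints = c(0, 2, 4, 7, 11, 16, 22, 30),
                            seed = seed)
    C <- solveHighPenaltyC(timepoints(tss), 1)
    inst <- exactInstanceFromData(tss, C, maxLag = 1)
    heur <- assignLagsHeuristic(tss, C, maxLag = 1)
    exact <- solveLagsExact(inst)
    expect_lte(lagObjective(inst, heur), exact$objective + 1e-12)
    # the heuristic assignment is always feasible for the exact problem
    expect_true(all(heur %in% inst@lagSet))
  }
})
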