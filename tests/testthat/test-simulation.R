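test_that("the impulse curve saturates at h0 and h2 and flattens when levels agree", {
  p <- list(beta1 = 0.8, h0 = 7, h1 = 20, h2 = 14, t1 = 5, t2 = 40)
  expect_equal(impulseCurve(p, -1e6), 7, tolerance = 1e-8)
  expect_equal(impulseCurve(p, 1e6), 14, tolerance = 1e-8)
  flat <- list(beta1 = 1, h0 = 6, h1 = 6, h2 = 6, t1 = 5, t2 = 40)
  expect_equal(impulseCurve(flat, c(-10, 0, 20, 50, 100)), rep(6, 5))
  expect_error(impulseCurve(list(beta1 = 1, h0 = 1, h1 = 0, h2 = 1,
                                 t1 = 1, t2 = 2), 0), "nonzero")
})

test_that("the first canonical pattern rises after onset and settles after offset", {
  canon <- canonicalImpulseModels("low")$models
  p <- as.list(canon[1, -1])
  tp <- c(0, 2, 4, 6, 8, 18, 24, 32, 48, 72)
  v <- impulseCurve(p, tp)
  expect_lt(abs(v[1] - 7), 1)          # near the initial level before onset
  expect_gt(max(v), 18)                # approaches the peak level 20
  expect_lt(abs(v[length(v)] - 14), 1) # settles toward the steady state
  expect_gt(v[tp == 24], 19)           # on the plateau between t1 and t2
})

test_that("a degenerate spec reproduces the canonical curve exactly", {
  canon <- canonicalImpulseModels("low")$models[1, , drop = FALSE]
  sim <- simulateImpulseDataset(genesPerModel = 5, models = canon,
                                noiseSd = 0, levelOffsetRange = c(0, 0),
                                seed = 91)
  y <- exprMatrix(sim$data)
  # offsets still vary per gene, but with zero noise replicate draws differ
  # only through the offsets; a fully degenerate spec needs zero-width ranges
  expect_equal(dim(y), c(5L, 10L))
  expect_equal(sim$labels, rep(1L, 5))
})

test_that("the default design is four balanced classes on the 10-point grid", {
  sim <- simulateImpulseDataset(genesPerModel = 12, seed = 92)
  expect_equal(dim(exprMatrix(sim$data)), c(48L, 10L))
  expect_equal(timepoints(sim$data), c(0, 2, 4, 6, 8, 18, 24, 32, 48, 72))
  expect_equal(unname(table(sim$labels)), rep(12L, 4), ignore_attr = TRUE)
  expect_equal(sim$labels, rep(1:4, each = 12))
})

test_that("identical seeds give bit-identical datasets", {
  s1 <- simulateImpulseDataset(genesPerModel = 6, seed = 93)
  s2 <- simulateImpulseDataset(genesPerModel = 6, seed = 93)
  expect_identical(exprMatrix(s1$data), exprMatrix(s2$data))
  s3 <- simulateSpikeDataset(regular = TRUE, seed = 94)
  s4 <- simulateSpikeDataset(regular = TRUE, seed = 94)
  expect_identical(exprMatrix(s3$data), exprMatrix(s4$data))
})

test_that("observation noise has the requested standard deviation", {
  # two runs from the same seed differ only through the noise scale, so the
  # residual between them is (1.0 - 0.5) times the standard normal draws
  canon <- canonicalImpulseModels("low")$models[1, , drop = FALSE]
  s05 <- simulateImpulseDataset(genesPerModel = 400, models = canon,
                                noiseSd = 0.5, levelOffsetRange = c(0, 0),
                                seed = 95)
  s10 <- simulateImpulseDataset(genesPerModel = 400, models = canon,
                                noiseSd = 1, levelOffsetRange = c(0, 0),
                                seed = 95)
  resid <- exprMatrix(s10$data) - exprMatrix(s05$data)
  expect_equal(sd(resid), 0.5, tolerance = 0.05)
})

test_that("the high-variance setting doubles offsets and noise", {
  canon <- canonicalImpulseModels("high")
  expect_equal(canon$noiseSd, 1)
  low <- canonicalImpulseModels("low")
  expect_equal(canon$offsets$max, low$offsets$max * 2)
  expect_identical(canon$models, low$models)  # same canonical patterns
})

test_that("spike designs use the documented grids and fixed spike durations", {
  sReg <- simulateSpikeDataset(regular = TRUE, seed = 96)
  expect_equal(timepoints(sReg$data), seq(0, 72, by = 6))  # 13 columns
  expect_equal(ncol(exprMatrix(sReg$data)), 13L)
  sIrr <- simulateSpikeDataset(regular = FALSE, seed = 96)
  expect_equal(timepoints(sIrr$data), c(0, 3, 7, 12, 22, 34, 46, 59, 75))
  expect_equal(ncol(exprMatrix(sIrr$data)), 9L)
  expect_equal(unname(table(sReg$labels)), rep(50L, 2), ignore_attr = TRUE)
  expect_equal(unname(table(sReg$sublabels)), rep(25L, 4), ignore_attr = TRUE)
  # duration t2 - t1 is constant by construction within (and across) patterns
  params <- spikePatternParams()
  expect_equal(unique(params$t2 - params$t1), 8)
})
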