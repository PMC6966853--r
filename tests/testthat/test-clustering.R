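test_that("the distance transform maps [-1, 1] to [0, 2]", {
  S <- matrix(c(1, -1, 0.5, -1, 1, 0, 0.5, 0, 1), 3)
  D <- similarityToDistance(S)
  expect_equal(D[1, 2], 2)
  expect_equal(D[1, 3], 0.5)
  expect_equal(unname(diag(D)), rep(0, 3))
  set.seed(71)
  R <- matrix(runif(49, -1, 1), 7); R <- (R + t(R)) / 2; diag(R) <- 1
  DR <- similarityToDistance(R)
  expect_true(all(DR >= 0 & DR <= 2))
  expect_error(similarityToDistance(matrix(c(1, 1.5, 1.5, 1), 2)),
               "must lie in")
})

test_that("well-separated blocks are recovered and k = N gives singletons", {
  y <- rbind(matrix(rep(c(1, 5, 2, 8, 3), each = 3), 3),
             matrix(rep(c(8, 2, 7, 1, 6), each = 3), 3))
  y <- y + matrix(seq(-0.01, 0.01, length.out = 30), 6)  # break exact ties
  D <- as.matrix(dist(y))
  res <- hierarchicalCluster(D, 2)
  expect_equal(res$labels[1:3], rep(res$labels[1], 3))
  expect_equal(res$labels[4:6], rep(res$labels[4], 3))
  expect_true(res$labels[1] != res$labels[4])
  expect_equal(sort(hierarchicalCluster(D, 6)$labels), 1:6)
  expect_error(hierarchicalCluster(D, 7), "between 1 and")
})

test_that("silhouette selection finds planted cluster counts", {
  models <- data.frame(beta1 = c(0.8, 1.5, 1.2), h0 = c(2, 18, 8),
                       h1 = c(20, 4, 9), h2 = c(5, 12, 25),
                       t1 = c(5, 12, 25), t2 = c(30, 40, 55))
  sim <- simulateImpulseDataset(genesPerModel = 8, models = models,
                                noiseSd = 0.2, levelOffsetRange = c(0, 1),
                                seed = 72)
  res <- lpwc(sim$data, penalty = "high", k = "auto")
  expect_equal(res@k, 3L)
  expect_true(all(res@silhouetteWidths >= -1 & res@silhouetteWidths <= 1))
  expect_equal(adjustedRandIndex(clusterLabels(res), sim$labels), 1)
})

test_that("silhouette ties and ranges are policed", {
  D <- as.matrix(dist(matrix(rnorm(10), 5)))
  expect_error(selectKSilhouette(D, kMin = 1), "kMin")
  expect_error(selectKSilhouette(D, kMin = 2, kMax = 5), "kMax")
})

test_that("zero lags reduce the pipeline to Pearson hierarchical clustering", {
  tss <- randomTimeSeries(15, seed = 73)
  res <- lpwc(tss, penalty = "high", maxLag = 0, k = 3)
  base <- baselineCluster(tss, "pearson_hier", k = 3)
  expect_equal(adjustedRandIndex(clusterLabels(res), base), 1)
  expect_equal(unname(similarityMatrix(res)), unname(cor(t(exprMatrix(tss)))),
               tolerance = 1e-12)
})

test_that("cluster labels are permutation-invariant under relabeling", {
  tss <- randomTimeSeries(10, seed = 74)
  res <- lpwc(tss, penalty = "high", k = 3)
  relabeled <- c(3L, 1L, 2L)[clusterLabels(res)]
  expect_equal(adjustedRandIndex(clusterLabels(res), relabeled), 1)
})

test_that("results are written and round-trip through the output files", {
  tss <- randomTimeSeries(8, seed = 75)
  res <- lpwc(tss, penalty = "high", k = 2)
  outdir <- withr::local_tempdir()
  paths <- writeResults(res, outdir)
  clusters <- read.delim(file.path(outdir, "clusters.tsv"))
  expect_equal(nrow(clusters), 8)
  expect_equal(clusters$cluster, clusterLabels(res))
  expect_equal(clusters$lag, lags(res))
  sim <- read.delim(file.path(outdir, "similarity.tsv"), check.names = FALSE)
  expect_equal(as.matrix(sim[, -1]), similarityMatrix(res),
               tolerance = 1e-12, ignore_attr = TRUE)
  info <- read.delim(file.path(outdir, "run_info.tsv"))
  expect_equal(as.numeric(info$value[info$key == "C"]), penaltyC(res),
               tolerance = 1e-12)
})
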