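#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two clusterings of the same items
#' (Hubert-Arabie form): 1 for identical partitions up to relabeling,
#' expectation about 0 for independent random partitions.
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return The adjusted Rand index.
#' @examples
#' adjustedRandIndex(c(1, 1, 2, 2), c("x", "x", "y", "y"))  # 1
#' @export
adjustedRandIndex <- function(a, b) {
  if (length(a) != length(b))
    stop("label vectors must have equal length", call. = FALSE)
  mclust::adjustedRandIndex(a, b)
}

#' Randomly permute the timepoint columns of a dataset
#'
#' Reorders the columns of the expression matrix by a uniformly random
#' permutation while leaving the timepoint vector in its original order, so
#' the observed values are preserved but their temporal structure is
#' destroyed.  Used to probe whether a clustering algorithm actually exploits
#' timing: methods that ignore it return identical clusters on permuted data.
#'
#' @param tss a [TimeSeriesSet-class].
#' @param perm optional explicit permutation of \code{seq_len(ncol(tss))};
#'   drawn uniformly from the session RNG when \code{NULL}.
#' @return A new [TimeSeriesSet-class] with shuffled expression columns and
#'   the original timepoints.
#' @export
permuteTimepoints <- function(tss, perm = NULL) {
  y <- exprMatrix(tss)
  if (is.null(perm)) perm <- sample.int(ncol(y))
  stopifnot(length(perm) == ncol(y), !anyDuplicated(perm))
  TimeSeriesSet(y[, perm, drop = FALSE], timepoints(tss),
                ids = rownames(y))
}

#' Timepoint-permutation stability of a clustering function
#'
#' Clusters the original dataset once, then repeatedly permutes the timepoint
#' columns, re-clusters, and records the adjusted Rand index between the
#' original and permuted-data labels.  Timing-insensitive algorithms (plain
#' Euclidean or Pearson clustering) score 1 on every permutation; an
#' algorithm that exploits temporal structure scores below 1 whenever its
#' lags or alignments react to the shuffling.  High scores throughout are
#' therefore a warning sign, not a virtue.
#'
#' @param tss a [TimeSeriesSet-class].
#' @param clusterFun function mapping a TimeSeriesSet to a label vector (with
#'   whatever k it fixes internally).
#' @param nPermutations number of random permutations (default 100).
#' @param seed optional integer seed for reproducibility.
#' @return A list with \code{ari} (numeric vector, one ARI per permutation),
#'   \code{labels} (the original-data labels), and a \code{summary} row with
#'   the median ARI and the fraction above 0.75.
#' @export
permutationStability <- function(tss, clusterFun, nPermutations = 100L,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  labels0 <- clusterFun(tss)
  ari <- vapply(seq_len(nPermutations), function(p) {
    adjustedRandIndex(labels0, clusterFun(permuteTimepoints(tss)))
  }, numeric(1))
  list(ari = ari, labels = labels0,
       summary = data.frame(median = stats::median(ari),
                            fractionAbove0.75 = mean(ari > 0.75)))
}

#' Timing-agnostic baseline clusterings
#'
#' The four standard baselines used to contrast lag-aware clustering:
#' hierarchical clustering (complete linkage) on Euclidean distances or on
#' Pearson-correlation distances (1 - r), and kmeans on the raw profiles
#' (Euclidean) or on row-standardized profiles (correlation-like).  All four
#' ignore the order of the timepoint columns.
#'
#' @param tss a [TimeSeriesSet-class].
#' @param method one of "euclidean_hier", "pearson_hier", "euclidean_kmeans",
#'   "pearson_kmeans".
#' @param k number of clusters.
#' @param nstart random restarts for the kmeans variants (default 10).
#' @return Integer label vector.
#' @export
baselineCluster <- function(tss, method = c("euclidean_hier", "pearson_hier",
                                            "euclidean_kmeans",
                                            "pearson_kmeans"),
                            k, nstart = 10L) {
  method <- match.arg(method)
  y <- exprMatrix(tss)
  switch(method,
    euclidean_hier = hierarchicalCluster(stats::dist(y), k)$labels,
    pearson_hier = hierarchicalCluster(1 - stats::cor(t(y)), k)$labels,
    euclidean_kmeans = unname(stats::kmeans(y, centers = k,
                                            nstart = nstart)$cluster),
    pearson_kmeans = {
      ys <- t(scale(t(y)))
      ys[is.nan(ys)] <- 0  # constant rows standardize to 0
      unname(stats::kmeans(ys, centers = k, nstart = nstart)$cluster)
    })
}
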