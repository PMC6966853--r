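#' Transform a similarity matrix to distances
#'
#' \eqn{dist(i, j) = 1 - corr(i, j)}, mapping similarities in [-1, 1] to
#' distances in [0, 2]: perfectly correlated pairs are at distance 0,
#' perfectly anticorrelated pairs at distance 2.
#'
#' @param S symmetric similarity matrix with entries in [-1, 1].
#' @return Symmetric distance matrix with zero diagonal and entries in
#'   [0, 2].
#' @export
similarityToDistance <- function(S) {
  S <- as.matrix(S)
  if (any(S < -1 - 1e-8) || any(S > 1 + 1e-8))
    stop("similarities must lie in [-1, 1]", call. = FALSE)
  D <- 1 - S
  D[D < 0] <- 0
  D[D > 2] <- 2
  diag(D) <- 0
  D
}

#' Complete-linkage hierarchical clustering of a precomputed distance matrix
#'
#' @param D symmetric distance matrix (or \code{dist}).
#' @param k number of clusters to cut the dendrogram into, \code{1 <= k <= N}.
#' @return A list with \code{labels} (integer vector, values 1..k) and
#'   \code{hclust} (the full \code{stats::hclust} tree).
#' @export
hierarchicalCluster <- function(D, k) {
  d <- stats::as.dist(D)
  n <- attr(d, "Size")
  if (k < 1 || k > n)
    stop("k must be between 1 and the number of genes (", n, ")",
         call. = FALSE)
  hc <- stats::hclust(d, method = "complete")
  list(labels = unname(stats::cutree(hc, k = k)), hclust = hc)
}

#' Choose the number of clusters by average silhouette width
#'
#' Cuts the complete-linkage dendrogram at each candidate \code{k} and scores
#' the partition by the average silhouette width; the maximizing \code{k} is
#' returned, preferring the smaller \code{k} on ties (parsimony).
#'
#' @param D symmetric distance matrix.
#' @param kMin,kMax candidate range; defaults to 2..min(10, N-1).
#' @return A list with \code{k} (the selected number of clusters) and
#'   \code{widths} (named numeric vector of average silhouette widths, one
#'   per candidate \code{k}).
#' @export
selectKSilhouette <- function(D, kMin = 2L, kMax = NULL) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n < 3L) stop("at least 3 genes are required to scan k", call. = FALSE)
  if (is.null(kMax)) kMax <- min(10L, n - 1L)
  if (kMin < 2L || kMax > n - 1L || kMin > kMax)
    stop("need 2 <= kMin <= kMax <= N - 1", call. = FALSE)
  hc <- stats::hclust(stats::as.dist(D), method = "complete")
  ks <- seq.int(kMin, kMax)
  widths <- vapply(ks, function(k) {
    sil <- cluster::silhouette(stats::cutree(hc, k = k), dmatrix = D)
    mean(sil[, "sil_width"])
  }, numeric(1))
  names(widths) <- ks
  list(k = ks[which.max(widths)], widths = widths)
}

#' Lag-penalized weighted correlation clustering
#'
#' The full pipeline: resolve the penalty parameter \code{C} (high-penalty
#' criterion, low-penalty stability sweep, or a fixed user value), assign one
#' lag per gene with the greedy heuristic, build the penalized similarity
#' matrix, transform to distances and cluster hierarchically with complete
#' linkage.  The number of clusters is chosen by average silhouette width
#' unless fixed by the caller.  When no lags are selected the result is
#' identical to ordinary Pearson-correlation hierarchical clustering.
#'
#' @param tss a [TimeSeriesSet-class].
#' @param penalty "high" (solve the mean-penalty-0.5 criterion; the default),
#'   "low" (stability sweep over penalty targets 0.50..0.95), or "fixed"
#'   (use \code{C} as given).
#' @param C penalty parameter; required when \code{penalty = "fixed"},
#'   ignored otherwise.
#' @param maxLag maximum lag magnitude; default [defaultMaxLag()] of the
#'   number of timepoints.
#' @param k number of clusters, or "auto" to select by silhouette.
#' @param kRange candidate range scanned when \code{k = "auto"}.
#' @param minOverlap smallest usable alignment length (default 2).
#' @return A [LagClustResult-class].
#' @examples
#' sim <- simulateImpulseDataset(genesPerModel = 10, seed = 1)
#' res <- lpwc(sim$data, penalty = "high", k = 4)
#' table(clusterLabels(res), sim$labels)
#' @export
lpwc <- function(tss, penalty = c("high", "low", "fixed"), C = NULL,
                 maxLag = NULL, k = "auto", kRange = NULL, minOverlap = 2L) {
  penalty <- match.arg(penalty)
  tp <- timepoints(tss)
  n <- nrow(tss)
  if (is.null(maxLag)) maxLag <- defaultMaxLag(length(tp), minOverlap)
  maxLag <- as.integer(maxLag)
  sweepDiag <- data.frame(target = numeric(0), C = numeric(0),
                          stability = numeric(0))
  if (penalty == "low") {
    sw <- lowPenaltySweep(tss, maxLag, minOverlap)
    C <- sw$C
    geneLags <- sw$lags
    S <- sw$similarity
    sweepDiag <- sw$diagnostics
  } else {
    if (penalty == "high") {
      C <- if (maxLag >= 1L) solveHighPenaltyC(tp, maxLag) else 1
    } else if (is.null(C) || C <= 0) {
      stop("penalty = \"fixed\" requires a positive C", call. = FALSE)
    }
    geneLags <- assignLagsHeuristic(tss, C, maxLag, minOverlap)
    S <- lpwcSimilarityMatrix(tss, geneLags, C, minOverlap)
  }
  D <- similarityToDistance(S)
  widths <- numeric(0)
  if (identical(k, "auto")) {
    if (is.null(kRange)) kRange <- c(2L, min(10L, n - 1L))
    sel <- selectKSilhouette(D, kRange[1L], kRange[2L])
    k <- sel$k
    widths <- sel$widths
  }
  k <- as.integer(k)
  hcres <- hierarchicalCluster(D, k)
  methods::new("LagClustResult", lags = as.integer(geneLags), similarity = S,
               penaltyC = C, penaltyMode = penalty, maxLag = maxLag,
               labels = as.integer(hcres$labels), k = k,
               silhouetteWidths = widths, hclust = hcres$hclust,
               sweep = sweepDiag)
}
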