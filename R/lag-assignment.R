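#' Default maximum lag
#'
#' One quarter of the number of timepoints (rounded down), additionally capped
#' so that the most extreme lag pair \eqn{(-m, +m)} still retains at least
#' \code{minOverlap} aligned timepoints.  Four timepoints are needed before a
#' single lag is allowed; with three or fewer the maximum lag is 0.
#'
#' @param nTimepoints number of observed timepoints.
#' @param minOverlap smallest usable alignment length (default 2).
#' @return A nonnegative integer maximum lag.
#' @examples
#' defaultMaxLag(10)  # 2
#' defaultMaxLag(4)   # 1
#' defaultMaxLag(3)   # 0
#' @export
defaultMaxLag <- function(nTimepoints, minOverlap = 2L) {
  m <- min(nTimepoints %/% 4L, (nTimepoints - minOverlap) %/% 2L)
  max(0L, as.integer(m))
}

# Candidate lags ordered by the tie-break preference: smaller |lag| first,
# negative before positive at equal magnitude.
.lagPreferenceOrder <- function(m) {
  M <- seq.int(-m, m)
  M[order(abs(M), M)]
}

# Full N x N penalized-correlation matrix for a *fixed* lag pair (ki, kj):
# entry [i, j] is the similarity when gene i takes lag ki and gene j lag kj.
# Because the alignment and weights depend only on the lags, all pairs share
# one weight vector and the computation reduces to a weighted cross-product.
.lagCorrMatrix <- function(y, tp, ki, kj, C) {
  ov <- .lagOverlap(length(tp), ki, kj)
  w <- (tp[ov$i] - tp[ov$j])^2
  z <- exp(-w / C)
  zs <- z / sum(z)
  yi <- y[, ov$i, drop = FALSE]
  yj <- y[, ov$j, drop = FALSE]
  ci <- yi - drop(yi %*% zs)
  cj <- yj - drop(yj %*% zs)
  vi <- drop((ci * ci) %*% z)
  vj <- drop((cj * cj) %*% z)
  num <- (ci * rep(z, each = nrow(ci))) %*% t(cj)
  den <- sqrt(outer(vi, vj))
  r <- num / den
  # constant aligned profiles have an undefined correlation: map to 0
  constI <- apply(yi, 1L, function(v) all(v == v[1L]))
  constJ <- apply(yj, 1L, function(v) all(v == v[1L]))
  r[constI, ] <- 0
  r[, constJ] <- 0
  r[!is.finite(r)] <- 0
  exp(-mean(w) / C) * r
}

#' Best pairwise lag for a gene against a reference gene
#'
#' Scans all candidate lags \eqn{X_i \in \{-m, \dots, m\}} for gene \code{i}
#' while holding gene \code{j} at lag 0, and returns the maximum penalized
#' similarity and its argmax lag.  Ties are broken toward the smaller
#' \code{abs(lag)}, then toward the negative lag.
#'
#' @inheritParams lpwcCorrelation
#' @param maxLag maximum lag magnitude \code{m}.
#' @return A list with \code{score} (the maximum similarity) and \code{lag}
#'   (its argmax).
#' @export
pairwiseBestLag <- function(tss, i, j, C, maxLag, minOverlap = 2L) {
  stopifnot(i != j)
  best <- -Inf
  bestLag <- 0L
  for (k in .lagPreferenceOrder(maxLag)) {
    s <- lpwcCorrelation(tss, i, j, k, 0L, C, minOverlap = minOverlap)
    if (s > best) {
      best <- s
      bestLag <- as.integer(k)
    }
  }
  list(score = best, lag = bestLag)
}

#' Assign a lag to every gene (greedy heuristic)
#'
#' For each gene \eqn{i}, every other gene \eqn{j} votes with its best
#' pairwise lag \eqn{lag_j} and score \eqn{score_j} (from the scan of
#' \eqn{corr(i, j, X_i, 0)} over \eqn{X_i \in \{-m,\dots,m\}}); the selected
#' lag is
#' \deqn{\hat X_i = \arg\max_k \sum_{j \ne i} I(lag_j = k)\, score_j,}
#' the lag whose supporters carry the largest summed similarity.  Candidate
#' lags that receive no votes contribute a sum of 0 and still compete.  Ties
#' are broken toward the smaller \code{abs(lag)}, then the negative lag, which
#' keeps the default behaviour conservative about introducing lags.
#'
#' @inheritParams pairwiseBestLag
#' @return Integer vector of selected lags, one per gene.
#' @export
assignLagsHeuristic <- function(tss, C, maxLag = NULL, minOverlap = 2L) {
  y <- exprMatrix(tss)
  tp <- timepoints(tss)
  n <- nrow(y)
  stopifnot(n >= 2L)
  if (is.null(maxLag)) maxLag <- defaultMaxLag(length(tp), minOverlap)
  maxLag <- as.integer(maxLag)
  if (maxLag == 0L) return(rep(0L, n))

  pref <- .lagPreferenceOrder(maxLag)
  # best score/lag over candidates, vectorized across all pairs at once
  bestScore <- matrix(-Inf, n, n)
  bestLag <- matrix(0L, n, n)
  for (k in pref) {
    s <- .lagCorrMatrix(y, tp, k, 0L, C)
    upd <- s > bestScore
    bestScore[upd] <- s[upd]
    bestLag[upd] <- as.integer(k)
  }
  diag(bestScore) <- 0
  diag(bestLag) <- NA_integer_

  lagsOut <- integer(n)
  for (i in seq_len(n)) {
    sums <- vapply(pref, function(k) {
      sel <- which(bestLag[i, ] == k)
      sum(bestScore[i, sel])
    }, numeric(1))
    lagsOut[i] <- as.integer(pref[which.max(sums)])  # first max = preferred tie
  }
  lagsOut
}

#' Final penalized similarity matrix at fixed lags
#'
#' With one lag fixed per gene, computes the symmetric gene-gene similarity
#' matrix \eqn{corr(i, j) = s(i, j, \hat X_i, \hat X_j)} with unit diagonal.
#' When the combination of two assigned lags leaves fewer than
#' \code{minOverlap} aligned timepoints (the greedy per-gene selection never
#' evaluated that joint combination), the pair falls back to its zero-lag
#' similarity with a warning so the matrix remains complete.
#'
#' @inheritParams pairwiseBestLag
#' @param geneLags integer vector of per-gene lags.
#' @return Symmetric numeric matrix with entries in [-1, 1] and unit diagonal,
#'   carrying the gene identifiers as dimnames.
#' @export
lpwcSimilarityMatrix <- function(tss, geneLags, C, minOverlap = 2L) {
  y <- exprMatrix(tss)
  tp <- timepoints(tss)
  n <- nrow(y)
  geneLags <- as.integer(geneLags)
  stopifnot(length(geneLags) == n)
  S <- matrix(NA_real_, n, n, dimnames = list(rownames(y), rownames(y)))
  zeroLag <- NULL
  uniq <- sort(unique(geneLags))
  nfall <- 0L
  for (ki in uniq) for (kj in uniq) {
    rows <- which(geneLags == ki)
    cols <- which(geneLags == kj)
    if (!length(rows) || !length(cols)) next
    if (.lagOverlap(length(tp), ki, kj)$n < minOverlap) {
      if (is.null(zeroLag)) zeroLag <- .lagCorrMatrix(y, tp, 0L, 0L, C)
      S[rows, cols] <- zeroLag[rows, cols]
      nfall <- nfall + length(rows) * length(cols)
    } else {
      S[rows, cols] <- .lagCorrMatrix(y, tp, ki, kj, C)[rows, cols]
    }
  }
  if (nfall > 0L)
    warning(nfall, " pair entries had insufficient overlap at the assigned ",
            "lags; their zero-lag similarity was used", call. = FALSE)
  diag(S) <- 1
  S
}
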