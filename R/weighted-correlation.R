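#' Weighted Pearson correlation
#'
#' Correlation in which each observation pair contributes proportionally to a
#' nonnegative weight \eqn{z_r}:
#' \deqn{corr_w(x, y, z) = \frac{\sum_r z_r (x_r - \bar x)(y_r - \bar y)}
#'   {\sqrt{\sum_r z_r (x_r - \bar x)^2 \sum_r z_r (y_r - \bar y)^2}}}
#' with \eqn{\bar x, \bar y} the \eqn{z}-weighted means.  Positions that are
#' \code{NA} in either \code{x} or \code{y} are dropped first.  With constant
#' weights this is exactly the ordinary Pearson correlation, and the value is
#' invariant to rescaling \code{z} by any positive constant.
#'
#' @param x,y numeric vectors of equal length.
#' @param z nonnegative weights, same length; at least one must be positive.
#' @return The weighted correlation in [-1, 1], or \code{NA} when either
#'   weighted variance is zero (a constant profile), in which case callers
#'   treat the similarity as undefined.
#' @examples
#' x <- c(1, 3, 2, 5); y <- c(2, 5, 4, 9)
#' weightedCorrelation(x, y, rep(1, 4)) == cor(x, y)
#' @export
weightedCorrelation <- function(x, y, z) {
  if (length(x) != length(y) || length(x) != length(z))
    stop("x, y and z must have equal lengths", call. = FALSE)
  if (any(z < 0) || all(z == 0))
    stop("weights must be nonnegative with at least one positive entry",
         call. = FALSE)
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]; z <- z[keep]
  # exactly constant profiles: undefined before roundoff can hide it
  if (all(x == x[1L]) || all(y == y[1L])) return(NA_real_)
  zs <- sum(z)
  xb <- sum(z * x) / zs
  yb <- sum(z * y) / zs
  vx <- sum(z * (x - xb)^2)
  vy <- sum(z * (y - yb)^2)
  if (vx <= 0 || vy <= 0) return(NA_real_)
  sum(z * (x - xb) * (y - yb)) / sqrt(vx * vy)
}

#' Lag-penalized weighted correlation of a gene pair
#'
#' The core similarity score: align the two profiles under the given lags,
#' weight each aligned observation pair by the Gaussian kernel
#' \eqn{\exp(-w_r / C)} of its squared time difference, compute the weighted
#' correlation, and multiply by the lag penalty \eqn{\exp(-\bar w / C)}:
#' \deqn{s(i, j, X_i, X_j) = \exp(-\bar w / C) \,
#'   corr_w(L^{X_i} Y_i,\; L^{X_j} Y_j,\; \exp(-w / C)).}
#' At zero lags the penalty factor is 1, the weights are constant, and the
#' score is exactly the unweighted Pearson correlation of the two profiles.
#'
#' @inheritParams alignPair
#' @param C positive penalty parameter, in squared time units; larger values
#'   penalize lags less.
#' @return A number with \eqn{|s| \le \exp(-\bar w / C) \le 1}.  An undefined
#'   correlation (constant aligned profile) is mapped to 0 with a warning so
#'   that one flat gene cannot abort a whole-matrix computation.
#' @examples
#' y <- rbind(a = c(1, 4, 2, 8, 3), b = c(2, 1, 4, 2, 8))
#' tss <- TimeSeriesSet(y, timepoints = c(0, 5, 15, 30, 45))
#' lpwcCorrelation(tss, "a", "b", 0, 0, C = 100) == cor(y["a", ], y["b", ])
#' lpwcCorrelation(tss, "a", "b", 1, 0, C = 100)
#' @export
lpwcCorrelation <- function(tss, i, j, lagI, lagJ, C, minOverlap = 2L) {
  if (!is.numeric(C) || C <= 0)
    stop("C must be a positive number", call. = FALSE)
  al <- alignPair(tss, i, j, lagI, lagJ, minOverlap = minOverlap)
  r <- weightedCorrelation(al$xi, al$xj, exp(-al$w / C))
  if (is.na(r)) {
    warning("undefined correlation (constant profile) for pair (", i, ", ", j,
            "); similarity set to 0", call. = FALSE)
    return(0)
  }
  exp(-al$wbar / C) * r
}
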