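#' Apply an integer lag to a vector
#'
#' The lag operator shifts a temporal profile by whole index positions,
#' introducing \code{NA} placeholders at the vacated end and truncating the
#' other end so the vector length is preserved.  A positive lag shifts the
#' profile toward later indices (an \code{NA} prefix appears); a negative lag
#' shifts toward earlier indices (an \code{NA} suffix appears).  For example,
#' lagging \code{c(0, 5, 15)} by \code{+1} gives \code{c(NA, 0, 5)} and by
#' \code{-1} gives \code{c(5, 15, NA)}.
#'
#' @param values numeric vector (expression levels or timepoints).
#' @param lag integer shift; \code{abs(lag)} must be smaller than
#'   \code{length(values)}.
#' @return The lagged vector, same length as the input, with \code{abs(lag)}
#'   \code{NA} placeholders forming a contiguous prefix (positive lag) or
#'   suffix (negative lag).
#' @examples
#' applyLag(c(0, 5, 15), 1)    # NA 0 5
#' applyLag(c(0.2, 1.4, 4.5), -1)  # 1.4 4.5 NA
#' @export
applyLag <- function(values, lag) {
  lag <- as.integer(lag)
  n <- length(values)
  if (abs(lag) >= n)
    stop("invalid lag: |lag| = ", abs(lag), " must be < length(values) = ", n,
         call. = FALSE)
  if (lag == 0L) return(values)
  if (lag > 0L) {
    c(rep(NA, lag), values[seq_len(n - lag)])
  } else {
    c(values[seq.int(1L - lag, n)], rep(NA, -lag))
  }
}

# Column indices of the original vector retained when lags (ki, kj) are applied
# to a pair: position r of the aligned pair reads column idxI[r] of gene i and
# idxJ[r] of gene j.
.lagOverlap <- function(n, ki, kj) {
  idxI <- applyLag(seq_len(n), ki)
  idxJ <- applyLag(seq_len(n), kj)
  keep <- !is.na(idxI) & !is.na(idxJ)
  list(i = idxI[keep], j = idxJ[keep], n = sum(keep))
}

#' Align a gene pair under a pair of lags
#'
#' Applies the lag operator to both genes' expression and timepoint vectors,
#' drops the positions where either lagged vector is \code{NA}, and returns
#' the retained values together with the alignment weights
#' \eqn{w_r = (t^{(i)}_r - t^{(j)}_r)^2} and their mean \eqn{\bar w}.  When
#' both lags are zero the weights are identically zero and \eqn{\bar w = 0}.
#'
#' @param tss a [TimeSeriesSet-class].
#' @param i,j gene indices (or names).
#' @param lagI,lagJ integer lags for genes \code{i} and \code{j}.
#' @param minOverlap smallest number of retained timepoints allowed (default
#'   2; below this a correlation cannot be formed).
#' @return A list with components \code{xi}, \code{xj} (retained expression
#'   values), \code{ti}, \code{tj} (retained timepoints), \code{w} (squared
#'   time differences) and \code{wbar} (their mean).
#' @examples
#' y <- rbind(a = c(1, 2, 3, 4), b = c(2, 3, 4, 5))
#' tss <- TimeSeriesSet(y, timepoints = c(0, 2, 4, 6))
#' alignPair(tss, "a", "b", 1, 0)  # w = (ti - tj)^2 = c(4, 4, 4)
#' @export
alignPair <- function(tss, i, j, lagI, lagJ, minOverlap = 2L) {
  y <- exprMatrix(tss)
  tp <- timepoints(tss)
  ov <- .lagOverlap(length(tp), as.integer(lagI), as.integer(lagJ))
  if (ov$n < minOverlap)
    stop("insufficient overlap: lags (", lagI, ", ", lagJ, ") retain ", ov$n,
         " timepoints, need at least ", minOverlap, call. = FALSE)
  ti <- tp[ov$i]
  tj <- tp[ov$j]
  w <- (ti - tj)^2
  list(xi = unname(y[i, ov$i]), xj = unname(y[j, ov$j]),
       ti = ti, tj = tj, w = w, wbar = mean(w))
}
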