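#' Mean squared time difference at a given lag
#'
#' For a timepoint vector \eqn{T} and positive lag \eqn{l}, computes
#' \eqn{\bar w^l}: the mean of \eqn{(L^l T - T)^2} over the positions where
#' the lagged vector is defined.  This is the penalty weight a lag of
#' \eqn{l} would incur on this sampling grid and drives the data-driven
#' choice of the penalty parameter \code{C}.
#'
#' @param tp strictly increasing numeric timepoint vector.
#' @param l positive integer lag, \code{l < length(tp)}.
#' @return A nonnegative number in squared time units.
#' @examples
#' lagWeightProfile(c(0, 5, 15), 1)  # mean(25, 100) = 62.5
#' lagWeightProfile(seq(0, 30, by = 5), 1)  # uniform grid: step^2 = 25
#' @export
lagWeightProfile <- function(tp, l) {
  l <- as.integer(l)
  if (l < 1L) stop("l must be a positive integer", call. = FALSE)
  lt <- applyLag(tp, l)
  keep <- !is.na(lt)
  mean((lt[keep] - tp[keep])^2)
}

#' Mean Gaussian-kernel penalty over all positive lags
#'
#' \deqn{penalty(C) = \frac{1}{m} \sum_{l=1}^{m} \exp(-\bar w^l / C)}
#' the average penalty factor a lag of 1..m would receive on this timepoint
#' grid.  Strictly increasing in \code{C}, approaching 1 as \eqn{C \to \infty}
#' and 0 as \eqn{C \to 0^+}, which makes the target criterion below
#' invertible.
#'
#' @inheritParams lagWeightProfile
#' @param C positive penalty parameter (squared time units).
#' @param m maximum lag, \code{m >= 1}.
#' @return A number in (0, 1).
#' @export
penaltyValue <- function(C, tp, m) {
  stopifnot(C > 0, m >= 1)
  wbars <- vapply(seq_len(m), function(l) lagWeightProfile(tp, l), numeric(1))
  mean(exp(-wbars / C))
}

#' Solve the high-penalty criterion for C
#'
#' Finds the \code{C} at which the mean penalty over all valid positive lags
#' equals the target (default 0.5, the high-penalty operating point).  The
#' penalty is strictly increasing in \code{C} so the root is unique; it is
#' located by geometric bracket expansion followed by bisection to a
#' tolerance of 1e-8 on the penalty value.  For \code{m = 1} the solution has
#' the closed form \eqn{C = -\bar w^1 / \log(target)}, which the solver
#' matches.
#'
#' @inheritParams penaltyValue
#' @param target desired mean penalty in (0, 1).
#' @param tol tolerance on the achieved penalty value.
#' @return The solved \code{C} (squared time units).  Scaling all timepoints
#'   by \eqn{a} scales the solution by \eqn{a^2}.
#' @examples
#' tp <- c(0, 2, 4, 6, 8, 18, 24, 32, 48, 72)
#' C <- solveHighPenaltyC(tp, m = 2)
#' penaltyValue(C, tp, m = 2)  # 0.5
#' @export
solveHighPenaltyC <- function(tp, m, target = 0.5, tol = 1e-8) {
  stopifnot(target > 0, target < 1)
  f <- function(C) penaltyValue(C, tp, m) - target
  lo <- mean(vapply(seq_len(m), function(l) lagWeightProfile(tp, l), numeric(1)))
  hi <- lo
  while (f(lo) > 0) lo <- lo / 4
  while (f(hi) < 0) hi <- hi * 4
  # bisection on the monotone penalty value, run to full floating-point
  # convergence of the bracket (the tolerance on the value is then met with
  # a wide margin)
  repeat {
    mid <- (lo + hi) / 2
    if (mid <= lo || mid >= hi) break
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  if (abs(f(mid)) > tol)
    stop("root finding did not reach the requested penalty tolerance")
  mid
}

#' Low-penalty stability sweep for C
#'
#' Computes the \code{C} values whose mean penalty hits each target in
#' 0.50, 0.55, ..., 0.95, runs the full lag assignment and similarity
#' computation at each, and scores the stability of consecutive similarity
#' matrices as the sum of squared element-wise differences.  The returned
#' \code{C} is the later member of the consecutive pair with the smallest
#' difference (ties toward the smaller \code{C}): the certified-stable matrix
#' is the one the pipeline then uses.  Because it re-runs the pipeline ten
#' times, this mode is slower than the high-penalty criterion.
#'
#' @inheritParams assignLagsHeuristic
#' @param targets increasing penalty targets in (0, 1).
#' @return A list with \code{C} (the selected value), \code{lags} and
#'   \code{similarity} (the pipeline outputs at the selected \code{C}), and
#'   \code{diagnostics}, a data.frame with one row per target: the target
#'   penalty, the solved \code{C}, and the stability score against the
#'   previous target's matrix (\code{NA} for the first).
#' @export
lowPenaltySweep <- function(tss, maxLag = NULL, minOverlap = 2L,
                            targets = seq(0.5, 0.95, by = 0.05)) {
  y <- exprMatrix(tss)
  if (nrow(y) < 2L) stop("at least two genes are required", call. = FALSE)
  tp <- timepoints(tss)
  if (is.null(maxLag)) maxLag <- defaultMaxLag(length(tp), minOverlap)
  Cs <- vapply(targets, function(tg) solveHighPenaltyC(tp, maxLag, target = tg),
               numeric(1))
  mats <- vector("list", length(Cs))
  lagList <- vector("list", length(Cs))
  for (t in seq_along(Cs)) {
    lagList[[t]] <- assignLagsHeuristic(tss, Cs[t], maxLag, minOverlap)
    mats[[t]] <- lpwcSimilarityMatrix(tss, lagList[[t]], Cs[t], minOverlap)
  }
  stab <- c(NA_real_,
            vapply(seq_along(Cs)[-1L],
                   function(t) sum((mats[[t]] - mats[[t - 1L]])^2), numeric(1)))
  pick <- which.min(stab[-1L]) + 1L  # first (smallest-C) minimum on ties
  list(C = Cs[pick], lags = lagList[[pick]], similarity = mats[[pick]],
       diagnostics = data.frame(target = targets, C = Cs, stability = stab))
}
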