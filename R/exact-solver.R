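#' Build an ExactLagInstance from a dataset
#'
#' Precomputes the full score tensor \eqn{s_{i,j}^{k,l}} (the penalized
#' similarity of genes \eqn{i > j} at every candidate lag pair) so the
#' lag-optimization objective can be evaluated or solved exactly.  Intended
#' for small problems where enumeration is feasible; the greedy heuristic in
#' [assignLagsHeuristic()] approximates the same objective at scale.
#'
#' @inheritParams pairwiseBestLag
#' @return An [ExactLagInstance-class].
#' @export
exactInstanceFromData <- function(tss, C, maxLag, minOverlap = 2L) {
  y <- exprMatrix(tss)
  tp <- timepoints(tss)
  n <- nrow(y)
  M <- seq.int(-maxLag, maxLag)
  L <- length(M)
  s <- array(NA_real_, dim = c(n, n, L, L))
  for (a in seq_len(L)) for (b in seq_len(L)) {
    if (.lagOverlap(length(tp), M[a], M[b])$n < minOverlap) {
      s[, , a, b] <- -1e9  # infeasible joint lag pair: never part of an optimum
    } else {
      s[, , a, b] <- .lagCorrMatrix(y, tp, M[a], M[b], C)
    }
  }
  ExactLagInstance(s, M)
}

#' Objective value of a lag assignment
#'
#' The lag-optimization objective: the sum of the pairwise scores
#' \eqn{s_{i,j}^{k,l}} over all gene pairs \eqn{i > j} under the given lags.
#'
#' @param instance an [ExactLagInstance-class].
#' @param geneLags integer vector of lags, one per gene, each in the lag set.
#' @return The summed pairwise score.
#' @export
lagObjective <- function(instance, geneLags) {
  idx <- match(as.integer(geneLags), instance@lagSet)
  if (anyNA(idx)) stop("lags outside the instance lag set", call. = FALSE)
  n <- instance@nGenes
  total <- 0
  for (i in seq_len(n)[-1L]) for (j in seq_len(i - 1L)) {
    total <- total + instance@scores[i, j, idx[i], idx[j]]
  }
  total
}

#' Exact lag optimization by exhaustive enumeration
#'
#' Enumerates every assignment of one lag per gene from the lag set and
#' returns the assignment maximizing the summed pairwise scores.  The
#' underlying decision problem is NP-complete (weighted maximum cut reduces
#' to it, see [maxcutToLagInstance()]), so this solver is a ground-truth
#' oracle for small instances, guarded at \eqn{|M|^N \le 10^7} assignments.
#' The first optimum in enumeration order (lag-set order, first gene varying
#' fastest) is returned, which makes the result deterministic.
#'
#' @param instance an [ExactLagInstance-class].
#' @return A list with \code{lags} (the optimal integer lag vector) and
#'   \code{objective} (the maximized sum).
#' @export
solveLagsExact <- function(instance) {
  n <- instance@nGenes
  M <- instance@lagSet
  L <- length(M)
  nAssign <- L^n
  if (nAssign > 1e7)
    stop("instance too large to enumerate: |M|^N = ", nAssign, " > 1e7",
         call. = FALSE)
  # assignment matrix: row = assignment, column = gene (lag index into M)
  A <- as.matrix(expand.grid(replicate(n, seq_len(L), simplify = FALSE),
                             KEEP.OUT.ATTRS = FALSE))
  obj <- numeric(nAssign)
  for (i in seq_len(n)[-1L]) for (j in seq_len(i - 1L)) {
    obj <- obj + instance@scores[cbind(i, j, A[, i], A[, j])]
  }
  best <- which.max(obj)
  list(lags = M[A[best, ]], objective = obj[best])
}

#' Reduce a weighted maximum-cut problem to a lag-optimization instance
#'
#' Given a weighted graph with nonnegative symmetric edge weights, builds the
#' two-lag instance with lag set \{1, 2\} in which placing two adjacent
#' vertices at different lags earns the edge weight and equal lags earn 0:
#' \eqn{s_{i,j}^{1,2} = s_{i,j}^{2,1} = w_{ij}} and
#' \eqn{s_{i,j}^{1,1} = s_{i,j}^{2,2} = 0}.  The optimal objective of the
#' resulting instance equals the graph's maximum cut weight, which is the
#' reduction behind the NP-completeness of lag optimization.
#'
#' @param weights symmetric nonnegative numeric matrix with zero diagonal.
#' @return An [ExactLagInstance-class] with lag set \code{c(1, 2)}.
#' @examples
#' w <- matrix(1, 3, 3); diag(w) <- 0           # unit triangle
#' solveLagsExact(maxcutToLagInstance(w))$objective  # max cut = 2
#' @export
maxcutToLagInstance <- function(weights) {
  weights <- as.matrix(weights)
  if (nrow(weights) != ncol(weights) || !isSymmetric(unname(weights)))
    stop("weights must be a symmetric square matrix", call. = FALSE)
  if (any(weights < 0))
    stop("edge weights must be nonnegative", call. = FALSE)
  if (any(diag(weights) != 0))
    stop("the diagonal must be zero (no self loops)", call. = FALSE)
  n <- nrow(weights)
  s <- array(0, dim = c(n, n, 2L, 2L))
  s[, , 1L, 2L] <- weights
  s[, , 2L, 1L] <- weights
  ExactLagInstance(s, c(1L, 2L))
}
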