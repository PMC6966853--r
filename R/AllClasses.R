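#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom S4Vectors DataFrame metadata
NULL

#' TimeSeriesSet: a genes-by-timepoints expression container
#'
#' An S4 container for a short biological time-series experiment: a numeric
#' matrix of expression (or phosphorylation intensity) values with rows for
#' genes/peptides and columns for observed timepoints, plus the numeric
#' timepoint vector itself.  Extends
#' \linkS4class{SummarizedExperiment}; the timepoints are stored in
#' \code{colData(x)$timepoint}.
#'
#' Validity requires a single numeric assay with no missing values, strictly
#' increasing timepoints matching the number of columns, and at least three
#' timepoints (four are needed before any lag can be introduced).
#'
#' @seealso [TimeSeriesSet()] for construction, [timepoints()] and
#'   [exprMatrix()] for access.
#' @export
setClass("TimeSeriesSet", contains = "SummarizedExperiment")

setValidity("TimeSeriesSet", function(object) {
  if (length(SummarizedExperiment::assays(object)) < 1L)
    return("a TimeSeriesSet needs one assay")
  y <- SummarizedExperiment::assay(object, 1L)
  if (!is.numeric(y))
    return("the expression assay must be numeric")
  if (anyNA(y)) {
    bad <- which(is.na(y), arr.ind = TRUE)[1L, ]
    return(sprintf("missing value at row %d (%s), column %d: input matrices must be complete",
                   bad[1L], rownames(y)[bad[1L]] %||% "?", bad[2L]))
  }
  cd <- SummarizedExperiment::colData(object)
  if (!"timepoint" %in% colnames(cd))
    return("colData must contain a 'timepoint' column")
  tp <- cd$timepoint
  if (!is.numeric(tp) || anyNA(tp))
    return("timepoints must be numeric and complete")
  if (length(tp) != ncol(y))
    return("length of timepoints must equal the number of columns")
  if (length(tp) < 3L)
    return("at least 3 timepoints are required")
  if (any(diff(tp) <= 0))
    return("timepoints must be strictly increasing")
  if (anyDuplicated(rownames(y)))
    return("row (gene) identifiers must be unique")
  TRUE
})

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a TimeSeriesSet
#'
#' @param values numeric matrix, rows = genes/peptides, columns = timepoints.
#' @param timepoints strictly increasing numeric vector of observation times
#'   (any consistent unit: seconds, minutes, days).
#' @param ids optional character vector of row identifiers; defaults to
#'   existing rownames or \code{gene1..geneN}.
#' @return A [TimeSeriesSet-class] object.
#' @examples
#' y <- rbind(a = c(0.2, 1.4, 4.5), b = c(1.1, 0.4, 0.2))
#' tss <- TimeSeriesSet(y, timepoints = c(0, 5, 15))
#' timepoints(tss)
#' @export
TimeSeriesSet <- function(values, timepoints, ids = NULL) {
  values <- as.matrix(values)
  timepoints <- as.numeric(timepoints)
  if (length(timepoints) != ncol(values))
    stop("length of timepoints (", length(timepoints),
         ") must equal the number of columns (", ncol(values), ")",
         call. = FALSE)
  if (is.null(ids)) {
    ids <- rownames(values) %||% paste0("gene", seq_len(nrow(values)))
  }
  rownames(values) <- ids
  colnames(values) <- NULL
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(expr = values),
    colData = S4Vectors::DataFrame(timepoint = as.numeric(timepoints))
  )
  methods::new("TimeSeriesSet", se)
}

#' ExactLagInstance: a precomputed lag-optimization instance
#'
#' Holds the pairwise similarity scores \eqn{s_{i,j}^{k,l}} of the
#' lag-optimization problem: for every unordered gene pair \eqn{i>j} and every
#' pair of candidate lags \eqn{(k,l)} from the lag set, the similarity obtained
#' when gene \eqn{i} takes lag \eqn{k} and gene \eqn{j} takes lag \eqn{l}.
#' Used by [solveLagsExact()] to find the assignment maximizing the summed
#' pairwise scores by exhaustive enumeration, and as the target of the
#' weighted maximum-cut reduction ([maxcutToLagInstance()]).
#'
#' @slot nGenes number of genes (vertices).
#' @slot lagSet integer vector of candidate lags.
#' @slot scores 4-d numeric array indexed \code{[i, j, k-index, l-index]};
#'   entries are meaningful for \code{i > j}.
#' @export
setClass("ExactLagInstance",
  representation(nGenes = "integer", lagSet = "integer", scores = "array"))

setValidity("ExactLagInstance", function(object) {
  d <- dim(object@scores)
  L <- length(object@lagSet)
  if (length(d) != 4L || d[1L] != object@nGenes || d[2L] != object@nGenes ||
      d[3L] != L || d[4L] != L)
    return("scores array must have dimensions N x N x |M| x |M|")
  low <- object@scores[lower.tri(matrix(0, object@nGenes, object@nGenes))]
  # only i > j entries are part of the objective; they must be finite
  for (k in seq_len(L)) for (l in seq_len(L)) {
    s <- object@scores[, , k, l]
    if (any(!is.finite(s[lower.tri(s)])))
      return("scores for i > j must be finite")
  }
  TRUE
})

#' Construct an ExactLagInstance
#'
#' @param scores 4-d array \code{[N, N, |M|, |M|]} of pairwise scores
#'   (entries with \code{i > j} are used by the objective).
#' @param lagSet integer vector of candidate lags, one per score slice.
#' @return An [ExactLagInstance-class].
#' @export
ExactLagInstance <- function(scores, lagSet) {
  methods::new("ExactLagInstance", nGenes = as.integer(dim(scores)[1L]),
               lagSet = as.integer(lagSet), scores = scores)
}

#' LagClustResult: output of the lag-penalized clustering pipeline
#'
#' @slot lags integer vector, one selected lag per gene.
#' @slot similarity symmetric gene-gene similarity matrix in [-1, 1] with unit
#'   diagonal.
#' @slot penaltyC the Gaussian-kernel penalty parameter actually used
#'   (squared time units).
#' @slot penaltyMode "high", "low" or "fixed".
#' @slot maxLag maximum lag allowed.
#' @slot labels integer cluster labels (1..k).
#' @slot k number of clusters.
#' @slot silhouetteWidths named numeric vector of average silhouette widths per
#'   candidate k (empty when k was fixed by the caller).
#' @slot hclust the complete-linkage dendrogram (a \code{stats::hclust}
#'   object).
#' @slot sweep data.frame of low-penalty sweep diagnostics (target penalty,
#'   solved C, stability score), or a 0-row data.frame for other modes.
#' @export
setClass("LagClustResult",
  representation(lags = "integer", similarity = "matrix",
                 penaltyC = "numeric",
                 penaltyMode = "character", maxLag = "integer",
                 labels = "integer", k = "integer",
                 silhouetteWidths = "numeric", hclust = "ANY",
                 sweep = "data.frame"))

setValidity("LagClustResult", function(object) {
  n <- length(object@lags)
  if (!all(dim(object@similarity) == c(n, n)))
    return("similarity matrix dimensions must match the number of genes")
  if (length(object@labels) != n)
    return("one cluster label per gene is required")
  if (object@k >= 1L && !all(sort(unique(object@labels)) == seq_len(object@k)))
    return("labels must cover 1..k")
  if (any(abs(object@lags) > object@maxLag))
    return("all lags must satisfy |lag| <= maxLag")
  TRUE
})
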