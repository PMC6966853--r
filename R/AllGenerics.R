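#' Accessors for TimeSeriesSet and LagClustResult
#'
#' \code{timepoints} returns the numeric timepoint vector; \code{exprMatrix}
#' the genes-by-timepoints expression matrix; \code{lags} the per-gene lag
#' vector; \code{similarityMatrix} the penalized gene-gene similarity matrix;
#' \code{clusterLabels} the integer cluster labels; \code{penaltyC} the
#' resolved Gaussian-kernel penalty parameter.
#'
#' @param x a [TimeSeriesSet-class] or [LagClustResult-class].
#' @name accessors
#' @return The requested component.
NULL

#' @rdname accessors
#' @export
setGeneric("timepoints", function(x) standardGeneric("timepoints"))

#' @rdname accessors
#' @export
setGeneric("exprMatrix", function(x) standardGeneric("exprMatrix"))

#' @rdname accessors
#' @export
setGeneric("lags", function(x) standardGeneric("lags"))

#' @rdname accessors
#' @export
setGeneric("similarityMatrix", function(x) standardGeneric("similarityMatrix"))

#' @rdname accessors
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))

#' @rdname accessors
#' @export
setGeneric("penaltyC", function(x) standardGeneric("penaltyC"))

#' @rdname accessors
setMethod("timepoints", "TimeSeriesSet", function(x)
  as.numeric(SummarizedExperiment::colData(x)$timepoint))

#' @rdname accessors
setMethod("exprMatrix", "TimeSeriesSet", function(x)
  SummarizedExperiment::assay(x, 1L))

#' @rdname accessors
setMethod("lags", "LagClustResult", function(x) x@lags)

#' @rdname accessors
setMethod("similarityMatrix", "LagClustResult", function(x) x@similarity)

#' @rdname accessors
setMethod("clusterLabels", "LagClustResult", function(x) x@labels)

#' @rdname accessors
setMethod("penaltyC", "LagClustResult", function(x) x@penaltyC)

setMethod("show", "TimeSeriesSet", function(object) {
  tp <- timepoints(object)
  cat(sprintf("TimeSeriesSet: %d genes x %d timepoints\n",
              nrow(object), ncol(object)))
  cat("timepoints:", paste(tp, collapse = ", "), "\n")
  invisible(NULL)
})

setMethod("show", "LagClustResult", function(object) {
  n <- length(object@lags)
  cat(sprintf("LagClustResult: %d genes, k = %d clusters (%s penalty)\n",
              n, object@k, object@penaltyMode))
  cat(sprintf("  C = %.6g, max lag = %d, nonzero lags = %d\n",
              object@penaltyC, object@maxLag, sum(object@lags != 0L)))
  cat("  cluster sizes:",
      paste(tabulate(object@labels, object@k), collapse = ", "), "\n")
  if (length(object@silhouetteWidths)) {
    best <- names(which.max(object@silhouetteWidths))
    cat(sprintf("  average silhouette widths scanned over k = %s (best: k = %s)\n",
                paste(names(object@silhouetteWidths), collapse = ","), best))
  }
  invisible(NULL)
})
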