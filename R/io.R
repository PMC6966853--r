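#' Read a genes-by-timepoints matrix from a delimited file
#'
#' Canonical layout: a header row whose first field is \code{id} followed by
#' the numeric timepoints, then one row per gene.  When the header is not
#' numeric, the timepoints must be supplied explicitly.  Missing or
#' non-numeric cells and duplicate gene identifiers are rejected with a
#' message naming the offending row/column.
#'
#' @param path file path.
#' @param timepoints optional numeric timepoint vector overriding the header.
#' @param format "tsv" (default) or "csv".
#' @return A [TimeSeriesSet-class].
#' @export
readTimeSeries <- function(path, timepoints = NULL, format = c("tsv", "csv")) {
  format <- match.arg(format)
  sep <- if (format == "tsv") "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                           stringsAsFactors = FALSE, comment.char = "")
  ids <- as.character(raw[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate gene identifiers: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  y <- as.matrix(raw[, -1L, drop = FALSE])
  if (!is.numeric(y))
    stop("non-numeric expression values in ", path, call. = FALSE)
  if (anyNA(y)) {
    bad <- which(is.na(y), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing value at gene '%s', timepoint column '%s'",
                 ids[bad[1L]], colnames(y)[bad[2L]]), call. = FALSE)
  }
  if (is.null(timepoints)) {
    timepoints <- suppressWarnings(as.numeric(colnames(y)))
    if (anyNA(timepoints))
      stop("header is not numeric; supply timepoints explicitly",
           call. = FALSE)
  }
  TimeSeriesSet(y, timepoints, ids = ids)
}

#' Write a TimeSeriesSet to a delimited file
#'
#' Inverse of [readTimeSeries()]: writes an \code{id} column followed by one
#' column per timepoint, with the numeric timepoints as header.
#'
#' @param tss a [TimeSeriesSet-class].
#' @param path output file path.
#' @param format "tsv" (default) or "csv".
#' @return \code{path}, invisibly.
#' @export
writeTimeSeries <- function(tss, path, format = c("tsv", "csv")) {
  format <- match.arg(format)
  sep <- if (format == "tsv") "\t" else ","
  y <- exprMatrix(tss)
  out <- data.frame(id = rownames(y), y, check.names = FALSE)
  colnames(out) <- c("id", as.character(timepoints(tss)))
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write clustering results to a directory
#'
#' Writes three tab-delimited files: \code{clusters.tsv} (id, cluster, lag),
#' \code{similarity.tsv} (the full symmetric similarity matrix with an id
#' column), and \code{run_info.tsv} (key-value pairs recording the penalty
#' mode, resolved C, maximum lag, number of clusters, nonzero lag count and
#' package version).
#'
#' @param result a [LagClustResult-class].
#' @param outdir output directory, created if absent.
#' @return Character vector of the written paths, invisibly.
#' @export
writeResults <- function(result, outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  ids <- rownames(similarityMatrix(result))
  if (is.null(ids)) ids <- paste0("gene", seq_along(lags(result)))
  clusters <- data.frame(id = ids, cluster = clusterLabels(result),
                         lag = lags(result))
  pClusters <- file.path(outdir, "clusters.tsv")
  utils::write.table(clusters, pClusters, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  sim <- data.frame(id = ids, similarityMatrix(result), check.names = FALSE)
  colnames(sim) <- c("id", ids)
  pSim <- file.path(outdir, "similarity.tsv")
  utils::write.table(sim, pSim, sep = "\t", quote = FALSE, row.names = FALSE)
  info <- data.frame(
    key = c("penalty_mode", "C", "max_lag", "k", "nonzero_lags", "version"),
    value = c(result@penaltyMode, format(penaltyC(result), digits = 17),
              result@maxLag, result@k, sum(lags(result) != 0L),
              as.character(utils::packageVersion("lagclust"))))
  pInfo <- file.path(outdir, "run_info.tsv")
  utils::write.table(info, pInfo, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(pClusters, pSim, pInfo))
}
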