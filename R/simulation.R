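#' Impulse-model expression curve
#'
#' The six-parameter double-sigmoid impulse describing a transient
#' transcriptional response: an initial level \code{h0}, a rise (or fall) to a
#' peak level \code{h1} around onset time \code{t1}, and a relaxation to a
#' steady state \code{h2} around offset time \code{t2}, with \code{beta1}
#' controlling the steepness of both transitions:
#' \deqn{f(t) = \frac{1}{h_1}\,\bigl[h_0 + (h_1 - h_0)\,\sigma(\beta_1 (t - t_1))\bigr]
#'   \bigl[h_2 + (h_1 - h_2)\,\sigma(\beta_1 (t_2 - t))\bigr]}
#' where \eqn{\sigma} is the logistic function.  The curve tends to \code{h0}
#' as \eqn{t \to -\infty} and to \code{h2} as \eqn{t \to +\infty}.
#'
#' @param params named list or vector with \code{beta1}, \code{h0},
#'   \code{h1}, \code{h2}, \code{t1}, \code{t2} (with \code{t1 < t2} and
#'   \code{h1 != 0}).
#' @param t numeric vector of times.
#' @return Expression values at \code{t}.
#' @examples
#' p <- list(beta1 = 0.8, h0 = 7, h1 = 20, h2 = 14, t1 = 5, t2 = 40)
#' impulseCurve(p, c(0, 2, 4, 6, 8, 18, 24, 32, 48, 72))
#' @export
impulseCurve <- function(params, t) {
  p <- as.list(params)
  if (p$h1 == 0) stop("h1 must be nonzero", call. = FALSE)
  (1 / p$h1) *
    (p$h0 + (p$h1 - p$h0) * stats::plogis(p$beta1 * (t - p$t1))) *
    (p$h2 + (p$h1 - p$h2) * stats::plogis(p$beta1 * (p$t2 - t)))
}

#' Canonical impulse-model parameter sets
#'
#' The four reference temporal patterns used by the simulator, together with
#' the per-parameter uniform offset ranges that diversify the simulated genes
#' around each pattern.  In the low-variance setting the offsets are
#' beta1 ~ U(0, 0.5), h0/h1/h2 ~ U(-3, 3), t1/t2 ~ U(0, 3) and observation
#' noise is N(0, 0.5); the high-variance setting doubles the offset ranges
#' and uses N(0, 1) noise.
#'
#' @param variance "low" or "high".
#' @return A list with \code{models} (data.frame of the four canonical
#'   parameter sets), \code{offsets} (data.frame of min/max per parameter)
#'   and \code{noiseSd}.
#' @export
canonicalImpulseModels <- function(variance = c("low", "high")) {
  variance <- match.arg(variance)
  models <- data.frame(
    model = 1:4,
    beta1 = c(0.8, 1.2, 1.5, 1.2),
    h0    = c(7, 13, 17, 4),
    h1    = c(20, 6, 10, 12),
    h2    = c(14, 20, 4, 20),
    t1    = c(5, 8, 20, 6),
    t2    = c(40, 23, 40, 44)
  )
  fac <- if (variance == "low") 1 else 2
  offsets <- data.frame(
    parameter = c("beta1", "h0", "h1", "h2", "t1", "t2"),
    min = c(0, -3 * fac, -3 * fac, -3 * fac, 0, 0),
    max = c(0.5, 3, 3, 3, 3, 3) * fac
  )
  list(models = models, offsets = offsets,
       noiseSd = if (variance == "low") 0.5 else 1)
}

.offsetFor <- function(offsets, parameter) {
  row <- offsets[offsets$parameter == parameter, , drop = FALSE]
  stats::runif(1, row$min, row$max)
}

#' Simulate an impulse-model time-series dataset
#'
#' Generates labeled synthetic expression profiles: for each gene, additive
#' offsets for all six impulse parameters are drawn from the per-parameter
#' uniform ranges, one shared level offset (default U(0, 20)) is added to
#' h0, h1 and h2 to shift the whole profile along the expression axis, the
#' impulse curve is evaluated on the timepoint grid, and i.i.d. Gaussian
#' observation noise is added.  The default design is four canonical
#' patterns, 50 genes per pattern, observed at 0, 2, 4, 6, 8, 18, 24, 32,
#' 48, 72 min.
#'
#' @param genesPerModel genes simulated per canonical pattern (default 50).
#' @param timepoints observation grid in minutes.
#' @param variance "low" or "high" (sets offset ranges and noise; see
#'   [canonicalImpulseModels()]).
#' @param models optional custom data.frame of canonical parameters (columns
#'   beta1, h0, h1, h2, t1, t2; one row per pattern).
#' @param levelOffsetRange range of the shared expression-level offset.
#' @param noiseSd observation noise standard deviation; default from the
#'   variance setting.
#' @param coupleTimeOffsets when TRUE a single shared offset (drawn from the
#'   t1 offset range) is added to both t1 and t2, preserving the impulse
#'   duration across genes (the spike designs use this).
#' @param seed optional integer seed; identical seeds give bit-identical
#'   datasets.
#' @return A list with \code{data} (a [TimeSeriesSet-class]) and
#'   \code{labels} (integer vector of the generating pattern per gene).
#' @examples
#' sim <- simulateImpulseDataset(genesPerModel = 5, seed = 7)
#' table(sim$labels)
#' @export
simulateImpulseDataset <- function(genesPerModel = 50L,
                                   timepoints = c(0, 2, 4, 6, 8, 18, 24, 32,
                                                  48, 72),
                                   variance = c("low", "high"),
                                   models = NULL, levelOffsetRange = c(0, 20),
                                   noiseSd = NULL, coupleTimeOffsets = FALSE,
                                   seed = NULL) {
  variance <- match.arg(variance)
  canon <- canonicalImpulseModels(variance)
  if (is.null(models)) models <- canon$models
  if (is.null(noiseSd)) noiseSd <- canon$noiseSd
  offsets <- canon$offsets
  if (!is.null(seed)) set.seed(seed)
  nModels <- nrow(models)
  n <- nModels * genesPerModel
  y <- matrix(NA_real_, n, length(timepoints))
  labels <- rep(seq_len(nModels), each = genesPerModel)
  for (g in seq_len(n)) {
    base <- as.list(models[labels[g], c("beta1", "h0", "h1", "h2", "t1", "t2")])
    p <- base
    p$beta1 <- base$beta1 + .offsetFor(offsets, "beta1")
    p$h0 <- base$h0 + .offsetFor(offsets, "h0")
    p$h1 <- base$h1 + .offsetFor(offsets, "h1")
    p$h2 <- base$h2 + .offsetFor(offsets, "h2")
    if (coupleTimeOffsets) {
      dt <- .offsetFor(offsets, "t1")
      p$t1 <- base$t1 + dt
      p$t2 <- base$t2 + dt
    } else {
      p$t1 <- base$t1 + .offsetFor(offsets, "t1")
      p$t2 <- base$t2 + .offsetFor(offsets, "t2")
    }
    level <- stats::runif(1, levelOffsetRange[1L], levelOffsetRange[2L])
    p$h0 <- p$h0 + level; p$h1 <- p$h1 + level; p$h2 <- p$h2 + level
    y[g, ] <- impulseCurve(p, timepoints) +
      stats::rnorm(length(timepoints), 0, noiseSd)
  }
  list(data = TimeSeriesSet(y, timepoints), labels = labels)
}

#' Default spike-pattern parameters
#'
#' Synthetic parameter sets for the early-spike / late-spike benchmark: two
#' main patterns (early, late) each split into an on-time and a
#' slightly-later sub-pattern, sharing the spike shape (baseline 2, peak 14,
#' return to 2, steepness 2) and duration (t2 - t1 = 8 min).  The onsets
#' (early 8, late 42; later sub-patterns +3 min) place at least one
#' timepoint of both the regular and the irregular sampling grid inside
#' every spike.
#'
#' @return A data.frame with one row per sub-pattern and a \code{group}
#'   column marking the early/late main pattern.
#' @export
spikePatternParams <- function() {
  data.frame(
    group = c(1L, 1L, 2L, 2L),
    beta1 = 2, h0 = 2, h1 = 14, h2 = 2,
    t1 = c(8, 11, 42, 45),
    t2 = c(16, 19, 50, 53)
  )
}

#' Simulate the early/late spike benchmark
#'
#' 100 genes: 50 with an early expression spike and 50 with a late spike;
#' within each group, half spike a few minutes later than the other half.
#' The regular design observes 13 timepoints from 0 to 72 min every 6 min;
#' the irregular design observes 9 timepoints at 0, 3, 7, 12, 22, 34, 46,
#' 59, 75 min.  Per gene, a shared level offset from U(0, 10) is added to
#' h0/h1/h2, a single shared offset from U(0, 1) is added to both t1 and t2
#' (so the spike duration is identical within a sub-pattern), and N(0, 0.5)
#' noise is added per observation.
#'
#' @param regular TRUE for the regular 13-point grid, FALSE for the
#'   irregular 9-point grid.
#' @param genesPerSubpattern genes per sub-pattern (default 25; four
#'   sub-patterns).
#' @param params spike parameter data.frame as from [spikePatternParams()];
#'   configurable because the canonical values are design choices.
#' @param seed optional integer seed.
#' @return A list with \code{data} (a [TimeSeriesSet-class]), \code{labels}
#'   (early = 1 / late = 2 main-pattern labels) and \code{sublabels} (the
#'   four sub-patterns).
#' @export
simulateSpikeDataset <- function(regular = TRUE, genesPerSubpattern = 25L,
                                 params = spikePatternParams(), seed = NULL) {
  timepoints <- if (regular) seq(0, 72, by = 6) else
    c(0, 3, 7, 12, 22, 34, 46, 59, 75)
  if (!is.null(seed)) set.seed(seed)
  nSub <- nrow(params)
  n <- nSub * genesPerSubpattern
  y <- matrix(NA_real_, n, length(timepoints))
  sub <- rep(seq_len(nSub), each = genesPerSubpattern)
  for (g in seq_len(n)) {
    p <- as.list(params[sub[g], c("beta1", "h0", "h1", "h2", "t1", "t2")])
    level <- stats::runif(1, 0, 10)
    p$h0 <- p$h0 + level; p$h1 <- p$h1 + level; p$h2 <- p$h2 + level
    dt <- stats::runif(1, 0, 1)  # shared onset/offset shift: duration fixed
    p$t1 <- p$t1 + dt; p$t2 <- p$t2 + dt
    y[g, ] <- impulseCurve(p, timepoints) +
      stats::rnorm(length(timepoints), 0, 0.5)
  }
  list(data = TimeSeriesSet(y, timepoints),
       labels = params$group[sub], sublabels = sub)
}
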