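# Small random datasets used across tests; all randomness is seeded locally.

randomTimeSeries <- function(nGenes, timepoints = c(0, 2, 4, 6, 8, 18, 24, 32,
                                                    48, 72),
                             seed = 1) {
  set.seed(seed)
  y <- matrix(rnorm(nGenes * length(timepoints)), nGenes)
  TimeSeriesSet(y, timepoints)
}

# Independent brute-force evaluation of the penalized similarity for one gene
# pair: index bookkeeping and the correlation formula written out from
# scratch, sharing no code with the package internals.
referenceLpwc <- function(y, tp, i, j, ki, kj, C) {
  n <- length(tp)
  lagVec <- function(v, k) {
    out <- rep(NA_real_, n)
    for (r in seq_len(n)) {
      src <- r - k
      if (src >= 1 && src <= n) out[r] <- v[src]
    }
    out
  }
  xi <- lagVec(y[i, ], ki); ti <- lagVec(tp, ki)
  xj <- lagVec(y[j, ], kj); tj <- lagVec(tp, kj)
  keep <- !is.na(xi) & !is.na(xj)
  xi <- xi[keep]; xj <- xj[keep]; ti <- ti[keep]; tj <- tj[keep]
  w <- (ti - tj)^2
  z <- exp(-w / C)
  xb <- sum(z * xi) / sum(z)
  yb <- sum(z * xj) / sum(z)
  r <- sum(z * (xi - xb) * (xj - yb)) /
    sqrt(sum(z * (xi - xb)^2) * sum(z * (xj - yb)^2))
  exp(-mean(w) / C) * r
}

# Independent enumeration of the lag-optimization objective: decodes every
# assignment from a single integer counter instead of using expand.grid.
referenceExactOptimum <- function(scores, lagSet) {
  n <- dim(scores)[1L]
  L <- length(lagSet)
  best <- -Inf
  for (code in 0:(L^n - 1L)) {
    idx <- integer(n)
    c0 <- code
    for (g in seq_len(n)) {
      idx[g] <- c0 %% L + 1L
      c0 <- c0 %/% L
    }
    obj <- 0
    for (i in seq_len(n)[-1L]) for (j in seq_len(i - 1L))
      obj <- obj + scores[i, j, idx[i], idx[j]]
    if (obj > best) best <- obj
  }
  best
}

# Brute-force weighted maximum cut over all bipartitions of <= ~20 vertices.
referenceMaxCut <- function(w) {
  n <- nrow(w)
  best <- 0
  for (code in 0:(2^n - 1L)) {
    side <- as.integer(intToBits(code)[seq_len(n)])
    cut <- 0
    for (i in seq_len(n)[-1L]) for (j in seq_len(i - 1L))
      if (side[i] != side[j]) cut <- cut + w[i, j]
    if (cut > best) best <- cut
  }
  best
}
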