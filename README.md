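# lagclust

Clustering of short biological time series — gene expression, protein
phosphorylation — whose temporal patterns may be shifted in time relative to
one another, using **lag-penalized weighted correlation**.

## The problem

High-throughput time-course experiments in molecular biology are short
(often 5–15 timepoints) and frequently sampled irregularly: densely right
after a stimulus, sparsely later. Two genes responding to the same signal
can show the same temporal shape delayed by a few sampling intervals, yet
plain correlation or Euclidean clustering treats them as unrelated — and
ignores the timepoint ordering entirely. Conversely, methods that align
freely (dynamic time warping) happily pair observations that are hours
apart, which is rarely meaningful for a 10-point time course.

`lagclust` takes the middle road. Profiles are aligned by bounded integer
**lags** (index shifts with truncation, no interpolation or stretching), the
aligned observation pairs are weighted by how close they are in actual time,
and every introduced lag is penalized, so synchronous explanations win
unless the data clearly prefer a shift.

## The similarity measure

For genes *i*, *j* with expression vectors *Y<sub>i</sub>*, *Y<sub>j</sub>*
observed at timepoints *T*, and integer lags *X<sub>i</sub>*, *X<sub>j</sub>*:

```
s(i, j, Xi, Xj) = exp(-w̄ / C) · corr_w( L^Xi Yi , L^Xj Yj , exp(-w / C) )
```

* `L^X` is the lag operator: it shifts a vector by `X` index positions,
  padding with `NA` (`L¹[0, 5, 15] = [NA, 0, 5]`); positions that are `NA`
  in either profile are dropped.
* `w_r = (L^Xi T_r − L^Xj T_r)²` is the squared time difference of the
  *r*-th aligned observation pair, and `w̄` its mean.
* `corr_w(x, y, z)` is weighted Pearson correlation with weights
  `z = exp(−w/C)`: aligned pairs far apart in real time count less.
* `exp(−w̄/C)` is a Gaussian-kernel penalty on the alignment as a whole;
  with both lags 0 it equals 1 and the score is exactly the ordinary
  Pearson correlation.

The kernel width `C` (in squared time units) controls how expensive lags
are. Two data-driven modes are provided: the **high penalty** solves
`mean over lags l = 1..m of exp(−w̄^l / C) = 0.5` for `C` by bisection, and
the **low penalty** sweeps penalty targets 0.50–0.95 and keeps the `C`
whose gene–gene similarity matrix is most stable against its predecessor.

One lag per gene is selected by a greedy vote: each gene *j* reports the
best pairwise lag and score against gene *i*, and *i* adopts the lag whose
supporters carry the largest summed score. (Selecting lags optimally is
NP-complete — weighted maximum cut reduces to it; the package ships the
exact enumeration solver and the reduction, used as correctness oracles.)
The resulting similarity matrix is transformed to distances
`d = 1 − s ∈ [0, 2]` and clustered hierarchically with complete linkage,
choosing the number of clusters by average silhouette width.

## Worked example

```r
library(lagclust)

sim <- simulateImpulseDataset(genesPerModel = 25, seed = 11)  # 100 genes, 4 patterns
res <- lpwc(sim$data, penalty = "high", k = "auto")
res
#> LagClustResult: 100 genes, k = 4 clusters (high penalty)
#>   C = 306.24, max lag = 2, nonzero lags = 0
#>   cluster sizes: 25, 25, 25, 25
#>   average silhouette widths scanned over k = 2,3,4,5,6,7,8,9,10 (best: k = 4)
adjustedRandIndex(clusterLabels(res), sim$labels)
#> [1] 1
```

The simulator draws each gene from one of four canonical impulse-model
curves (double-sigmoid rise/fall with six parameters) with per-parameter
uniform offsets, a shared expression-level shift, and Gaussian observation
noise. Here the high-penalty run solves `C = 306.24` from the 10-point
sampling grid alone, introduces no lags (the four patterns are synchronous,
so this is correct), the silhouette scan picks `k = 4`, and the clusters
match the generating patterns exactly (adjusted Rand index 1).

Real data come in as a TSV (first column `id`, header row of numeric
timepoints) via `readTimeSeries()`; `writeResults()` exports cluster
assignments with per-gene lags, the similarity matrix, and the run
parameters. A command-line front end with `cluster`, `simulate`,
`select-c` and `permute-eval` subcommands is installed at
`system.file("scripts/lagclust.R", package = "lagclust")`.

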