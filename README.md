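# npclust

Cluster discovery and network analysis for preschool neuropsychological
test batteries.

## What problem this solves

Developmental neuropsychologists screen preschoolers (30–71 months) with
large test batteries — here 52 tests covering receptive (8), expressive
(15), attention/memory (9), processing (13) and executive (7) functions —
and need to answer population-level questions from the resulting
children × tests score matrix: which test correlations are real, whether
the children fall into discrete performance clusters, how scores grow
with age, which abilities are "hubs" in the network of tests, and which
domestic/educational factors predict performance. `npclust` implements
that full analysis pipeline for R, together with a synthetic cohort
generator that emulates the study design, so every stage can be validated
by parameter recovery without access to an undeposited cohort.

The core methods, in standard notation:

* **Surrogate-validated correlation structure.** Pearson correlations
  r_jk between all test pairs; significance from n_surr = 1000 surrogates
  that permute each child's scores across the 52 tests, with two-sided
  empirical p = (1 + #{|r_surr| ≥ |r_obs|}) / (1 + n_surr).
* **Cluster discovery.** k-means (squared Euclidean, k-means++ starts,
  best of 10 restarts) with the number of clusters selected by the
  Calinski–Harabasz index CH(k) = [B/(k−1)] / [W/(n−k)] (maximized) and
  checked against the Davies–Bouldin index (minimized); the same
  selection re-run inside each cluster yields nested sub-clusters.
* **Trajectories.** OLS of the global score (mean of the 52 normalized
  scores) on age in months per group, y = b + m·a, with bootstrap
  contrasts of slopes/intercepts and size-matched subsample regressions
  (20–90% fractions, 1000 iterations).
* **Ability network.** Binary graphs from thresholding each age group's
  correlation matrix at r ≥ 0.5; unnormalized Brandes betweenness
  centrality per test; Σ(BC) across the seven age groups ranks tests and
  defines five nested predictor sets at percentile cutoffs.
* **Classification.** A k-nearest-neighbour classifier (≈20 neighbours,
  stratified tenfold cross-validation) predicts cluster membership from
  the centrality-ranked test subsets.
* **Covariates.** A multivariable linear regression of global score or
  cluster label on six predictors (school, household, parent ages and
  schooling), with coefficients tested against 1000 surrogates that
  permute the predictor rows jointly.

## Worked example

```r
library(npclust)

se <- generateCohort(defaultCohortConfig(seed = 1))
se
#> ScoreExperiment: 643 children x 52 tests
#>   missing scores: 194  incomplete children: 32
#>   age range (months): 30-71
#>   synthetic cohort with planted labels

cc  <- filterComplete(se)          # drops the 32 partial records
mod <- selectK(scoreMatrix(cc), kRange = 2:10, seed = 1)
mod
#> ClusterModel: k = 2 (CH), DB argmin = 2
#>   cluster sizes: 267/344

gs <- globalScore(cc)
round(100 * tapply(gs, mod@labels, mean), 2)
#>     1     2
#> 34.20 72.12
```

Both criteria agree on two clusters; their mean scores (34.2% and 72.1%)
recover the planted 34.15% / 71.44% — the lower-scoring cluster holds
267 of 611 children (≈44%). Age trajectories per recovered cluster:

```r
fit <- fitTrajectory(gs, ages(cc), mod@labels, nBoot = 200, seed = 1)
fit$fits
#>   group       m      b      mSe    bSe   n
#> 1     1 0.00684 0.0723 0.001100 0.0440 267
#> 2     2 0.00621 0.3659 0.000589 0.0341 344
fit$slopeContrast$p      # 0.67  -> slopes indistinguishable
fit$interceptContrast$p  # 0.0100 -> intercepts differ
```

The two clusters improve at statistically indistinguishable rates
(~0.006–0.007 normalized score per month) but at different levels —
the signature of a level difference, not a rate difference. (Slopes
fitted within *recovered* clusters are attenuated relative to the planted
8.6/7.8 × 10⁻³ because the assignment boundary trades children between
clusters; fitting within the planted clusters recovers the planted
slopes, which is what the acceptance script measures.) Finally, the
ability network:

```r
cen <- summedBcAndGroups(bcByAgeGroup(scoreMatrix(cc), ageGroups(cc)))
head(sort(cen@summedBc, decreasing = TRUE))
#>     t25      t32      t27      t36      t24      t30
#> 15.0    14.1    12.8    12.5    12.3    12.2
```

`runAll(pipelineConfig(...))` executes every stage in order and writes a
CSV/JSON results bundle; `inst/scripts/npclust-cli.R` wraps `simulate`
and `run-all` for shell use.

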