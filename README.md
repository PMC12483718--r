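# fsexplore

Unique factor scores for matrix decomposition factor analysis, via
regression on external criteria (RFE) or a joint K-means penalty (CFE).

## The problem

Matrix decomposition factor analysis (MDFA) fits the common factor model
directly to a column-centered data matrix,

```
minimize  || X − F A′ − U Ψ ||²   subject to  (1/n) [F U]′[F U] = I,
```

treating the common scores `F` (n × r) and unique scores `U` (n × p) as
parameters alongside the loadings `A` and the uniqueness square roots on
the diagonal of `Ψ`. That buys nonnegative uniquenesses and
per-observation residuals, but the scores are *indeterminate*: they split
into a part that is a linear function of `X` and a free component lying
in the orthogonal complement of `col(X)` which the loss cannot see.
Anyone who wants to use individual scores downstream — comparing groups,
flagging outliers, clustering people — needs that freedom resolved.

`fsexplore` implements two resolutions, for applied researchers in
psychometrics and epidemiology who work with samples-by-variables data:

* **RFE** (regression-based factor score exploration) adds
  `α · || Y − F B′ ||²` for external criteria `Y` (demographics, outcome
  measures). With at least as many criteria as factors and full-rank
  blocks, the scores become uniquely determined — linear in `[X, Y]` —
  while a small `α` leaves loadings and uniquenesses essentially those of
  plain MDFA. Everything is estimated jointly by alternating exact
  conditional minimizers (an SVD-based orthogonal Procrustes score
  update; closed forms for `Ψ`, `A`, `B`).
* **CFE** (clustering-based factor exploration) instead penalizes with
  the K-means objective `α · || F − M C′ ||²`, clustering the scores
  while estimating them. The prior two-stage baseline **CCFE** (fit MDFA,
  then rotate the free score component toward a K-means structure) is
  included for comparison — it carves sharp clusters even in data that
  have none, which is exactly the failure mode CFE moderates.

Around the estimators: geomin oblique rotation with consistent
counter-rotation of scores, orthogonal Procrustes alignment,
permutation-sign alignment for recovery scoring, Bartlett post-hoc
scores, matrix RMSEA and local-solution diagnostics, Cohen's d with a
large-sample interval, and seeded generators for the simulation designs
used to validate everything.

## Worked example

Simulate a study with 200 respondents, 12 observed variables, 3 factors
and 3 external criteria at explained variance 0.7, then fit RFE:

```r
library(fsexplore)

sim <- generate_dataset(simulation_design(n = 200, p = 12, q = 3, r = 3,
                                          rho = 0.7, seed = 42))
fit <- fit_rfe(sim$data, r = 3,
               control = fe_control(alpha = 0.01, n_starts = 20, seed = 1))
fit
#> <rfe_fit: 3 factor(s), n = 200, p = 12, q = 3>
#>   loss 9.45323 after 14 iteration(s) (converged), alpha = 0.01
#>   20 start(s), local-solution proportion 0.000
```

All 20 random starts reached the same loss (no local solutions). How well
did it recover the generating parameters? The estimator is defined up to
an orthogonal rotation, so the report aligns with a single Procrustes
transformation before comparing:

```r
recovery_report(fit, sim$truth)
#> # A tibble: 1 × 6
#>   rmsea_A rmsea_F rmsea_U rmsea_B rmsea_uniqueness local_solution_proportion
#> 1  0.0416   0.459   0.893   0.113            0.360                         0
```

Loadings are recovered to RMSEA 0.04 at 30% noise. And are the scores
actually identified? The rank conditions hold and the fitted scores sit
in the column space of the observed data to machine precision:

```r
check_identification(fit)
#> 7 F lies in the column space of [X, Y] (relative residual) 4.07e-14 TRUE
```

Per-respondent scores and model residuals come from `augment(fit)`;
`autoplot(fit)` scatters the first two factors. For clustering,
`fit_cfe(data, r = 2, k = 3)` returns memberships and centroids, and
`cluster_stats()` summarizes within-cluster variance and centroid
separation.

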