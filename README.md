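# mobstyle

Latent activity behaviors and lifestyles from urban mobility data.

## What it does, and for whom

City-scale venue-visit records (who visited which category of place, when,
and for how long) carry far more behavioral information than census tables,
but each person's activity is high-dimensional and noisy. `mobstyle` is for
computational social scientists and urban/health researchers who want to
compress such records into a small set of interpretable **latent activity
behaviors** and study what those behaviors explain.

The core model: describe each user *i* by a normalized activity vector
**x**\_i of M = 248 venue-category fractions plus 5 temporal fractions
(morning / afternoon / evening, weekday / weekend), stack the N users into a
matrix X, and factorize

> X ≈ W·B,  W ≥ 0 (N × k), B ≥ 0 (k × M),

minimizing the generalized Kullback–Leibler divergence
D(X‖WB) = Σ \[x log(x/y) − x + y\]. Rows of B are latent behaviors; row *i*
of W gives the mixture weights that make up user *i*'s lifestyle —
**x**\_i ≈ Σ\_j w\_ij **b**\_j. The rank k is chosen by restart stability
and Owen–Perry bi-cross-validation. On top of the weights the package
computes:

* normalized weight entropy S\_i = −Σ ŵ\_ij log ŵ\_ij / log k,
* experienced income integration I\_i = 1 − (2/3) Σ\_q |τ\_iq − 1/4| from
  dwell-time exposure shares τ\_iq = Σ\_α τ\_iα τ\_qα over within-city income
  quartiles,
* place exploration E\_i = (unique places) / (visits),
* city fixed-effects OLS of outcomes on behavior weights and area
  demographics, with a demographics-only / behaviors-only / both R²
  decomposition.

Commercial mobility feeds are proprietary, so the package includes a
first-class synthetic generator with a planted ground truth (behaviors,
weights, venues with income-group compositions, outcomes from a known linear
model) against which every stage is tested.

## Worked example

A full synthetic run — generation, ingest, features, rank selection over
k ∈ {2..6}, factorization, metrics, and outcome models — in one call:

```r
library(mobstyle)
cfg <- pipeline_config(master_seed = 1, n_users_per_city = 250, n_cities = 3,
                       n_areas_per_city = 8, m_cat = 30, visits_per_user = 100,
                       noise_rate = 0.02, k_grid = 2:6, n_restarts = 6,
                       bcv_restarts = 2, max_iter = 250)
demo <- run_demo(1, cfg)
print(demo)
```

```
mobstyle synthetic demo run
  selected rank: 4 (planted 4)
  planted-basis recovery (mean matched cosine): 0.9999
  mean weight entropy: 0.621
  mean integration: 0.671; mean exploration: 0.634
  R^2 [integration]: D = 0.157, M = 0.038, M+D = 0.163
  R^2 [exploration]: D = 0.051, M = 0.087, M+D = 0.095
  checks passed: 9 / 9
```

The generator planted 4 behaviors; bi-cross-validation selects k = 4 and the
recovered basis matches the planted one almost perfectly (matched cosine
0.9999). Mean weight entropy 0.62 says a typical synthetic user mixes
several behaviors rather than following one. The R² triplets show, for each
outcome, how much variance demographics (D), behavior weights (M), and both
(M+D) explain; nested monotonicity (M+D ≥ max(M, D)) is asserted on every
triplet. The rank diagnostics behind the selection:

```r
demo$diagnostics
#>   k mean_loss best_loss stability bcv_error
#> 1 2     270.8     270.2     0.989   0.01390
#> 2 3     166.9     159.6     0.970   0.01015
#> 3 4      72.6      72.6     1.000   0.00428
#> 4 5      69.0      68.6     0.935   0.00443
#> 5 6      65.4      65.0     0.917   0.00473
```

and the per-user statistics:

```r
head(demo$stats[, c("user_id", "entropy", "integration", "exploration")], 4)
#>   user_id entropy integration exploration
#> 1 u00001    0.620       0.752        0.73
#> 2 u00002    0.760       0.748        0.68
#> 3 u00003    0.716       0.583        0.71
#> 4 u00004    0.883       0.539        0.70
```

Stages can also be run individually against CSV artifacts with
`run_stage("simulate" | "ingest" | "features" | "factorize" | "metrics",
config)`, each writing a JSON manifest with seeds and input checksums; see
the vignette in `vignettes/latent-behaviors.Rmd` for the methods.

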