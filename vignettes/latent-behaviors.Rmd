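---
title: "Latent activity behaviors from mobility data: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent activity behaviors from mobility data: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mobstyle)
```

# The problem

Venue-visit mobility records describe where people spend time: each record is
a user, a venue with a category label (Coffee Shop, Gym, Bus Station, ...), a
start time, and a dwell duration. `mobstyle` models a person's *lifestyle*
not as a single cluster label but as a non-negative mixture of a small number
of *latent activity behaviors* — recurring visitation/temporal patterns shared
across the population. The package covers the full path from raw visit
records to those behaviors and the statistics built on them: income-exposure
integration, place exploration, behavior-weight entropy, and fixed-effects
regressions linking behaviors and area demographics to social,
transportation, and health outcomes.

Because commercial mobility feeds cannot be redistributed, the package ships
a synthetic generator that emulates their statistical structure from a
planted ground truth. Every stage of the pipeline is exercised and tested
against that generator.

# From visits to the activity matrix

**Filtering.** A stay qualifies as a visit when its dwell is strictly
between 5 minutes and 4 hours. A user qualifies with strictly more than 50
visits and at least 5 distinct categories. Analyses are restricted to the
most-visited categories (default 248) counted over the whole filtered
dataset; ties at the cutoff break by lexicographic category name so runs are
reproducible across platforms. The stages are ordered extraction →
category restriction → user filter, so every retained user meets the
thresholds on the *final* category set; the user filter is therefore applied
after restriction, and all operations are idempotent.

**Home areas.** A user's home area is the modal area among their pings in
the 10 pm–6 am window, with lexicographic tie-breaking. Users without night
pings are flagged and excluded from exposure and regression stages. Local
time is read from the timestamp's stored offset; no geographic timezone
lookup is attempted.

**Features.** Each user becomes an M-dimensional vector: the fraction of
visits per category (summing to 1) concatenated with five temporal
fractions — morning (5 am–noon), afternoon (noon–6 pm), evening (6
pm–midnight) computed over classified visits, and weekday/weekend computed
over all visits. Visits between midnight and 5 am fall in no time-of-day
window (the printed windows do not cover them); they are excluded from the
time-of-day fractions but still count toward category and weekday/weekend
fractions. The blocks are concatenated without re-weighting. A consequence
worth noting: each user's vector carries a total mass of 3 (category 1 +
time-of-day 1 + week 1), which matters for the regression design below.

# KL non-negative matrix factorization

The `N × M` activity matrix `X` is factorized as `X ≈ W B` with `W (N × k)`
and `B (k × M)` non-negative, minimizing the generalized Kullback–Leibler
divergence

```
D(X || WB) = Σ_ij [ x_ij log(x_ij / (WB)_ij) − x_ij + (WB)_ij ].
```

`kl_nmf()` uses multiplicative updates, which carry a proven monotone
non-increase of the objective per sweep; the per-sweep loss trace is stored
so this contract is assertable, and the test suite asserts it on randomized
instances. Numerical choices:

* initialization draws all entries i.i.d. uniform(0.1, 1.1), rescaled so the
  initial product matches `mean(X)`; strictly positive starts avoid the KL
  singularity at zero;
* a floor of `1e-12` guards every logarithm and denominator;
* convergence is declared when the relative loss change per sweep drops
  below `tol` (default `1e-6`, `max_iter` 500 sweeps);
* on return, rows of `B` are rescaled to sum to 1 with the compensating
  rescale absorbed into the columns of `W`, fixing the scale ambiguity of
  the product without changing `W %*% B`.

Multiplicative KL updates converge slowly in their tail on exactly-low-rank
inputs (sublinear near a zero-loss optimum), so the tolerance and iteration
cap are exposed; rank-1 and rank-2 exact instances reach machine-level loss
quickly while higher exact ranks approach it more slowly. Because the
objective is non-convex, `multi_restart()` runs many seeds (200 by
convention for a production factorization; diagnostics default to 20) and
keeps the run with the smallest loss, retaining every restart's basis for
the stability diagnostic.

Users outside the factorization sample are attached by `project_weights()`,
which holds `B` fixed and minimizes the same KL objective per user from a
deterministic positive start. A least-squares variant is available behind a
flag; the KL objective is the default because it matches the factorization
loss, and the two differ only through the (ambiguous) choice of regression
loss. To avoid over-representing large cities, `sample_users_per_city()`
draws an equal-size sample per city (10,000 by convention) for the
factorization; everyone else is projected.

# Choosing the rank

Three diagnostics are computed per candidate rank by `rank_diagnostics()`:

* **loss** — best and mean KL loss across restarts;
* **stability** — restarts recover factors only up to permutation and scale,
  so bases are compared after optimal row matching (`match_factors()`,
  Hungarian assignment on pairwise cosine similarity, exact against
  brute-force search); the stability score is the mean matched cosine over
  all restart pairs. Cosine similarity makes the score invariant to row
  permutation and positive rescaling;
* **bi-cross-validation** — rows and columns are partitioned into folds
  (3 × 3 by default); each (row-fold, column-fold) block is held out, the
  complementary submatrix is factorized, held-out rows and columns are
  attached by one-sided projection, and the block is predicted as the
  product of the projected factors, scored by mean per-entry generalized KL.

`select_rank()` picks the rank minimizing the bi-cross-validation error among
candidates whose stability reaches a floor (default 0.8), with ties going to
the smaller rank. On planted synthetic data the minimum falls at the true
rank in the large majority of seeds; individual seeds can prefer a
neighboring rank when the curve is shallow past the truth, which is expected
behavior of held-out validation, not an error.

# Behavior-derived statistics

* **Weight entropy** `S = −Σ ŵ log ŵ / log k` on normalized weights: 0 when
  one behavior strictly dominates, 1 when all k are equally present.
* **Exposure shares**: `τ_iα` is the fraction of user *i*'s dwell time at
  place *α*; `τ_qα` is the fraction of all dwell time at *α* contributed by
  income quartile *q*; `τ_iq = Σ_α τ_iα τ_qα` is the user's exposure to
  group *q*. The product of stochastic maps conserves mass, so `Σ_q τ_iq = 1`
  exactly — a property the acceptance suite asserts on random instances.
  Exposure is dwell-time weighted by default ("proportion of time"); a
  visit-count variant sits behind a flag. "Place" means venue, not area,
  and a user's own dwell is included in the composition of the places they
  visit (no self-exclusion; a flag provides it).
* **Income quartiles** are computed within each city on users' home-area
  median incomes, with boundary ties going to the lower quartile.
* **Integration** `I = 1 − (2/3) Σ_q |τ_iq − 1/4|`: the 2/3 prefactor is the
  exact normalizer (the deviation sum is at most 3/2), so `I = 1` only at
  uniform exposure and `I = 0` exactly on one-hot exposure.
* **Exploration** `E = (unique places) / (total visits)`: explorers ≈ 1,
  returners ≈ 0. Note the unique-place count and the weight entropy are
  distinct statistics even though both are conventionally written `S`; the
  package names them `n_unique_places` and `entropy`.

# Outcome models

The association of behaviors with outcomes is estimated by OLS with city
fixed effects:

```
y_i = Σ_j β_j w_ij + Σ_l γ_l d_il + city_i + ε_i
```

with four area demographics (median household income, population density,
fraction Black population, fraction public-transport use) and dummy-encoded
cities (reference level dropped). Coefficients are estimated on raw scales —
so simulation recovery is exact — and reported alongside standardized values
(`β · sd(x)/sd(y)`). Classical standard errors are the default; HC1 robust
errors sit behind a flag. `r2_decomposition()` fits demographics-only (D),
behaviors-only (M), and both (M+D) on identical observations; because the
model spaces nest, `R²(M+D) ≥ max(R²(M), R²(D))` must hold on every dataset
and is asserted in the demo report.

One design point deserves emphasis. At a converged KL fit with `B` rows
summing to 1, each user's weights sum *exactly* to the mass of their
activity vector (the KL stationarity conditions conserve row mass) — the
weight block is compositional and spans the intercept. An explicit intercept
would make the design singular, so `fit_fixed_effects()` detects a
compositional weight block (relative variation of row sums below `1e-4`) and
drops the intercept, which the weights then absorb; the R² is always
computed centered, which stays valid because the constant remains inside the
model span. Behavior coefficients are then identified relative to the
reference-city level; generating coefficients are recovered exactly when the
reference city's effect is zero, the usual fixed-effects normalization.
Tract-level analyses average user weights per tract
(`aggregate_tract_weights()`) and reuse the same model machinery, and
`weight_demographics_correlation()` screens whether behavior weights are
explainable by the four census features at all.

# The synthetic generator

The generator is the package's stand-in for proprietary ping/venue feeds and
defines the study conditions for every statistical test:

* **Planted behaviors**: a `k_true × (m_cat + 5)` row-stochastic basis;
  80% of category entries are zeroed per row by default (sparse, hence
  well-separated behaviors) and each row allocates a fixed 20% of its mass
  to the five temporal features so both blocks influence the factorization.
  The 20% share is a configurable stand-in — no canonical weighting exists
  for the concatenation — and rows are regenerated (up to 100 attempts) if
  sparsification leaves duplicates.
* **User weights** are Dirichlet draws; the concentration parameter tunes
  the weight entropy (0.5 by default — users dominated by a couple of
  behaviors, matching the intuition that lifestyles mix a few patterns).
* **Visits** draw, per visit: a behavior from the user's weights, then a
  category, a time-of-day window, and a weekday/weekend flag from that
  behavior's block-renormalized propensities; with probability `noise_rate`
  all three are uniform instead. Timestamps pick a date consistent with the
  weekday/weekend draw inside a six-month window and a uniform time inside
  the drawn window; dwells are uniform on (6, 180) minutes. In expectation a
  user's activity vector is their weight mixture of the block-renormalized
  planted basis (`planted_basis_features()`), which is therefore the
  recovery target for the factorization.
* **Geography**: areas carry strictly distinct log-normal median incomes
  (non-degenerate within-city quartiles), log-normal density, and Beta
  fractions; each (area, category) hosts Poisson(3) venues (minimum 1), and
  each venue carries a Dirichlet-planted income-group composition that
  biases which venues each quartile's users pick — this makes co-visitation,
  and hence the exposure metrics, non-trivial and recoverable. Nighttime
  anchor pings at the home area make home inference testable.
* **Outcomes** follow the fixed-effects linear model exactly, with optional
  Gaussian noise, so regression recovery can be checked both exactly
  (`noise_sd = 0`) and statistically (coverage of ±3 standard errors).

What the generator does *not* emulate: GPS noise and ping density, real
category hierarchies, day-to-day routine persistence, venue capacity, or
spatial autocorrelation of demographics. Passing tests therefore demonstrate
correctness of the pipeline's statistics and estimators under the planted
model, not robustness to the messiness of commercial feeds.

# Problem sizes and determinism

Every stochastic stage derives its seed from a single master seed and a
stage label (`derive_seed()`), so a run is fixed end to end by one integer,
and fixing the seed fixes every emitted table byte-for-byte. The bundled
demo (`run_demo()`) defaults to 3 cities × 2,000 users with a planted rank
of 4 and a candidate grid of 2–8. The test suite runs the same machinery at
reduced sizes chosen to keep the factorization sample informative while
staying desk-scale: planted-recovery checks use 2,000 users with 60 visits
each; bi-cross-validation replicates use 240 users × 80 visits with a 3 × 3
fold scheme and 2 inner restarts; regression recovery uses n = 10,000 over
20 seeds. Restart counts for diagnostics default to 20 (configurable to the
production-scale 200).

# Known limitations

* Multiplicative KL updates can need many sweeps for machine-precision loss
  on exact inputs of rank ≥ 3; the defaults favor the realistic noisy case.
* Bi-cross-validation curves are shallow to the right of the true rank, so
  single seeds may select a slightly larger rank; decisions should rest on
  the majority behavior across seeds, which is what the diagnostics report.
* The exposure metrics use aggregate time shares at places, not
  time-resolved co-presence; two users count as mutually exposed at a venue
  they visit at different times.
* Classical OLS standard errors ignore within-area correlation of
  demographics; the HC1 flag mitigates heteroskedasticity only.
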