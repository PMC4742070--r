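# ordipa

Parallel analysis for ordered categorical items, with positive-definite
smoothing of polychoric correlation matrices.

## The problem

Deciding how many latent dimensions underlie a set of Likert-type items is a
routine step in psychological, educational and epidemiological scale
construction. Parallel analysis (PA) answers it by comparing the observed
eigenvalues of an item correlation matrix against a null distribution of
eigenvalues obtained from data with the same marginals but no inter-item
association. For ordinal items the correlation matrix of choice is often the
**polychoric** matrix — the maximum-likelihood correlation of the standard
normal variables assumed to underlie each pair of observed items — because
Pearson correlations of category codes are attenuated, severely so when the
response distributions are skewed. The price is that a matrix assembled from
pairwise polychoric estimates can be **indefinite** (have negative
eigenvalues), which breaks the variance interpretation of eigenvalues and
many factoring methods.

`ordipa` implements the full pipeline and the three classical remedies:

* **Polychoric estimation** — Olsson's two-step estimator with
  pair-specific thresholds: thresholds fixed at normal quantiles of each
  pair's cumulative marginal proportions, then the correlation maximizing the
  multinomial likelihood `sum(n_ij log pi_ij(rho))` over `(-0.999, 0.999)`,
  with rectangle probabilities `pi_ij` from a bivariate-normal CDF accurate
  to ~1e-15.
* **Smoothing** of indefinite matrices to positive definiteness by
  - alternating projections onto the PSD cone and the unit-diagonal set
    (nearest correlation matrix in Frobenius norm, `smooth_higham()`),
  - eigenvalue clipping
    `R(δ) = Diag(KD⁺Kᵗ)^{-1/2} KD⁺Kᵗ Diag(KD⁺Kᵗ)^{-1/2}` with floor
    `δ = 0.1` (`smooth_knol_berger()`),
  - rescaling of Heywood-type variables, `R* = ΔR₀Δ + D_R`, with the
    implicated variables located by **minimum trace factor analysis**
    (`smooth_bentler_yuan()`, `minimum_trace_decomposition()` — an
    interior-point semidefinite solver maximizing `tr(D)` subject to
    `R − D ⪰ 0`).
* **Parallel analysis** — permutation reference distributions (each column
  shuffled independently), Horn's mean or Glorfeld's 95th-percentile
  criterion, principal components or principal axis factoring with
  squared-multiple-correlation communalities, and the sequential
  stop-at-first-failure retention rule (`run_parallel_analysis()`).
* **A Monte-Carlo engine** (`pa_grid()`, `run_condition()`, `run_study()`,
  `tabulate_study()`, `overall_summary()`) reproducing a 288-condition
  factorial study over ordinal factor models
  `Σ = w_ma Λ_ma Λ_maᵗ + w_mi Λ_mi Λ_miᵗ + w_un I` with major, minor and
  unique factors, 2–4 response categories, symmetric or skewed (|skewness|
  ≈ 1.4) category frequencies, and 200–1000 respondents.

## Worked example

Simulate a hard case — three major factors, binary skewed items, only 200
respondents — and run PA on the smoothed polychoric matrix:

```r
library(ordipa)

cond  <- condition_spec(
  n_major_factors = 3, vars_per_factor = 5, n_respondents = 200,
  n_categories = 2, skewed = TRUE, loading_level = "high"
)
model <- build_population_model(cond, seed = 41)
x     <- simulate_responses(model, seed = 141)

polychoric_matrix(x)
#> polychoric correlation estimate (15 items), smoothing: none
#>   min eigenvalue: -0.00901082 (indefinite)

run_parallel_analysis(
  x, extraction = "pca", correlation = "polychoric",
  smoothing = "bentler_yuan", criterion = "p95", n_draws = 100, seed = 244
)
#> Parallel analysis (PCA, polychoric correlations, bentler_yuan smoothing, p95 criterion)
#>   retained dimensions: 3 of 15
#>   observed correlation matrix was indefinite before smoothing
#>   eigenvalues:  3.589 3.080 2.409 1.118 0.884
#>   thresholds:   2.322 1.965 1.748 1.610 1.439
```

The observed pairwise polychoric matrix is indefinite (smallest eigenvalue
−0.009). The Heywood-rescaling smoother changes only four of fifteen
variables (`delta_i` ≈ 0.991 for the implicated ones, 1 elsewhere, largest
elementwise change 0.008), and the first three eigenvalues — and only those —
exceed their permutation thresholds, so PA retains exactly the three major
factors that generated the data. `tidy()`, `glance()` and `autoplot()` give
a per-position tibble, a one-row summary and a scree plot with the threshold
line.

The same machinery scales to study fragments:

```r
res <- run_condition(cond, methods = pa_methods(arms = c("kb", "by", "pearson")),
                     n_replicates = 20, n_draws = 100, seed = 1)
overall_summary(res)$accuracy
tabulate_study(res)
```

A thin command-line wrapper is installed at `exec/ordipa`
(`ordipa analyze`, `ordipa simulate`, `ordipa smooth`, `ordipa study`).

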