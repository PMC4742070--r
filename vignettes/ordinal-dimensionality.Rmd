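---
title: "Assessing the dimensionality of ordinal items: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing the dimensionality of ordinal items: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ordipa)
```

`ordipa` decides how many latent dimensions underlie a set of ordered
categorical items by permutation-based parallel analysis (PA) of Pearson or
polychoric correlation matrices, with three positive-definite smoothing
algorithms for the indefinite matrices that pairwise polychoric estimation
can produce, and a Monte-Carlo engine for evaluating all of these methods on
simulated ordinal factor models. This vignette is the package's account of
the statistical machinery: the models and algorithms, every tunable
parameter with its default and rationale, what the simulation engine does
and does not emulate, and the places where the design was genuinely open.

## 1. The latent factor model behind the simulations

Simulated datasets are generated from a common factor model on a latent
continuous scale. For `J = n_major_factors * vars_per_factor` latent
variables, the population correlation matrix is assembled as

$$\Sigma = w_{ma}\,\Lambda_{ma}\Lambda_{ma}^{t}
        + w_{mi}\,\Lambda_{mi}\Lambda_{mi}^{t}
        + w_{un}\,I_J .$$

* $\Lambda_{ma}$ is a binary simple-structure loading matrix: each variable
  loads on exactly one of the 1 or 3 major factors, with loading 1. Major
  factors are uncorrelated; variables on different factors have population
  correlation 0.
* $\Lambda_{mi}$ (present in half the design) holds loadings of **40 minor
  factors**, drawn independently from Uniform(−1, 1). Minor factors model
  structured noise — shared nuisance influences too weak to count as
  dimensions, but strong enough to perturb eigenvalue spectra.
* $w_{ma}$ is 0.5 ("high" loadings) or 0.3 ("medium"), so 50% or 30% of each
  latent variance is attributable to major factors.

**Minor-factor weight normalisation.** Since $E[\lambda^2] = 1/3$ for a
Uniform(−1, 1) loading, the expected diagonal of
$\Lambda_{mi}\Lambda_{mi}^{t}$ is $40/3$. We set
$w_{mi} = 0.2\,w_{ma} / (40/3)$, so the expected minor-factor contribution
to each latent variance is exactly $0.2\,w_{ma}$, and
$w_{un} = 1 - w_{ma} - 0.2\,w_{ma}$. With this choice the expected diagonal
of $\Sigma$ is exactly 1. Because the *realized* diagonal still varies
across variables (the 40 draws do not average out exactly), the assembled
matrix is rescaled to an exact correlation matrix by pre- and
post-multiplying with the inverse square root of its diagonal. The
discretization step below assumes standard-normal marginals, so an exact
unit diagonal is not cosmetic. Minor loadings are redrawn for every
simulated replicate: they represent noise, and a shared nuisance structure
across replicates would understate between-replicate variability.

**Discretization.** Respondents are drawn from a multivariate standard
normal with correlation $\Sigma$ and each coordinate is cut at fixed
thresholds into 2–4 ordered categories coded `0..C-1`. Thresholds are
standard-normal quantiles of cumulative design frequencies: equal
frequencies in the symmetric conditions; `[0.2, 0.8]`, `[0.1, 0.2, 0.7]`
and `[0.1, 0.1, 0.1, 0.7]` in the skewed conditions, which puts the
population skewness of the category scores at about −1.4 (for the binary
split, exactly $(1-2p)/\sqrt{p(1-p)} = -1.5$ with $p = 0.8$). Rare
categories sit at the low end of the scale; only the magnitude of the
skewness matters to any method in the package, since all estimators are
invariant to jointly reflecting the category order of an item pair.

The full factorial design — 2 (major factors) × 2 (variables per factor) ×
3 (respondents: 200/500/1000) × 3 (categories) × 2 (skewness) × 2 (minor
factors) × 2 (loading level) = **288 conditions** — is enumerated by
`pa_grid()`.

```{r}
nrow(pa_grid())
abs(population_skewness(category_probs(3, skewed = TRUE)))
```

## 2. Correlation estimation

`pearson_matrix()` computes product-moment correlations of the raw category
codes; such matrices are positive semidefinite by construction, but the
coefficients are attenuated relative to the latent correlation — severely
under skew, where the attainable range of a Pearson correlation between two
items shrinks with unequal marginals.

`polychoric_matrix()` estimates, for every item pair, the correlation of
the two underlying normal variables by **Olsson's two-step estimator with
pair-specific thresholds**:

1. thresholds are fixed at standard-normal quantiles of the *pair's own*
   cumulative marginal proportions (not estimated jointly per item across
   all pairs — the pairwise variant is numerically more stable in small
   samples, at the cost of thresholds that may differ slightly between
   pairs involving the same item);
2. $\rho$ maximizes the multinomial log-likelihood
   $\sum_{ij} n_{ij} \log \pi_{ij}(\rho)$, where $\pi_{ij}$ is the
   bivariate-normal rectangle probability between consecutive thresholds.

Numerical choices, none of which has a canonical published value:

* The rectangle probabilities come from a vectorised Gauss–Legendre
  quadrature of the bivariate normal CDF (the Drezner–Wesolowsky integrand
  with 6/12/20 nodes by |ρ| regime, and a tail expansion for |ρ| ≥ 0.925),
  accurate to about 1e−15. The likelihood surface is extremely flat as
  |ρ| → 1, so CDF accuracy well beyond 1e−10 is required for stable
  boundary behaviour; the unit tests verify agreement with
  `mvtnorm::pmvnorm` (TVPACK) to 1e−10.
* $\rho$ is maximized by bounded scalar optimization (`stats::optimize`,
  golden-section/parabolic) on (−0.999, 0.999) with tolerance 1e−6. A
  bounded method needs no starting value.
* Perfect-association tables drive the optimum to the boundary; estimates
  within 1e−4 of the box are clipped to ±0.999 and flagged `"boundary"`.
  Empty cells contribute nothing ($0 \cdot \log \pi := 0$); no continuity
  correction is applied, which keeps the estimator exactly the likelihood
  maximizer the grid-search oracle in the tests reproduces.
* A pair in which one variable shows a single observed category cannot
  identify a correlation: `polychoric_pair()` flags it `"degenerate"`, and
  `polychoric_matrix()` raises an error naming the offending items rather
  than silently imputing.

Because each coefficient uses its own thresholds, the assembled matrix need
not be positive semidefinite. `is_positive_definite()` declares a
symmetric matrix PD iff its smallest eigenvalue exceeds **1e−8** — a
tolerance chosen to be far below any eigenvalue a genuine factor structure
produces at these dimensions, yet far above accumulated rounding error of a
45 × 45 eigendecomposition.

## 3. Smoothing indefinite correlation matrices

All three smoothers share two contracts: the output is symmetric, has an
exactly unit diagonal and smallest eigenvalue above zero; and **inputs that
are already positive definite are returned unchanged**. The second contract
is enforced by a short-circuit on the PD test above. For the
eigenvalue-clipping smoother this matters: its floor δ = 0.1 would
otherwise alter a valid correlation matrix whose smallest eigenvalue is,
say, 0.05. Clipping therefore engages only on matrices that fail the PD
test, which also makes all smoothing arms of a simulation agree exactly on
replicates whose observed matrix was definite to begin with.

**Alternating projections** (`smooth_higham()`) computes the nearest
correlation matrix in the Frobenius norm by Dykstra-corrected alternating
projections between the PSD cone and the unit-diagonal affine set: at most
1000 sweeps, declared converged when successive iterates differ by less
than 1e−9 in Frobenius norm. The limit point is guaranteed PSD, not PD, so
a final eigenvalue floor of 1e−8 (followed by diagonal rescaling) moves it
strictly inside the cone. The tests compare against a 10,000-iteration
projection oracle (agreement to 1e−6) and confirm no random nearby
correlation matrix is closer to the input.

**Eigenvalue clipping** (`smooth_knol_berger()`) replaces eigenvalues below
δ with δ and rescales to unit diagonal:
$R(\delta) = \mathrm{Diag}(KD^{+}K^{t})^{-1/2}\,KD^{+}K^{t}\,
\mathrm{Diag}(KD^{+}K^{t})^{-1/2}$. The default δ = 0.1 is the
conventional study value; it is exposed as a parameter. The formula is
invariant to the arbitrary eigenbasis the numeric routine returns within a
repeated eigenvalue's eigenspace (verified in the tests by random
orthogonal remixing). Note the rescaling means output eigenvalues can fall
below δ; the guarantee is positive definiteness, with pre-rescaling
eigenvalues at least δ.

**Heywood-variable rescaling** (`smooth_bentler_yuan()`) returns
$R^{*} = \Delta R_0 \Delta + D_R$, where $R_0$ is $R$ with zeroed diagonal,
$D_R$ its diagonal and $\Delta = \mathrm{diag}(\delta_i)$,
$\delta_i \in (0, 1]$. Off-diagonal $(i,j)$ of the output is exactly
$\delta_i\delta_j\,r_{ij}$ and the diagonal is untouched, so the method
alters only the rows and columns of rescaled variables. Which variables to
rescale is decided by **minimum trace factor analysis**: the diagonal $D$
maximizing $\mathrm{tr}(D)$ subject to $R - D \succeq 0$. For an
indefinite $R$ some $d_i$ are necessarily negative — these are the
Heywood-type variables (implied negative unique variance). The
decomposition does not pin $\Delta$ down uniquely; our rule sets
$\delta_i = 1$ for variables with $d_i \ge 0$ and applies a *single scalar*
shrink to the implicated set, found by 60 bisection steps as the largest
value in (0, 1] keeping the smallest output eigenvalue above 1e−8. A
scalar shrink minimally perturbs uninvolved variables, is fully testable
through the multiplicative pattern, and cannot over-shrink one variable to
spare another. (A per-variable shrink schedule would also satisfy the PD
condition; nothing in the method's definition selects between them, so we
chose the simpler, more reproducible rule.) If even the limiting shrink
cannot reach definiteness — possible only when the unimplicated block is
itself singular — the function fails loudly rather than falling back.

The embedded semidefinite program is solved by a log-barrier interior-point
method written for this package (no SDP solver is part of the package's
dependency set): for a barrier weight μ decreasing geometrically from 1 by
factors of 0.2, Newton's method maximizes
$\sum_i d_i + \mu \log\det(R - \mathrm{diag}(d))$ — gradient
$1 - \mu\,\mathrm{diag}(S)$ and Hessian $-\mu\, S \circ S$ with
$S = (R - \mathrm{diag}(d))^{-1}$ are exact — from the strictly feasible
start $d_i = \lambda_{\min}(R) - 0.5$, with backtracking to stay inside the
cone. The duality gap at weight μ is $J\mu$; iteration stops below 1e−8.
The tests pin the solver to closed-form optima (equicorrelation matrices,
where the dual certificate $Y = (JI - \mathbf{1}\mathbf{1}^t)/(J-1)$ proves
$D = (1-\rho)I$ optimal; 2 × 2 matrices, where the optimal common trace is
$2|r|$) and to convexity-based perturbation checks.

```{r}
r <- matrix(c(1, .9, .9, .9, 1, -.9, .9, -.9, 1), 3, 3)
minimum_trace_decomposition(r)$d
smooth_bentler_yuan(r)$report$delta_i
```

## 4. Parallel analysis

`run_parallel_analysis()` composes the pipeline:

1. estimate the configured correlation matrix of the observed data and
   record whether it is indefinite *before* smoothing;
2. smooth if configured (never for Pearson, whose matrices are PSD already —
   the configuration is rejected);
3. extract eigenvalues: **PCA** uses the matrix as is; **PAFA** first
   replaces the diagonal with communality estimates;
4. build the reference distribution: `n_draws` (default 100) datasets, each
   obtained by independently permuting every column of the observed data —
   preserving marginals exactly, destroying association — and each run
   through *the same pipeline*, including threshold re-estimation,
   smoothing of any indefinite permuted matrix, and communality reduction.
   Anything less would bias the thresholds relative to the observed
   eigenvalues;
5. threshold at position k = mean (Horn) or empirical 95th percentile
   (Glorfeld) of the k-th largest reference eigenvalues. The percentile is
   `stats::quantile` type 7 (linear interpolation of order statistics, R's
   default); with 100 draws this interpolates between the 95th and 96th
   order statistic;
6. retain by the **sequential rule**: the count of leading positions whose
   observed eigenvalue exceeds its threshold, stopping at the first failure.
   The alternative — counting all exceedances anywhere in the spectrum — can
   resurrect dimensions after a failure and is not standard PA practice.

Communalities are **squared multiple correlations**,
$\mathrm{SMC}_i = 1 - 1/(R^{-1})_{ii}$, clipped to [0, 1] — the canonical
choice for principal-axis PA. For the deliberately unsmoothed polychoric
arm an indefinite matrix may still be inverted; if it is singular the run
is recorded as failed. Reference-draw failures are tolerated up to 25% of
draws (each failure logged), beyond which the analysis aborts: a fixed,
testable policy in place of ad-hoc stopping rules.

Reproducibility: a single `seed` governs the whole analysis; permutations
consume one RNG stream in a fixed order, so equal seeds give bit-identical
`pa_result` objects. In the study engine, replicate r of a condition runs
under a seed derived deterministically from the master seed (a 32-bit
mixing recurrence), so conditions are independent and individually
re-runnable.

## 5. The Monte-Carlo study engine

`run_condition()` simulates replicates (rebuilding the population model per
replicate, so minor loadings are redrawn) and evaluates every configured PA
variant on each. Within a replicate, the permutation draws and the
correlation matrices are computed **once** and shared across arms — the
polychoric matrix of each of the 100 permuted datasets is by far the
dominant cost, and sharing it is exactly what a method comparison wants:
all arms see the same data and the same null draws. A replicate is correct
for an arm iff the retained count equals the number of major factors.
`tabulate_study()` lays results out as percent-correct marginals by design
factor with a final indefinite-rate row, mirroring the conventional
simulation-study table; `overall_summary()` pools replicates with equal
weight and reports two denominators (failures counted as incorrect, and
failures excluded), since either convention is defensible.

**Problem sizes.** The full-scale study — 288 conditions × 100 replicates ×
100 draws, with up to 45 items — is a many-hour desk-machine computation
dominated by ~10⁸ pairwise polychoric fits. The package treats scale-down
knobs (replicate count, draw count, grid filters) as first-class arguments
with full-scale defaults. The shipped test suite and the acceptance script
run deliberately scaled instances: the accuracy benchmark uses the
one-factor, five-item, binary, symmetric, high-loading, n = 1000 condition
at 20 replicates × 100 draws (a stratum where smoothed-polychoric and
Pearson PCA variants are essentially always correct at full scale, so 20
replicates suffice to detect any systematic failure), and parameter
recovery uses 40 replicates per (ρ, C) cell at n = 5000.

## 6. What the simulations do and do not emulate

The generator reproduces the designed study conditions: uncorrelated
simple-structure major factors with equal loadings, many weak random minor
factors, normal latent variables, fixed category thresholds shared by all
items, complete data. Real item sets violate most of these in some degree —
correlated factors (where the 95th-percentile criterion is known to become
conservative), cross-loadings, non-normal latent response processes,
item-specific marginals, missing responses. Passing tests therefore
demonstrate that the algorithms are implemented correctly and behave as
expected *under the factor model*, not that PA with any particular
correlation/smoothing choice is accurate for arbitrary empirical data.
Known limitations of scope, by design: no polyserial correlations, no
one-step full-matrix ML polychoric estimation, no minimum-rank or
model-based (regression) PA variants, no imputation.

## 7. Degenerate inputs and tie-breaks, collected

* Zero-variance item → error (Pearson); single observed category in a pair
  → degenerate flag, matrix-level error naming the items (polychoric).
* Perfect association → ±0.999 with `"boundary"` flag.
* Missing values anywhere → error; data files are validated on read.
* Repeated eigenvalues → whatever basis LAPACK returns; all downstream
  formulas are basis-invariant (tested).
* Smoothing a PD matrix → identity operation, reported as zero change.
* `n_draws = 1` → both criteria degenerate to that draw's eigenvalues.
* Retention on equal values → a threshold is exceeded only by a strictly
  greater eigenvalue, so exact ties do not retain.
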