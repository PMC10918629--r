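---
title: "Methods and design of metimp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of metimp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metimp)
```

# The problem

Mass-spectrometry metabolomics feature tables — samples in rows,
metabolite intensities in columns — almost always contain missing
cells. Three mechanisms dominate. Missing completely at random (MCAR)
arises from stochastic acquisition failures and is independent of all
intensities. Missing at random (MAR) means the probability of a cell
going missing depends on *other, observed* variables. Missing not at
random (MNAR) means it depends on the unobserved value itself; in
metabolomics this is overwhelmingly left-censoring at the instrument's
limit of detection (LOD), so missing cells are disproportionately the
*small* values. Real tables typically mix at least two mechanisms.

Choosing an imputation method without knowing how methods behave under
each mechanism invites bias, so `metimp` couples a set of native
imputation methods to a ground-truthed amputation simulator and a
benchmark harness, and turns the benchmark output into per-mechanism
recommendations.

# Data model and conventions

An `intensity_matrix` stores a numeric matrix plus an explicit logical
mask; masked cells are physically `NA` so no code path can read them as
data. Conventions, fixed rather than guessed:

* **Orientation** is samples × metabolites and the readers never
  auto-transpose. Tools in this space disagree on orientation; a fixed,
  documented convention avoids silent transposition bugs.
* **Missing-value encodings**: textual tokens (`NA`, `NaN`, `N/A`,
  empty) are always treated as missing; literal `0` and `1` — both used
  in practice as missing-value markers — are **opt-in**
  (`zero_as_missing`, `one_as_missing`), because both can also be
  legitimate intensities.
* **Validity** means every observed cell is finite and non-negative.
  `validate_intensities()` reports offending cells instead of throwing,
  so a whole table can be triaged at once.
* Duplicate sample or metabolite ids are an error, never auto-renamed.
* Intensities are kept on their raw scale by the reader; any log
  transformation is an explicit modelling choice (see below).

# The synthetic-data generator

`generate_complete()` draws log-intensities as

$$\log x_{ij} = \mu + \sum_{k=1}^{r} u_{ik}\, s_k\, v_{jk} +
  \varepsilon_{ij}, \qquad u_{ik}, v_{jk} \sim N(0,1),\;
  \varepsilon_{ij} \sim N(0, \sigma_\varepsilon^2),$$

and exponentiates, giving strictly positive, log-normal, column-wise
correlated data. The factor strengths $s_k$ halve with each component
($s_k \propto 2^{-(k-1)}$) and are normalized so the expected latent
variance per cell is `sd_log_intensity`². Defaults: `latent_rank = 3`,
`sd_log_intensity = 1`, `noise_sd = 0.3`, `mean_log_intensity = 7`.

Rationale: principal-component spectra of real LC–MS cohort data are
dominated by a first component (overall abundance and batch-scale
effects) with rapidly decaying tails, and the structured variation
clearly exceeds the residual technical noise. The defaults emulate that
signal-dominant regime — the regime in which well-matched model-based
imputation can be accurate — with per-metabolite dispersions on the
high end of cohort-scale studies. What the generator deliberately does
**not** emulate: batch boundaries and drift, QC-sample structure,
heavy-tailed outliers, metabolite classes with distinct noise models,
and missingness that is already present before amputation. Passing
tests on these data therefore demonstrate correctness of the
algorithms and calibration of the harness, not performance on any
particular real study.

# Amputation mechanisms

All amputers return the amputed matrix, the intact truth, and a
per-cell mechanism label; unmasked cells are never altered, and the
mask is a pure function of `(truth, pattern, seed)`.

* **MCAR**: each cell masked independently with the target probability.
* **MAR**: one fully observed *driver* metabolite (by default the
  highest-variance column) controls missingness in all other columns
  through a logistic link in its standardized log value,
  $\Pr(\text{miss}) = \text{logit}^{-1}(a - \beta z_i)$. The intercept
  $a$ is calibrated by bisection (to 0.5% relative) so the expected
  overall missing share hits the target; low-driver samples lose more
  cells. $\beta = 0$ degenerates exactly to MCAR, which the tests
  exploit.
* **MNAR-LOD**: each metabolite gets its own detection limit, the
  empirical `lod_quantile` of its true values — detection limits are
  compound-specific, so a global threshold would be wrong. In
  deterministic mode exactly the cells strictly below the column
  threshold are masked (exhaustively checkable); probabilistic mode
  uses a logistic taper of width 0.2 column-sd around the threshold.
* **Mixtures**: the missing-cell budget is split by weight and applied
  in the fixed order MNAR-LOD → MAR → MCAR on still-observed cells, so
  censoring acts on the genuinely small values before the random
  mechanisms consume budget. A deterministic LOD component derives its
  quantile from its budget share.

The default benchmark design crosses missing fractions
{0.1, 0.2, 0.3} with the three pure mechanisms plus one equal-weight
mixture (10 patterns) and 23 shapes from 20×10 to 500×200 — 230
scenarios. The shapes and patterns are this package's own defaults for
a broad, realistic sweep; they are not a reconstruction of any specific
published design.

# Imputation methods and their defaults

Eleven methods sit behind one dispatcher and one contract: observed
cells are returned bit-identical (imputation must never touch
non-missing data), converged results are complete, and every stochastic
method is a pure function of `(input, params, seed)` — there are no
hidden or hard-coded seeds.

| method | family | key defaults |
|---|---|---|
| `zero`, `min`, `half_min`, `mean`, `median` | constant | per-column statistics |
| `random` | random baseline | uniform in the column's observed range |
| `knn` | neighbour | `k = 5`, log scale |
| `svd` | low rank | `rank = 2`, `tol = 1e-4`, `max_iter = 100` |
| `iterative_pca` | iterative model | `ncomp = 2`, `regularization = 1` |
| `forest` | iterative model | `n_trees = 100`, `max_iter = 10` |
| `qrilc` | censored | `tune_sigma = 1` |

Hyperparameter defaults follow the conventions of the field's standard
implementations (e.g. two components is the common default for
iterative-PCA imputation); they are fixed and documented here rather
than tuned per dataset.

**Working scale.** Model-based methods (`svd`, `iterative_pca`,
`forest`, `qrilc`) and `knn` fit on the log scale by default, because
intensities are log-normal. For KNN this was a measured design
decision, not an aesthetic one: on raw log-normal data, Euclidean
distances are dominated by the few highest-abundance metabolites and
neighbour averages inherit the right tail's skew — raw-scale KNN fails
to beat even column-mean imputation on the synthetic protocol, while
log-scale KNN (whose neighbour mean is a geometric mean, preserving
scale-equivariance) roughly halves the error. Constant and random
strategies operate on the raw scale, where their definitions live.
Every method exposes `log_transform` so the caller can override.

Numerical notes: the low-rank loop measures convergence by the relative
change of imputed entries; the iterative-PCA shrinkage replaces each
retained singular value $\lambda$ by
$\lambda(\lambda^2 - \rho\hat\sigma^2)/\lambda^2$ (floored at zero)
with $\hat\sigma^2$ the mean discarded squared singular value and
$\rho$ the `regularization` weight, so $\rho = 0$ recovers the plain
SVD fixed point and `ncomp = 0` degenerates to column means. The
forest sweep visits metabolites by increasing missing fraction and
stops when the normalized change of imputed values first increases,
returning the previous sweep. QRILC fits the censored-normal model by
regressing observed order statistics on normal quantiles restricted to
the observed probability range, then draws from the fitted Gaussian
truncated above at the observed minimum. KNN breaks distance ties by
sample order for determinism; columns with no observed values are a
hard error for every method except `zero`.

# NRMSE

Accuracy is scored only on the masked cells, with each squared error
normalized by the **true variance of its own metabolite**:

$$\mathrm{NRMSE} = \sqrt{\;\underset{(i,j)\in\text{mask}}{\mathrm{mean}}
 \frac{(c_{ij} - t_{ij})^2}{\widehat{\mathrm{Var}}(t_{\cdot j})}\;}$$

Per-variable normalization is what makes the measure insensitive to
heteroscedasticity between metabolites — a single global normalization
would let high-variance metabolites dominate. The variance estimator is
the sample variance (denominator $n-1$, R's `var()`); with five truth
values $\{1\dots5\}$, masked truths $\{2,4\}$ and both imputed as 3,
$\mathrm{Var} = 2.5$ and NRMSE $= \sqrt{(1+1)/2/2.5} \approx 0.6325$,
the worked example frozen in the tests after verification against an
independent double-loop reference. Perfect imputation gives exactly 0;
column-mean imputation under MCAR tends to 1, a useful mental anchor.

# Benchmark harness

`run_scenario()` regenerates a scenario's data from its derived seed,
amputes, and runs the method inside a forked child process that is
killed once a wall-clock budget elapses (default 120 s per attempt, 3
attempts, stopping at the first success) — methods in this space
either finish quickly or grind indefinitely, and a harness must survive
both, as well as outright errors, without aborting the run. A method
failing all attempts is "not working" for that scenario. The summary
reports, per method: success rate (scenarios with ≥ 1 successful
attempt), mean and per-mechanism NRMSE over first successful attempts,
maximum wall time, and the split of failures between timeouts and
errors. `rank_methods()` orders by NRMSE or by maximum time and demotes
methods whose success rate falls below a floor (default 0.8): an
unstable method is not a recommendation, however accurate when it
happens to finish. Execution is serial; because every scenario is
regenerated from its own derived seed, results are independent of
execution order and the benchmark is resumable by scenario.

# Recommendations

`recommend_method()` with your own benchmark summary is a pure
reordering of `rank_methods()`. Without one it returns the shipped
default table: per-mechanism rankings whose accuracy leaders map the
per-pattern winners reported in the metabolomics imputation literature
onto this package's native families — random-forest for MCAR,
regularized iterative PCA for MAR, and the minimum-value heuristic for
LOD-driven MNAR — with the rest of each ranking ordered by family
suitability. The shipped table always carries a caveat saying exactly
that: it was not computed from your data. The package's own acceptance
tests regenerate a constant-family benchmark under MNAR-LOD and
confirm that `min` leads that family under left-censoring on the
default generator. Recommendations are never auto-applied; picking the
method remains an explicit user decision, made *before* looking at
which method best supports a desired conclusion.

# Problem sizes used by the tests

The test suite exercises the full stack at deliberately modest sizes:
oracle comparisons on ≤ 12×8 matrices, calibration checks at 10⁴
cells, the mixed-mechanism protocol at 100×50 over 10 replicates, the
harness semantics with a seconds-scale budget and a deliberately
sleeping method, and the regenerated recommendation benchmark on six
MNAR-LOD scenarios. These sizes were chosen so the whole suite
completes in a few minutes while every statistical assertion retains
comfortable power; all constants are visible in the tests themselves.

# Known limitations

* The MAR and MNAR parameterizations are reasonable, documented forms
  (logistic link; per-column empirical quantile thresholds), not
  reconstructions of any particular published amputation code.
* KNN is a plain sample-wise Euclidean implementation; truncated or
  weighted KNN variants are out of scope.
* The harness enforces timeouts via POSIX fork; on platforms without
  fork it falls back to inline execution without hard enforcement.
* The generator omits batch structure and outliers (see above), so
  absolute NRMSE values on real data will differ from synthetic ones;
  the *relative* ordering of methods per mechanism is the transferable
  result.
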