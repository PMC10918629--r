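# metimp

Missing-value imputation, amputation simulation and benchmarking for
metabolomics feature tables.

Mass-spectrometry metabolomics tables (samples × metabolite
intensities) are riddled with missing cells, and the missingness is
rarely innocent: besides values missing completely at random (MCAR) or
at random given other metabolites (MAR), a large share is *left-censored*
— intensities below the instrument's limit of detection (MNAR-LOD), so
precisely the small values are gone. Different imputation methods
behave very differently under these mechanisms, and picking one
blindly (or worse, post hoc) distorts downstream statistics. `metimp`
is for metabolomics analysts and methodologists who want to impute
with a method matched to their missingness mechanism, and to *verify*
that match by benchmark rather than folklore.

The package provides:

* a validated `intensity_matrix` data model with CSV/TSV I/O and the
  field's missing-value encodings (`NA` tokens; opt-in `0`/`1`
  markers);
* a ground-truthed amputation simulator for MCAR, MAR (logistic in an
  observed driver metabolite), MNAR-LOD (per-metabolite empirical
  detection limits) and weighted mixtures;
* eleven native imputation methods behind one contract — constant
  strategies (`zero`, `min`, `half_min`, `mean`, `median`), a
  `random`-range baseline, sample-wise Euclidean `knn`, low-rank `svd`
  completion, regularized `iterative_pca` (EM), missForest-style
  `forest`, and left-censored `qrilc` — which never alter observed
  cells and take explicit seeds;
* a benchmark harness with per-attempt wall-clock timeouts (default
  2 min × 3 attempts), failure isolation, stability accounting and
  rankings;
* a per-mechanism method recommender.

Imputation accuracy is scored by the normalized root mean squared
error over the masked cells, normalized per metabolite so that
high-variance metabolites cannot dominate:

```
NRMSE = sqrt( mean over masked (i,j) of (c_ij − t_ij)² / Var(t_·j) )
```

with `Var` the sample variance of the metabolite's true values.
Perfect imputation gives 0; column-mean imputation under MCAR gives ≈ 1.

## Worked example

```r
library(metimp)

# 60 samples x 30 metabolites of correlated log-normal intensities
cfg   <- simulation_config(n_samples = 60, n_metabolites = 30, seed = 11)
truth <- generate_complete(cfg)

# knock out 20% of cells: half MCAR, half detection-limit censoring
pat <- amputation_pattern("MIXTURE", missing_fraction = 0.2,
                          mixture_weights = c(MCAR = 0.5, MNAR_LOD = 0.5))
amp <- ampute(truth, pat, seed = 12)
amp
#> <amputation_result> 60 x 30, 360 masked cells (20.0%)
#>     MCAR MNAR_LOD
#>      180      180

missingness_summary(amp$amputed)
#> <missingness_summary> total missing fraction: 0.2000
#> per-metabolite fractions: min 0.133 / median 0.192 / max 0.283
#> per-sample fractions:     min 0.000 / median 0.200 / max 0.433

for (m in c("half_min", "min", "knn", "iterative_pca")) {
  res <- impute(amp$amputed, m, seed = 13)
  print(nrmse(amp$truth, res, amp$amputed$mask))
}
#> NRMSE 1.2299 over 360 imputed cells
#> NRMSE 1.0052 over 360 imputed cells
#> NRMSE 0.7007 over 360 imputed cells
#> NRMSE 0.6131 over 360 imputed cells
```

Reading the numbers: under a mixture that is half censoring, the
constant heuristics pay for their bias on the MCAR half (NRMSE ≥ 1, no
better than guessing the mean), while KNN and regularized iterative
PCA exploit the between-metabolite correlation and cut the error well
below the mean-imputation anchor of 1. On *pure* MNAR-LOD scenarios
the ordering flips in favour of `min` — which is exactly why the
recommender is mechanism-aware:

```r
recommend_method("MNAR_LOD", "accuracy")$ranked_methods[1:3]
#> [1] "min"      "half_min" "qrilc"
```

A command-line interface with `validate`, `simulate`, `ampute`,
`impute`, `benchmark` and `recommend` subcommands ships at
`system.file("cli", "metimp.R", package = "metimp")`; exit codes are
0 (success), 1 (validation/convergence failure), 2 (usage error).

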