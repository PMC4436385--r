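# rrscurve

Sample-size planning for supervised classifiers from small pilot cohorts.

Clinical imaging studies typically have to pick a classifier — and budget the
cohort — long before a large annotated dataset exists. `rrscurve` estimates
how a two-class classifier's error rate will fall as the training set grows,
using only the pilot data: it measures error at a grid of training-set sizes
`n` by repeated random subsampling (RRS) nested inside a stratified K-fold
rotation, screens each size against a permutation null of label-randomized
classifiers, and fits the inverse power law

    e(n) = a * n^(-alpha) + b,      a, alpha, b >= 0

where `a` is the learning rate, `alpha` the decay rate, and `b` the Bayes
error — the extrapolated floor with unlimited data. A traditional-RRS
baseline (one fixed split, matched number of classification tasks, no
rotation), interquartile-range stability summaries, leave-one-out validation
on a larger cohort, and patient-level (grouped) sampling for pixel/metavoxel
data are included, along with kNN, Gaussian naive Bayes and RBF-SVM adapters
behind one train/predict contract and a two-class Gaussian synthetic-data
generator for end-to-end validation.

## Worked example

Estimate learning curves for a kNN (k = 3) classifier on a synthetic
100-sample pilot (two 2-D Gaussian classes, unit covariance, mean separation
2 — analytic Bayes error Φ(−1) ≈ 0.1587), compare both engines, and validate
against leave-one-out error on a 500-sample cohort:

```r
library(rrscurve)

pilot      <- gaussian_two_class(gaussian_spec(seed = 11))
validation <- gaussian_two_class(gaussian_spec(n_per_class = 250, seed = 12))

cfg <- rrs_config(T2 = 20, seed = 7)          # K=4, R=10, T1=50 defaults
rep <- compare_methods(pilot, size_grid(seq(25, 55, 5)), cfg,
                       validation = validation)
print(rep)
#> <comparison_report> kNN (k=3)
#>   mean IQR: with CV 0.0076 | traditional 0.0914 (ratio 0.084)
#>   validation LOO error: 0.1980 (at n = 499)
#>   predicted error (CV mean curve):
#>    n predicted_error
#>   55          0.1855
#>  499          0.1855

print(rep$cv)
#> <curve_bundle> cross-validated RRS
#>   n mean_error    p25    p75      iqr p_value valid
#>  25     0.1894 0.1841 0.1946 0.010527 0.01383  TRUE
#>  30     0.1864 0.1833 0.1873 0.004070 0.01130  TRUE
#>  35     0.1836 0.1787 0.1893 0.010570 0.00800  TRUE
#>  40     0.1860 0.1805 0.1883 0.007805 0.00625  TRUE
#>  45     0.1866 0.1833 0.1878 0.004519 0.00555  TRUE
#>  50     0.1859 0.1826 0.1870 0.004355 0.00475  TRUE
#>  55     0.1860 0.1800 0.1917 0.011667 0.00435  TRUE
#>   valid sizes M: 25, 30, 35, 40, 45, 50, 55
#>   mean IQR over M: 0.007645
#>   Bayes error estimate b = 0.1855
```

Reading the output: every size passed the permutation screen
(`p_value < 0.05`), so all seven mean errors enter the fit. The rotation
makes the cross-validated estimates an order of magnitude more stable than
the fixed-split baseline (mean IQR 0.0076 vs 0.0914). The pilot's error
curve is already nearly flat for this classifier, so the extrapolated error
at n = 499 equals the fitted floor b = 0.1855 — close to, and as expected
slightly above, the analytic Bayes error 0.1587, with the validation LOO
error 0.198 nearby. `plot(rep$cv, loo = rep$loo, loo_n = rep$loo_n)` draws
the mean and P25/P75 curves with the LOO marker.

A command-line wrapper with `simulate`, `run`, `compare`, `fit` and
`validate` subcommands is installed under `exec/` (see
`Rscript exec/rrscurve` from the source tree).

For patient-level data where each patient contributes many pixels or
metavoxels of both classes, set `grouped = TRUE` in `rrs_config()` and
supply a `group_id` column: all partitioning then happens at the patient
level and sizes count patients.

See the vignette (`vignettes/learning-curves.Rmd`) for the model,
conventions (quantile type, null construction, RNG keying) and limitations.

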