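---
title: "Extrapolating classifier error rates from pilot cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extrapolating classifier error rates from pilot cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Supervised classifiers in medical-imaging studies are usually chosen early,
when only a small pilot cohort is annotated. Two questions then matter: how
will the error rate of a classifier improve as the cohort grows, and will the
classifier that looks best on the pilot still be best at scale? `rrscurve`
answers both by estimating a *learning curve* — error rate as a function of
training-set size $n$ — from the pilot alone, and extrapolating it with the
inverse power law

$$\bar e(n) = a\,n^{-\alpha} + b, \qquad a, \alpha, b \ge 0,$$

where $a$ is the learning rate, $\alpha$ the decay rate, and the intercept
$b$ estimates the Bayes error, the lowest error attainable with unlimited
training data.

## The resampling engine

Error rates at each size are estimated by repeated random subsampling (RRS)
nested inside a stratified $K$-fold rotation:

1. The pilot is partitioned into $K$ class-stratified pools; fold $k$ tests
   on pool $k$ and draws training subsets from the remaining $K-1$ pools.
2. For each size $n$ in the grid, $T_1$ subsets of $n$ samples are drawn
   without replacement from the training pool (class-stratified, so that
   sizes as small as $n = 2$ remain trainable); each subset trains a
   classifier that is evaluated on the *entire* testing pool, giving
   replicate errors $e_i(n)$ and a fold mean $\bar e_{k,r}(n)$.
3. The pools rotate so every sample is tested exactly once per repeat, and
   the whole process is repeated $R$ times with a fresh partition each time.
   The comprehensive mean $\bar e(n) = \frac{1}{KR}\sum_{k,r}\bar e_{k,r}(n)$
   feeds the curve fit.

The *traditional RRS* baseline skips the rotation: one fixed stratified
split (training fraction $(K-1)/K$, so pool sizes match) and $T_1 K R$
replicates per size against the fixed testing pool — the same number of
classification tasks as the cross-validated engine, which keeps the
stability comparison fair.

Repeats use a fresh random partition each time. Read literally, "repeated
cross-validation" could also reuse one partition; we re-randomize because
independent repeats are the field's standard and because a single partition
would make the repeat-to-repeat spread blind to partition variability. The
consequence is documented under *Stability summaries* below.

### Defaults

| Parameter | Default | Meaning |
|---|---|---|
| `K` | 4 | cross-validation folds |
| `R` | 10 | independent repeats (re-partitioned) |
| `T1` | 50 | training subsets per size and fold |
| `T2` | 50 | label-randomized replicates per subset |
| `alpha` | 0.05 | significance level of the permutation screen |

These defaults are the framework's reference protocol; all are plain
arguments of `rrs_config()`.

## The permutation screen

A mean error at size $n$ enters the curve fit only if it beats label noise.
For every actual subset, `T2` *null* classifiers are trained on
label-randomized training data of the same size and evaluated on the same
testing pool. The p-value counts null errors the actual mean fails to beat:

$$P_n = \frac{1}{T_1 T_2}\sum_{i}\sum_{j} \theta\!\left(\bar e(n) - \hat e_{i,j}(n)\right),
\qquad \theta(z) = \mathbf 1\{z \ge 0\},$$

and $n$ is kept only when $P_n < 0.05$ (strict). Only the kept sizes
$M = \{n : P_n < \alpha\}$ are fitted. Two conventions deserve comment:

* **Direction of the count.** $\theta(\bar e - \hat e)$ counts null errors
  *at or below* the actual mean; a small $P_n$ therefore certifies genuine
  learning. (Counting nulls *above* the mean would invert the test and make
  $P_n < 0.05$ certify chance-level behaviour.)
* **Null construction.** Each null replicate draws a fresh random subset of
  the training pool and then randomizes its labels by permutation, which
  preserves the class marginal and is the standard exchangeability null;
  `rrs_config(null_subsets = "same")` reuses the actual subset's rows and
  `null_labels = "iid"` switches to coin-flip labels.
* **Pooling.** $P_n$ is defined within one pool pass; across the $K \times R$
  passes we pool all $K R T_1 T_2$ null errors against the comprehensive
  mean. Per-fold p-values remain available as a diagnostic
  (`attr(significance_table(res), "per_fold")`).

## Curve fitting

`fit_power_law()` minimizes $\sum_{m}(a n_m^{-\alpha} + b - \bar e(n_m))^2$
subject to $a, \alpha, b \ge 0$. For fixed $\alpha$ the problem is linear
least squares in $(a, b)$ with closed-form solution (projected onto the
feasible boundary when needed), so the optimizer is a 60-point log-spaced
multi-start over $\alpha \in [0.01, 3]$ followed by a bounded 1-D refinement
between the neighbouring grid points at tolerance $10^{-10}$. SSE ties
resolve to the smallest $\alpha$. Three or more valid sizes are required
(three free parameters); noiseless power-law series are recovered to
$|\Delta| < 10^{-4}$ per parameter.

`predict_error(fit, n)` evaluates the law; `n = Inf` returns $\hat b$, the
extrapolated Bayes error. P25 and P75 learning curves are fitted to the
per-size quartiles of the engine's error distribution over the same valid
set $M$, using type-7 (linear-interpolation) quantiles throughout — IQR
values depend on the quantile rule, so it is fixed and documented.

## Stability summaries

The stability metric is the per-size interquartile range
$\mathrm{IQR}(n) = P_{75}(n) - P_{25}(n)$ and its mean over sizes
$\overline{\mathrm{IQR}}$. The two engines are summarised over different
distributions, on purpose:

* the **traditional** engine has only one natural unit, its raw replicate
  errors against the fixed testing pool;
* the **cross-validated** engine is summarised over its $R$ per-repeat
  comprehensive means. Within one repeat every sample is tested exactly
  once, so the mean over the $K$ folds integrates out test-pool-difficulty
  noise, and the repeat-to-repeat spread isolates what the rotation cannot
  remove: subsampling and partition variability. Quantiles over raw pooled
  replicates would be dominated by the per-replicate binomial noise of small
  testing pools in *both* arms and would say nothing about the rotation.

Both conventions are overridable (`iqr_summary(res, units = ...)`). Because
repeats are re-partitioned, partition variance is part of the cross-validated
spread; for pilots with many borderline samples the CV
$\overline{\mathrm{IQR}}$ can approach — for unlucky fixed splits of the
traditional arm, occasionally exceed — the traditional value, which is
itself highly variable from split to split. Arm-level
$\overline{\mathrm{IQR}}$ comparisons in `compare_methods()` run over the
full size grid: the significance screen can legitimately reject *every* size
of a badly split traditional arm (observed in practice: a fixed split whose
testing pool is far harder than average), and the filtered mean would then
be undefined. Per-bundle summaries keep the filter.

## Grouped (pixel/voxel) data

Radiological data are classified per pixel or metavoxel while independence
holds only between patients. In grouped mode every partitioning step —
pools, training subsets, leave-one-out folds — operates on patient
identifiers, and classifiers are trained and evaluated on all rows of the
selected patients, so no patient contributes to both sides of any split.
Group sizes in the size grid then count patients, not rows. When groups span
both classes (the pixel-level case) pool stratification falls back to group
counts alone.

## The synthetic generator

`gaussian_two_class()` emulates the validation setup the framework was
designed around: two classes drawn from two-dimensional Gaussians, a
100-sample pilot (50 per class) and a 500-sample validation cohort. The
default specification — unit covariance, means $(0,0)$ and $(2,0)$ — is a
reconstruction chosen for its analytic Bayes error
$\Phi(-1) \approx 0.1587$ and realistic class overlap; the original
Gaussian parameters are not recoverable, so synthetic benchmarks are
order-of-magnitude and inequality checks, not equalities.
`grouped_two_class()` adds patient-specific mean offsets on top of the class
Gaussians to mimic intra-patient pixel correlation. What the generator does
*not* emulate: feature selection upstream of the table, heavy-tailed or
discrete feature distributions, class imbalance, and annotation noise —
conclusions from passing synthetic tests transfer to real data only to the
extent those factors are benign.

`powerlaw_error_oracle()` generates exact (optionally noise-perturbed)
power-law series for testing the fitting stage against known ground truth.

## Numerical choices and edge cases

* **Classifiers.** kNN (default $k = 3$), Gaussian naive Bayes, and an
  RBF-kernel SVM (via libsvm; default $C = 1$,
  $\gamma = 1/(d \cdot \mathrm{Var}(X))$) sit behind one train/predict
  contract. kNN and naive Bayes are implemented in-package so determinism
  can be pinned: distance ties at the $k$-th neighbour break to the lowest
  training row index, vote ties to the class of the single nearest
  neighbour, and naive Bayes floors per-feature variances at
  $10^{-9}\max_f \mathrm{Var}(x_f)$. Feature standardization is off by
  default; when on, its parameters are fitted on the training subset only.
* **Reproducibility.** One root seed; every (stage, fold, repeat, size,
  replicate) tuple derives its own RNG stream via `child_seed()`, so any
  replicate can be recomputed in isolation and results are independent of
  execution order. kNN replicates are evaluated by a compiled kernel against
  a per-fold distance matrix; the kernel follows the same RNG sequence as
  the generic train/predict path and the test suite asserts the two paths
  produce identical engine results.
* **Degenerate inputs.** Single-class training subsets are prevented by
  stratified draws (or redrawn up to 100 times when unstratified); constant
  error series fit as $b = \text{const}$ with $a \approx 0$; rising error
  series hit the non-negativity constraints and return the best
  non-increasing fit rather than failing.

## Problem sizes used in the checks

The package's end-to-end checks run the reference protocol ($K = 4$,
$R = 10$, $T_1 = 50$) on the 100-sample pilot over
$N = \{25, \dots, 55\}$, with $T_2 = 50$ in the acceptance script and
$T_2 = 20$ in the test suite — the unfiltered IQR statistics are unaffected
by $T_2$, since the keyed RNG streams make actual replicate draws
independent of the permutation stage. Property sweeps (pool invariants,
p-value oracle, fit recovery) use thousands of small randomized instances
under fixed seeds.

## Known limitations

* Extrapolation inherits the power law's bias: if the true learning curve
  leaves the power-law family (e.g. plateaus early), $\hat b$ is biased and
  no alternative families are provided.
* The LOO validation marker is itself an optimistic estimator, and for
  unstable classifiers (notably kNN) the extrapolated band can sit above it.
* Imbalanced cohorts are out of scope; subsets are drawn class-balanced.
* The permutation screen's pooled p-value treats folds as exchangeable;
  per-fold p-values are reported but not combined by a dependence-aware
  rule.
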