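# Shared fixtures and independent reference implementations used as oracles.

# Small well-separated two-cluster dataset: class1 near the origin, class2
# near (10, 10); kNN/NB/SVM should all classify it perfectly.
separated_clusters <- function(n_per_class = 10, seed = 404) {
  gaussian_two_class(gaussian_spec(
    mean1 = c(0, 0), mean2 = c(10, 10),
    cov1 = 0.25 * diag(2), cov2 = 0.25 * diag(2),
    n_per_class = n_per_class, seed = seed))
}

default_pilot <- function(seed = 11) gaussian_two_class(gaussian_spec(seed = seed))

# Reference kNN, written independently of the compiled kernel: full ordering
# by (distance, training row) with the same tie rules, in plain R.
ref_knn_predict <- function(xtr, ytr, xte, k) {
  k <- min(k, nrow(xtr))
  apply(xte, 1, function(pt) {
    d2 <- colSums((t(xtr) - pt)^2)
    ord <- order(d2, seq_along(d2))
    top <- ytr[ord[seq_len(k)]]
    c1 <- sum(top == 1L)
    if (c1 > k - c1) 1L else if (c1 < k - c1) 2L else ytr[ord[1]]
  })
}

# Brute-force permutation p-value: literal theta-count loop.
ref_pvalue <- function(mean_error, null) {
  cnt <- 0L
  for (z in null) if (mean_error - z >= 0) cnt <- cnt + 1L
  cnt / length(null)
}

# Dense brute-force power-law fit: fine alpha grid, closed-form (a, b) by
# unconstrained least squares projected onto the feasible region.
ref_powerlaw_sse <- function(sizes, errors, alphas = seq(0.01, 3, by = 0.002)) {
  best <- Inf
  for (al in alphas) {
    w <- sizes^(-al)
    fit <- stats::lm.fit(cbind(w, 1), errors)
    a <- max(0, fit$coefficients[1]); b <- max(0, fit$coefficients[2])
    sse <- sum((a * w + b - errors)^2)
    # boundary candidates when projection is not optimal
    sse <- min(sse,
               sum((max(0, mean(errors)) - errors)^2),
               sum((max(0, sum(w * errors) / sum(w * w)) * w - errors)^2))
    if (sse < best) best <- sse
  }
  best
}
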