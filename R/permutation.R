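# Permutation-based significance screen for mean error rates.
#
# Null classifiers are trained on label-randomized subsets of the training
# pool and evaluated on the testing pool. A size n is kept for curve fitting
# only when the actual mean error beats the null distribution: the p-value
# counts null errors at or below the mean,
#   P_n = (1/T1)(1/T2) * sum_i sum_j theta(ebar(n) - ehat_{i,j}(n)),
# with theta(z) = 1 for z >= 0 and 0 otherwise, and n is valid when
# P_n < alpha.

#' Null error rates for one training subset
#'
#' Produces `T2` error rates of classifiers trained on label-randomized
#' training data and evaluated on the entire testing pool. By default each
#' null replicate draws a fresh random subset of the training pool (same size
#' as the actual subset) before randomizing its labels; `subsets = "same"`
#' reuses the actual subset's rows.
#'
#' @param data a [feature_dataset()].
#' @param subset row indices of the actual training subset \eqn{S_i(n)}.
#' @param pool_train,pool_test row indices of the training and testing pools.
#' @param T2 number of null replicates.
#' @param spec a [classifier_spec()].
#' @param seed RNG seed.
#' @param subsets `"fresh"` (default) or `"same"`, see above.
#' @param labels `"permute"` (default) shuffles true labels, preserving class
#'   proportions; `"iid"` flips fair coins (single-class outcomes redrawn, up
#'   to 100 times).
#' @return numeric vector of `T2` null error rates.
#' @export
null_errors <- function(data, subset, pool_train, pool_test, T2,
                        spec = classifier_spec("knn"), seed = 1L,
                        subsets = c("fresh", "same"),
                        labels = c("permute", "iid")) {
  subsets <- match.arg(subsets)
  labels <- match.arg(labels)
  if (T2 < 1L) stop("T2 must be >= 1")
  n <- length(subset)
  with_seed(seed, {
    vapply(seq_len(T2), function(j) {
      rows <- if (subsets == "fresh")
        pool_train[sample.int(length(pool_train), n)] else subset
      y <- .null_labels(data$label[rows], labels)
      model <- train_classifier(spec, data$features[rows, , drop = FALSE], y)
      error_rate(model, data$features[pool_test, , drop = FALSE],
                 data$label[pool_test])
    }, numeric(1))
  })
}

#' Permutation p-value for a mean error rate
#'
#' The fraction of null errors that the actual mean error rate matches or
#' beats: \eqn{P_n = \frac{1}{|null|}\sum \theta(\bar e(n) - \hat e)} with
#' \eqn{\theta(z) = 1} for \eqn{z \ge 0}. Small values mean the classifier
#' performs genuinely better than label noise.
#'
#' @param mean_error the actual mean error rate \eqn{\bar e(n)}.
#' @param null numeric vector of null error rates (non-empty).
#' @return the p-value in \[0, 1\].
#' @export
permutation_pvalue <- function(mean_error, null) {
  if (!length(null)) stop("null error list is empty")
  mean(mean_error - null >= 0)
}

#' Significance table over a size grid
#'
#' Computes the pooled permutation p-value per size (all `K*R*T1*T2` null
#' errors against the comprehensive mean error) and flags the sizes that pass
#' `P_n < alpha`. Per-(fold, repeat) p-values — each fold's `T1*T2` null
#' errors against that fold's mean — are attached as a diagnostic.
#'
#' @param result an `engine_result` with null records.
#' @param alpha significance level; defaults to the run configuration's.
#' @return a data.frame with columns `n`, `p_value`, `valid`, `n_null`, and
#'   attribute `per_fold` (columns `n`, `k`, `r`, `p_value`).
#' @export
significance_table <- function(result, alpha = NULL) {
  if (is.null(result$null_records))
    stop("engine result holds no null errors; run with run_permutation = TRUE")
  if (is.null(alpha)) alpha <- result$config$alpha
  nulls <- result$null_records
  means <- result$means
  tab <- do.call(rbind, lapply(seq_len(nrow(means)), function(ii) {
    nn <- means$n[ii]
    z <- nulls$error[nulls$n == nn]
    data.frame(n = nn, p_value = permutation_pvalue(means$error[ii], z),
               n_null = length(z))
  }))
  tab$valid <- tab$p_value < alpha
  tab <- tab[, c("n", "p_value", "valid", "n_null")]
  fm <- result$fold_means
  per_fold <- do.call(rbind, lapply(seq_len(nrow(fm)), function(ii) {
    sel <- nulls$n == fm$n[ii] & nulls$k == fm$k[ii] & nulls$r == fm$r[ii]
    data.frame(n = fm$n[ii], k = fm$k[ii], r = fm$r[ii],
               p_value = permutation_pvalue(fm$error[ii], nulls$error[sel]))
  }))
  attr(tab, "per_fold") <- per_fold
  attr(tab, "alpha") <- alpha
  tab
}

#' Valid training-set sizes
#'
#' Restricts the size grid to the sizes whose mean error passed the
#' permutation screen, \eqn{M = \{n : n \in N, P_n < \alpha\}}; only these
#' enter the power-law fit.
#'
#' @param grid a [size_grid()].
#' @param table a [significance_table()] covering every size in `grid`.
#' @return integer vector `M`, in grid order.
#' @export
filter_valid_sizes <- function(grid, table) {
  grid <- as.integer(grid)
  missing <- setdiff(grid, table$n)
  if (length(missing))
    stop("significance table does not cover sizes: ",
         paste(missing, collapse = ", "))
  grid[grid %in% table$n[table$valid]]
}
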