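# Resampling engines.
#
# The cross-validated engine nests T1 random training subsets per size inside
# a stratified K-fold rotation repeated R times: every repeat re-partitions
# the data, every fold trains on subsets of its training pool and evaluates
# each classifier on the entire held-out testing pool, so that within one
# repeat every sample is tested exactly once. The traditional engine is the
# baseline without rotation: one fixed stratified split and T1*K*R subset
# replicates per size against the fixed testing pool, matching the total
# number of classification tasks.
#
# kNN replicates are evaluated through a compiled kernel against a squared
# distance matrix computed once per fold; all other families (and kNN with
# standardization) take the generic train/predict path. The two paths are
# equivalent and tested as such.

.sq_dist <- function(a, b) {
  d <- outer(rowSums(a * a), rep(1, nrow(b))) +
    outer(rep(1, nrow(a)), rowSums(b * b)) - 2 * tcrossprod(a, b)
  d[d < 0] <- 0
  d
}

# Permute (or coin-flip) a label factor for one null replicate; guarantees
# both classes are present.
.null_labels <- function(labels, scheme) {
  if (scheme == "permute") return(sample(labels))
  for (attempt in 1:100) {
    y <- factor(levels(labels)[sample.int(2L, length(labels), replace = TRUE)],
                levels = levels(labels))
    if (length(unique(as.integer(y))) == 2L) return(y)
  }
  stop("failed to draw a two-class random labelling in 100 attempts")
}

# One pass over a single (fold, repeat) pool: all sizes, T1 actual replicates
# each, plus T2 null replicates per actual replicate when requested.
.pool_pass <- function(data, pool, grid, config, k, r, stage) {
  spec <- config$classifier
  train_rows <- pool$train
  test_rows <- pool$test
  y_test <- data$label[test_rows]
  y_pool <- data$label[train_rows]
  n_act <- length(grid) * config$T1
  n_nul <- if (config$run_permutation) n_act * config$T2 else 0L

  grouped <- config$grouped
  if (grouped) {
    units <- pool$train_groups
    rows_of_unit <- lapply(units, function(g)
      which(data$group_id[train_rows] == g))
    unit_class <- vapply(rows_of_unit, function(ix) {
      cl <- unique(as.integer(y_pool[ix]))
      if (length(cl) == 1L) cl else NA_integer_
    }, integer(1))
    unit_labels <- if (anyNA(unit_class)) NULL else
      factor(levels(y_pool)[unit_class], levels = levels(y_pool))
    sample_pool <- seq_along(units)
  } else {
    sample_pool <- seq_along(train_rows)
    unit_labels <- y_pool
  }

  fast_knn <- spec$family == "knn" && !spec$standardize
  if (fast_knn) {
    D <- .sq_dist(data$features[test_rows, , drop = FALSE],
                  data$features[train_rows, , drop = FALSE])
    y_pool_int <- as.integer(y_pool)
    y_test_int <- as.integer(y_test)
  }

  eval_subset <- function(sub_pos, labels_sub) {
    if (fast_knn) {
      cpp_knn_error_pool(D, sub_pos, y_pool_int, integer(0),
                         as.integer(labels_sub), y_test_int,
                         min(spec$k, length(sub_pos)))
    } else {
      model <- train_classifier(
        spec, data$features[train_rows[sub_pos], , drop = FALSE], labels_sub)
      error_rate(model, data$features[test_rows, , drop = FALSE], y_test)
    }
  }

  draw_positions <- function(n) {
    if (grouped) {
      sel <- draw_subset(sample_pool, n, seed = NULL,
                         stratified = config$stratified_subsets &&
                           !is.null(unit_labels),
                         labels = unit_labels)
      sort(unlist(rows_of_unit[sel]))
    } else {
      sort(draw_subset(sample_pool, n, seed = NULL,
                       stratified = config$stratified_subsets,
                       labels = unit_labels))
    }
  }

  a_n <- integer(n_act); a_i <- integer(n_act); a_e <- numeric(n_act)
  if (n_nul) {
    z_n <- integer(n_nul); z_i <- integer(n_nul); z_j <- integer(n_nul)
    z_e <- numeric(n_nul)
  }
  ai <- 0L; zi <- 0L

  if (fast_knn && !grouped) {
    # Tight path for ungrouped kNN: identical RNG sequence to the generic
    # path (same sample.int calls in the same order), integer labels, and the
    # compiled distance-matrix kernel. Equivalence with the generic path is
    # asserted in the test suite.
    pos1 <- which(y_pool_int == 1L); l1 <- length(pos1)
    pos2 <- which(y_pool_int == 2L); l2 <- length(pos2)
    lp <- length(sample_pool)
    stratified <- config$stratified_subsets
    permute <- config$null_labels == "permute"
    fresh <- config$null_subsets == "fresh"
    kk <- spec$k
    T1 <- config$T1; T2 <- if (config$run_permutation) config$T2 else 0L
    draw_fast <- if (stratified) function(n) {
      n1 <- n %/% 2L; n2 <- n - n1
      if (n1 != n2 && sample.int(2L, 1L) == 1L) { t <- n1; n1 <- n2; n2 <- t }
      if (n1 > l1 || n2 > l2)
        stop("class '", levels(y_pool)[if (n1 > l1) 1 else 2],
             "' has too few pool members for a stratified draw of size ", n)
      c(pos1[sample.int(l1, n1)], pos2[sample.int(l2, n2)])
    } else function(n) {
      if (n < 2L) return(sample.int(lp, n))
      for (attempt in 1:100) {
        s <- sample.int(lp, n)
        if (any(y_pool_int[s] == 1L) && any(y_pool_int[s] == 2L))
          return(s)
      }
      stop("failed to draw a two-class subset of size ", n, " in 100 attempts")
    }
    none <- integer(0)
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old_seed <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    for (n in grid) {
      for (i in seq_len(T1)) {
        set.seed(child_seed(config$seed, stage, k, r, n, i))
        sub <- draw_fast(n)
        ai <- ai + 1L
        a_n[ai] <- n; a_i[ai] <- i
        a_e[ai] <- cpp_knn_error_pool(D, sub, y_pool_int, none, none,
                                      y_test_int, min(kk, length(sub)))
        if (T2) for (j in seq_len(T2)) {
          nsub <- if (fresh) draw_fast(n) else sub
          ns <- length(nsub)
          zi <- zi + 1L
          z_n[zi] <- n; z_i[zi] <- i; z_j[zi] <- j
          z_e[zi] <- if (permute) {
            cpp_knn_error_pool(D, nsub, y_pool_int, sample.int(ns), none,
                               y_test_int, min(kk, ns))
          } else {
            ok <- FALSE
            for (attempt in 1:100) {
              yy <- sample.int(2L, ns, replace = TRUE)
              if (any(yy == 1L) && any(yy == 2L)) { ok <- TRUE; break }
            }
            if (!ok) stop("failed to draw a two-class random labelling")
            cpp_knn_error_pool(D, nsub, y_pool_int, none, yy, y_test_int,
                               min(kk, ns))
          }
        }
      }
    }
    if (has_old) assign(".Random.seed", old_seed, envir = globalenv())
  } else {
    for (n in grid) {
      for (i in seq_len(config$T1)) {
        seed_i <- child_seed(config$seed, stage, k, r, n, i)
        with_seed(seed_i, {
          sub <- draw_positions(n)
          ai <- ai + 1L
          a_n[ai] <- n; a_i[ai] <- i
          a_e[ai] <- eval_subset(sub, y_pool[sub])
          if (config$run_permutation) {
            for (j in seq_len(config$T2)) {
              nsub <- if (config$null_subsets == "fresh") draw_positions(n)
                      else sub
              zi <- zi + 1L
              z_n[zi] <- n; z_i[zi] <- i; z_j[zi] <- j
              z_e[zi] <- eval_subset(nsub,
                                     .null_labels(y_pool[nsub],
                                                  config$null_labels))
            }
          }
        })
      }
    }
  }
  list(
    actual = data.frame(n = a_n, k = k, r = r, i = a_i, error = a_e),
    null = if (n_nul)
      data.frame(n = z_n, k = k, r = r, i = z_i, j = z_j, error = z_e)
    else NULL
  )
}

.bind_passes <- function(passes, what) {
  parts <- lapply(passes, `[[`, what)
  parts <- parts[!vapply(parts, is.null, logical(1))]
  if (!length(parts)) NULL else do.call(rbind, parts)
}

.aggregate_means <- function(actual) {
  fold <- aggregate(error ~ n + k + r, data = actual, FUN = mean)
  rep_means <- aggregate(error ~ n + r, data = fold, FUN = mean)
  comp <- aggregate(error ~ n, data = rep_means, FUN = mean)
  list(fold_means = fold[order(fold$n, fold$r, fold$k), ],
       repeat_means = rep_means[order(rep_means$n, rep_means$r), ],
       means = comp[order(comp$n), ])
}

.engine_result <- function(engine, passes, grid, config) {
  actual <- .bind_passes(passes, "actual")
  nulls <- .bind_passes(passes, "null")
  agg <- .aggregate_means(actual)
  structure(
    list(engine = engine, records = actual, null_records = nulls,
         fold_means = agg$fold_means, repeat_means = agg$repeat_means,
         means = agg$means, grid = grid, config = config),
    class = "engine_result"
  )
}

#' @export
print.engine_result <- function(x, ...) {
  cat("<engine_result> ", if (x$engine == "cv") "cross-validated RRS"
      else "traditional RRS", ", ", format(x$config$classifier), "\n", sep = "")
  cat("  sizes n: ", paste(x$grid, collapse = ", "), "\n", sep = "")
  cat("  actual replicates per n: ", sum(x$records$n == x$grid[1]),
      if (!is.null(x$null_records))
        paste0("; null replicates per n: ",
               sum(x$null_records$n == x$grid[1])), "\n", sep = "")
  m <- x$means
  cat("  mean error: ",
      paste(sprintf("%d:%.4f", m$n, m$error), collapse = "  "), "\n", sep = "")
  invisible(x)
}

#' Subsampling error rates for one training pool and one size
#'
#' Draws `T1` independent training subsets of size `n` from the training
#' pool, trains a classifier on each and evaluates it on the entire testing
#' pool, returning the replicate error rates \eqn{e_i(n)} and their mean
#' \eqn{\bar e(n) = \frac{1}{T_1}\sum_i e_i(n)}.
#'
#' @param data a [feature_dataset()].
#' @param pool_train,pool_test row indices of the training and testing pools.
#' @param n training-set size.
#' @param T1 number of subsampling replicates.
#' @param spec a [classifier_spec()].
#' @param seed RNG seed.
#' @param stratified draw subsets class-stratified.
#' @return a list with `errors` (length `T1`) and `mean`.
#' @export
subsampling_errors <- function(data, pool_train, pool_test, n, T1,
                               spec = classifier_spec("knn"), seed = 1L,
                               stratified = TRUE) {
  if (n > length(pool_train))
    stop("n = ", n, " exceeds the training pool (", length(pool_train), ")")
  if (T1 < 1L) stop("T1 must be >= 1")
  cfg <- rrs_config(K = 2L, R = 1L, T1 = as.integer(T1), T2 = 1L,
                    classifier = spec, seed = seed,
                    stratified_subsets = stratified, run_permutation = FALSE)
  pool <- structure(list(fold = 1L, train = pool_train, test = pool_test),
                    class = "pool_assignment")
  pass <- .pool_pass(data, pool, as.integer(n), cfg, k = 1L, r = 1L,
                     stage = "subset")
  list(errors = pass$actual$error, mean = mean(pass$actual$error))
}

#' Cross-validated repeated-random-sampling error rates
#'
#' Runs the full nested resampling: for each repeat `r` the dataset is
#' re-partitioned into `K` stratified pools; each fold's training pool is
#' subsampled `T1` times per training-set size and every classifier is
#' evaluated on the entire testing pool, rotating the pools so each repeat
#' tests every sample exactly once. Fold means \eqn{\bar e_{k,r}(n)} and the
#' comprehensive mean \eqn{\bar e(n) = \frac{1}{KR}\sum_{k}\sum_{r}
#' \bar e_{k,r}(n)} are recorded, along with every replicate error and (when
#' `run_permutation`) every label-randomized null error.
#'
#' In grouped mode the partition and the subsets are patient-level and the
#' classifiers are trained and evaluated on all rows (pixels/metavoxels) of
#' the selected patients.
#'
#' @param data a [feature_dataset()].
#' @param grid a [size_grid()]; validated against the training pool of the
#'   chosen `K`.
#' @param config an [rrs_config()].
#' @return an `engine_result` with elements `records` (actual replicate
#'   errors, columns n/k/r/i/error), `null_records` (n/k/r/i/j/error),
#'   `fold_means`, `repeat_means`, `means`, `grid`, `config`.
#' @export
cross_validated_errors <- function(data, grid, config = rrs_config()) {
  grid <- if (inherits(grid, "size_grid")) grid else size_grid(grid)
  pool_units <- if (config$grouped) length(unique(data$group_id))
                else n_samples(data)
  validate_size_grid(grid, pool_units - ceiling(pool_units / config$K))
  passes <- list()
  for (r in seq_len(config$R)) {
    pools <- make_stratified_pools(
      data, config$K, seed = child_seed(config$seed, "pools", r),
      grouped = config$grouped)
    for (k in seq_len(config$K)) {
      passes[[length(passes) + 1L]] <-
        .pool_pass(data, pools[[k]], grid, config, k = k, r = r,
                   stage = "subset")
    }
  }
  .engine_result("cv", passes, grid, config)
}

#' Traditional repeated-random-sampling error rates (no rotation)
#'
#' The baseline scheme: one fixed stratified train/test split (training
#' fraction `(K-1)/K`, matching the cross-validated pool sizes) and
#' `T1 * K * R` subsampling replicates per size against the fixed testing
#' pool, so both engines perform the same number of classification tasks.
#'
#' @inheritParams cross_validated_errors
#' @return an `engine_result` (engine `"traditional"`); replicate indices
#'   `i` run over `1..T1*K*R` with `k = r = 1`.
#' @export
traditional_rrs_errors <- function(data, grid, config = rrs_config()) {
  grid <- if (inherits(grid, "size_grid")) grid else size_grid(grid)
  pool_units <- if (config$grouped) length(unique(data$group_id))
                else n_samples(data)
  validate_size_grid(grid, pool_units - ceiling(pool_units / config$K))
  pools <- make_stratified_pools(
    data, config$K, seed = child_seed(config$seed, "split"),
    grouped = config$grouped)
  cfg1 <- config
  cfg1$T1 <- config$T1 * config$K * config$R
  pass <- .pool_pass(data, pools[[1L]], grid, cfg1, k = 1L, r = 1L,
                     stage = "trial")
  .engine_result("traditional", list(pass), grid, config)
}
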