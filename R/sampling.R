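# Stratified K-fold pool construction and training-subset draws.
#
# Sampling units are rows by default, or groups (patients/images) in grouped
# mode, where every row of a group follows its group into the training or
# testing pool so that no patient spans both.

#' Partition a dataset into K stratified training/testing pools
#'
#' Splits the dataset into `K` disjoint testing pools covering every row
#' exactly once; for fold `k` the testing pool is pool `k` and the training
#' pool is everything else. Per-class pool counts differ from perfect
#' stratification by at most one. In grouped mode the partition is performed
#' on group identifiers: stratification is by class when each group carries a
#' single class, and on group counts alone when groups span both classes (the
#' pixel/voxel case).
#'
#' @param data a [feature_dataset()].
#' @param K number of folds (>= 2).
#' @param seed RNG seed; the partition is deterministic given
#'   `(data, K, seed)`.
#' @param grouped partition on group ids instead of rows.
#' @return a list of `K` `pool_assignment` objects, each with elements
#'   `fold` (k), `train` and `test` (row indices), and, in grouped mode,
#'   `train_groups` / `test_groups`.
#' @export
make_stratified_pools <- function(data, K, seed = 1L, grouped = FALSE) {
  K <- as.integer(K)
  if (K < 2L) stop("K must be >= 2")
  if (grouped && is.null(data$group_id))
    stop("grouped partitioning requires group ids")

  if (grouped) {
    units <- unique(data$group_id)
    # a group's class is well-defined only when all its rows agree
    gclass <- tapply(as.integer(data$label), data$group_id, function(z)
      if (length(unique(z)) == 1L) z[1] else NA_integer_)
    gclass <- gclass[units]
    strata <- if (anyNA(gclass)) rep(1L, length(units)) else as.integer(gclass)
  } else {
    units <- seq_len(n_samples(data))
    strata <- as.integer(data$label)
  }

  fold_of <- integer(length(units))
  with_seed(seed, {
    for (s in unique(strata)) {
      members <- which(strata == s)
      m <- length(members)
      if (m < K)
        stop("stratum '", s, "' has ", m, " members, fewer than K = ", K)
      base <- m %/% K
      extra <- m %% K
      counts <- rep(base, K)
      if (extra > 0) counts[sample.int(K, extra)] <- base + 1L
      fold_of[sample(members)] <- rep(seq_len(K), counts)
    }
  })

  lapply(seq_len(K), function(k) {
    test_units <- units[fold_of == k]
    train_units <- units[fold_of != k]
    if (grouped) {
      structure(list(
        fold = k,
        train = which(data$group_id %in% train_units),
        test = which(data$group_id %in% test_units),
        train_groups = train_units, test_groups = test_units
      ), class = "pool_assignment")
    } else {
      structure(list(fold = k, train = train_units, test = test_units),
                class = "pool_assignment")
    }
  })
}

#' Draw one training subset from a pool
#'
#' Samples `n` distinct elements of `pool` without replacement. With
#' stratification (two classes present in `labels`), per-class counts differ
#' by at most one and the class receiving the excess element (odd `n`) is
#' chosen uniformly at random. Without stratification, single-class draws are
#' rejected and redrawn up to 100 times.
#'
#' @param pool vector of candidate elements (row indices, or group ids in
#'   grouped mode).
#' @param n subset size; must not exceed `length(pool)`.
#' @param seed RNG seed; `NULL` uses the current RNG state (the engines draw
#'   many subsets inside one keyed stream).
#' @param stratified draw class-stratified (requires `labels`).
#' @param labels optional two-level factor aligned with `pool`, used for
#'   stratification and single-class rejection.
#' @return a vector of `n` distinct elements of `pool`.
#' @export
draw_subset <- function(pool, n, seed = NULL, stratified = TRUE, labels = NULL) {
  n <- as.integer(n)
  if (n > length(pool))
    stop("subset size ", n, " exceeds pool size ", length(pool))
  draw <- function() {
    if (stratified && !is.null(labels) && nlevels(labels) == 2L) {
      lev <- levels(labels)
      n1 <- n %/% 2L
      n2 <- n - n1
      if (n1 != n2 && sample.int(2L, 1L) == 1L) { tmp <- n1; n1 <- n2; n2 <- tmp }
      want <- c(n1, n2)
      out <- vector(mode = mode(pool), length = 0L)
      for (ci in 1:2) {
        cand <- pool[labels == lev[ci]]
        if (length(cand) < want[ci])
          stop("class '", lev[ci], "' has ", length(cand),
               " pool members, fewer than the ", want[ci], " required")
        out <- c(out, cand[sample.int(length(cand), want[ci])])
      }
      out
    } else if (!is.null(labels) && nlevels(labels) == 2L && n >= 2L) {
      # unstratified: reject single-class draws (classifiers need both classes)
      for (attempt in 1:100) {
        out <- pool[sample.int(length(pool), n)]
        if (length(unique(labels[match(out, pool)])) == 2L) return(out)
      }
      stop("failed to draw a two-class subset of size ", n, " in 100 attempts")
    } else {
      pool[sample.int(length(pool), n)]
    }
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Export pool assignments for audit
#'
#' @param pools a list of `pool_assignment`s from [make_stratified_pools()].
#' @param data the `feature_dataset` the pools were built from.
#' @return a data.frame with columns `sample_id`, `fold`, `role`
#'   (train/test), one row per (row, fold) pair.
#' @export
pools_to_table <- function(pools, data) {
  do.call(rbind, lapply(pools, function(p) {
    data.frame(
      sample_id = data$sample_id[c(p$train, p$test)],
      fold = p$fold,
      role = rep(c("train", "test"), c(length(p$train), length(p$test))),
      stringsAsFactors = FALSE
    )
  }))
}
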