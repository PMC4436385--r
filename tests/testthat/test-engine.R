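small_cfg <- function(...) {
  rrs_config(K = 2, R = 2, T1 = 5, T2 = 3, seed = 99, ...)
}

test_that("subsampling errors average replicate error rates exactly", {
  data <- separated_clusters(n_per_class = 15)
  out <- subsampling_errors(data, pool_train = 1:20, pool_test = 21:30,
                            n = 6, T1 = 8, seed = 4)
  expect_length(out$errors, 8)
  expect_true(all(out$errors >= 0 & out$errors <= 1))
  expect_equal(out$mean, mean(out$errors))
  expect_error(subsampling_errors(data, 1:10, 11:20, n = 11, T1 = 2),
               "exceeds")
})

test_that("replicate counts and mean aggregation satisfy the bookkeeping identities", {
  data <- default_pilot(seed = 71)
  grid <- size_grid(c(10, 20))
  cfg <- small_cfg()
  res <- cross_validated_errors(data, grid, cfg)
  # conservation: T1*K*R actual and T1*T2*K*R null records per size
  for (nn in grid) {
    expect_equal(sum(res$records$n == nn), 5 * 2 * 2)
    expect_equal(sum(res$null_records$n == nn), 5 * 3 * 2 * 2)
  }
  expect_true(all(res$records$error >= 0 & res$records$error <= 1))
  # fold means re-derivable from raw records
  for (row in sample(nrow(res$fold_means), 4)) {
    fm <- res$fold_means[row, ]
    raw <- res$records$error[res$records$n == fm$n & res$records$k == fm$k &
                             res$records$r == fm$r]
    expect_equal(fm$error, mean(raw), tolerance = 1e-12)
  }
  # comprehensive mean equals the mean of the K*R fold means
  for (nn in grid) {
    expect_equal(res$means$error[res$means$n == nn],
                 mean(res$fold_means$error[res$fold_means$n == nn]),
                 tolerance = 1e-12)
  }
  # traditional arm: same totals, one fixed pool
  tr <- traditional_rrs_errors(data, grid, cfg)
  for (nn in grid) expect_equal(sum(tr$records$n == nn), 5 * 2 * 2)
})

test_that("identical configuration reproduces the engine result bit-for-bit", {
  data <- default_pilot(seed = 81)
  grid <- size_grid(c(10, 20))
  cfg <- small_cfg()
  a <- cross_validated_errors(data, grid, cfg)
  b <- cross_validated_errors(data, grid, cfg)
  expect_identical(a$records, b$records)
  expect_identical(a$null_records, b$null_records)
  t1 <- traditional_rrs_errors(data, grid, cfg)
  t2 <- traditional_rrs_errors(data, grid, cfg)
  expect_identical(t1$records, t2$records)
  # a different seed changes the draws
  c <- cross_validated_errors(data, grid, rrs_config(K = 2, R = 2, T1 = 5,
                                                     T2 = 3, seed = 100))
  expect_false(identical(a$records$error, c$records$error))
})

test_that("any stored replicate can be recomputed in isolation from its keyed stream", {
  data <- default_pilot(seed = 91)
  grid <- size_grid(c(15, 25))
  cfg <- rrs_config(K = 3, R = 2, T1 = 4, T2 = 2, seed = 55,
                    run_permutation = FALSE)
  res <- cross_validated_errors(data, grid, cfg)
  picks <- res$records[sample(nrow(res$records), 6), ]
  for (row in seq_len(nrow(picks))) {
    rec <- picks[row, ]
    pools <- make_stratified_pools(data, cfg$K,
                                   seed = child_seed(cfg$seed, "pools", rec$r))
    p <- pools[[rec$k]]
    # replay draws i' = 1..i inside the keyed stream, then evaluate the
    # subset through the generic train/predict path
    err <- with_seed(child_seed(cfg$seed, "subset", rec$k, rec$r, rec$n, rec$i), {
      sub <- sort(draw_subset(seq_along(p$train), rec$n, seed = NULL,
                              stratified = TRUE,
                              labels = data$label[p$train]))
      m <- train_classifier(cfg$classifier,
                            data$features[p$train[sub], , drop = FALSE],
                            data$label[p$train[sub]])
      error_rate(m, data$features[p$test, , drop = FALSE],
                 data$label[p$test])
    })
    expect_equal(rec$error, err)
  }
})

test_that("the compiled kNN path and the generic path give identical engine results", {
  # grouped mode with singleton groups routes the identical draws through the
  # generic evaluator while the plain run uses the compiled kernel
  data <- default_pilot(seed = 95)
  grid <- size_grid(c(8, 16))
  fast <- cross_validated_errors(data, grid, small_cfg())
  slow_data <- data
  slow_data$group_id <- data$sample_id   # one group per row
  slow <- cross_validated_errors(slow_data, grid, small_cfg(grouped = TRUE))
  expect_equal(fast$records$error, slow$records$error)
  expect_equal(fast$null_records$error, slow$null_records$error)
})

test_that("grouped subsampling keeps patients intact and group-exclusive", {
  # 4 patients x 10 pixels, K=2, n=1: each training subset is one patient
  data <- grouped_two_class(n_groups = 4, rows_per_class = 5, seed = 33)
  cfg <- rrs_config(K = 2, R = 2, T1 = 6, T2 = 2, seed = 12, grouped = TRUE)
  res <- cross_validated_errors(data, size_grid(1), cfg)
  expect_equal(nrow(res$records), 6 * 2 * 2)
  # replay each replicate's draw and check group exclusivity
  for (r in 1:2) {
    pools <- make_stratified_pools(data, 2,
                                   seed = child_seed(cfg$seed, "pools", r),
                                   grouped = TRUE)
    for (k in 1:2) {
      p <- pools[[k]]
      expect_length(intersect(data$group_id[p$train],
                              data$group_id[p$test]), 0)
      expect_length(p$train_groups, 2L)
    }
  }
  # error granularity: testing pool is 2 patients x 10 pixels = 20 rows
  expect_true(all(abs(res$records$error * 20 -
                      round(res$records$error * 20)) < 1e-9))
})

test_that("permutation can be switched off and grids are validated against pools", {
  data <- default_pilot(seed = 97)
  res <- cross_validated_errors(data, size_grid(10),
                                small_cfg(run_permutation = FALSE))
  expect_null(res$null_records)
  expect_error(cross_validated_errors(data, size_grid(60), small_cfg()),
               "exceed")
  expect_error(traditional_rrs_errors(data, size_grid(80), small_cfg()),
               "exceed")
})
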