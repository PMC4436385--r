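test_that("IQR summaries follow the quantile convention and average correctly", {
  res <- structure(list(
    engine = "traditional",
    records = data.frame(n = rep(c(10L, 20L), each = 4), k = 1L, r = 1L,
                         i = rep(1:4, 2),
                         error = c(0.1, 0.2, 0.3, 0.4, 0.2, 0.2, 0.2, 0.2)),
    repeat_means = NULL, grid = c(10L, 20L)), class = "engine_result")
  s <- iqr_summary(res)
  expect_equal(s$per_size$iqr, c(0.15, 0))       # type-7 on {.1,.2,.3,.4}
  expect_equal(s$mean_iqr, 0.075)
  s10 <- iqr_summary(res, sizes = 10)
  expect_equal(s10$mean_iqr, 0.15)
})

test_that("LOO error handles the textbook cases", {
  # perfectly separated clusters: 1-NN is perfect
  data <- separated_clusters()
  expect_equal(loo_error(data, classifier_spec("knn", k = 1)), 0)

  # alternating labels on a line: every nearest neighbour is the other class
  line <- feature_dataset(matrix(c(1, 2, 3, 4), ncol = 1),
                          label = c("a", "b", "a", "b"))
  expect_equal(loo_error(line, classifier_spec("knn", k = 1)), 1)

  # identical features for both classes: chance-level error
  same <- feature_dataset(matrix(rep(c(1, 2), each = 20), ncol = 2),
                          label = rep(c("a", "b"), 10))
  e <- loo_error(same, classifier_spec("knn", k = 3))
  expect_gte(e, 0.3)
  expect_lte(e, 0.7)

  expect_error(loo_error(subset_rows(data, 1), classifier_spec("knn")),
               "at least 2")
})

test_that("grouped LOO holds out whole patients", {
  data <- grouped_two_class(n_groups = 5, rows_per_class = 4, seed = 19)
  e <- loo_error(data, classifier_spec("knn", k = 3), grouped = TRUE)
  expect_gte(e, 0)
  expect_lte(e, 1)
  expect_error(loo_error(separated_clusters(), classifier_spec("knn"),
                         grouped = TRUE), "group ids")
})

test_that("crossover detection and classifier ranking read the fitted curves", {
  f1 <- structure(list(a = 1.0, alpha = 0.6, b = 0.10), class = "power_law_fit")
  f2 <- structure(list(a = 0.5, alpha = 0.6, b = 0.13), class = "power_law_fit")
  # f1 starts higher but has the lower asymptote: curves cross once
  x <- detect_crossover(f1, f2, 2, 5000)
  expect_false(is.na(x))
  expect_gt(predict_error(f1, x - 1), predict_error(f2, x - 1))
  expect_lt(predict_error(f1, x), predict_error(f2, x))
  # parallel curves never cross
  f3 <- structure(list(a = 1.0, alpha = 0.6, b = 0.20), class = "power_law_fit")
  expect_true(is.na(detect_crossover(f1, f3, 2, 5000)))
  # constant curves rank by intercept alone
  c1 <- structure(list(a = 0, alpha = 1, b = 0.2), class = "power_law_fit")
  c2 <- structure(list(a = 0, alpha = 1, b = 0.1), class = "power_law_fit")
  rk <- rank_classifiers(list(one = c1, two = c2), sizes = c(10, 100))
  expect_equal(rk$rank[rk$classifier == "two"], c(1L, 1L))
})

test_that("curve bundles assemble summaries, fits and the valid set", {
  data <- separated_clusters(n_per_class = 25)
  cfg <- rrs_config(K = 2, R = 4, T1 = 8, T2 = 6, seed = 23)
  res <- cross_validated_errors(data, size_grid(c(6, 10, 14, 18)), cfg)
  b <- curve_bundle(res)
  expect_named(b$summary, c("n", "mean_error", "p25", "p75", "iqr",
                            "p_value", "valid"))
  expect_true(all(b$summary$iqr >= 0))
  expect_true(all(b$summary$p25 <= b$summary$p75))
  if (length(b$valid_sizes) >= 3) {
    expect_s3_class(b$fit_mean, "power_law_fit")
    expect_s3_class(b$fit_p25, "power_law_fit")
    expect_s3_class(b$fit_p75, "power_law_fit")
  }
  path <- withr::local_tempfile(fileext = ".csv")
  write_curve_summary(b, path)
  back <- read.csv(path)
  expect_equal(names(back), names(b$summary))
  expect_equal(back$mean_error, b$summary$mean_error)
})

test_that("fit records serialize to JSON with full precision", {
  fit <- fit_power_law(seq(25, 55, 5),
                       powerlaw_error_oracle(1, 0.5, 0.05,
                                             size_grid(seq(25, 55, 5)))$errors)
  path <- withr::local_tempfile(fileext = ".json")
  write_fit_json(fit, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$a, fit$a, tolerance = 1e-12)
  expect_equal(back$alpha, fit$alpha, tolerance = 1e-12)
  expect_equal(back$b, fit$b, tolerance = 1e-12)
  expect_equal(back$sizes, seq(25L, 55L, 5L))
})

test_that("engine records export to long-format CSV", {
  data <- separated_clusters(n_per_class = 10)
  cfg <- rrs_config(K = 2, R = 1, T1 = 3, T2 = 2, seed = 29)
  res <- cross_validated_errors(data, size_grid(c(4, 8)), cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_engine_records(res, path)
  back <- read.csv(path)
  expect_equal(names(back), c("n", "k", "r", "i", "j", "kind", "error"))
  expect_equal(sum(back$kind == "actual"), 2 * 3 * 2)
  expect_equal(sum(back$kind == "null"), 2 * 3 * 2 * 2)
})

test_that("compare_methods pairs the arms with matched effort", {
  data <- default_pilot(seed = 141)
  cfg <- rrs_config(K = 2, R = 2, T1 = 6, T2 = 4, seed = 31)
  validation <- gaussian_two_class(gaussian_spec(n_per_class = 60, seed = 142))
  rep <- compare_methods(data, size_grid(c(10, 20, 30)), cfg,
                         validation = validation)
  expect_s3_class(rep$cv, "curve_bundle")
  expect_s3_class(rep$traditional, "curve_bundle")
  expect_true(is.finite(rep$mean_iqr_cv) && is.finite(rep$mean_iqr_trad))
  expect_equal(rep$cv$summary$n, c(10L, 20L, 30L))
  expect_equal(rep$traditional$summary$n, c(10L, 20L, 30L))
  expect_equal(rep$loo_n, 119L)
  expect_gte(rep$loo, 0)
  expect_lte(rep$loo, 1)
  expect_output(print(rep), "mean IQR")
})
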