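# Stability summaries, curve bundles, leave-one-out validation, and the
# head-to-head comparison of the cross-validated engine against traditional
# RRS.

#' Interquartile-range stability summary
#'
#' Per-size IQR = P75 - P25 of the engine's error distribution (type-7
#' quantiles) and the mean IQR across the summarised sizes — the framework's
#' stability metric. The cross-validated engine is summarised over its `R`
#' per-repeat comprehensive means, the traditional engine over its raw
#' replicate errors; override with `units`.
#'
#' @param result an `engine_result`.
#' @param sizes sizes to summarise (default: all in the grid; pass the valid
#'   set `M` to drop sizes that failed the permutation screen).
#' @param units `"repeat_mean"` or `"replicate"` (default by engine).
#' @return a list with `per_size` (columns `n`, `p25`, `p75`, `iqr`) and
#'   `mean_iqr`.
#' @export
iqr_summary <- function(result, sizes = NULL, units = NULL) {
  tab <- error_quantiles(result, c(0.25, 0.75), units)
  names(tab) <- c("n", "p25", "p75")
  if (!is.null(sizes)) tab <- tab[tab$n %in% as.integer(sizes), ]
  tab$iqr <- tab$p75 - tab$p25
  list(per_size = tab, mean_iqr = mean(tab$iqr))
}

#' Leave-one-out error rate
#'
#' For each sample (or each group, when the dataset has group ids and
#' `grouped = TRUE`), trains on all remaining samples and predicts the
#' held-out one(s); returns the fraction misclassified. This is the
#' validation-cohort lower-bound error the extrapolated curves are compared
#' against.
#'
#' @param data a [feature_dataset()] with >= 2 samples and both classes.
#' @param spec a [classifier_spec()].
#' @param grouped leave one group out instead of one sample (requires group
#'   ids).
#' @return the LOO error rate in \[0, 1\].
#' @export
loo_error <- function(data, spec = classifier_spec("knn"), grouped = FALSE) {
  m <- n_samples(data)
  if (m < 2L) stop("leave-one-out needs at least 2 samples")
  if (nlevels(droplevels(data$label)) < 2L)
    stop("leave-one-out needs both classes present")
  holdouts <- if (grouped) {
    if (is.null(data$group_id)) stop("grouped LOO requires group ids")
    lapply(unique(data$group_id), function(g) which(data$group_id == g))
  } else as.list(seq_len(m))
  wrong <- 0L
  for (ho in holdouts) {
    model <- train_classifier(spec, data$features[-ho, , drop = FALSE],
                              data$label[-ho])
    pred <- predict(model, data$features[ho, , drop = FALSE])
    wrong <- wrong + sum(as.character(pred) != as.character(data$label[ho]))
  }
  wrong / m
}

#' Learning-curve bundle from an engine result
#'
#' Assembles the reporting unit for one engine run: the per-size summary
#' (mean error, P25/P75, IQR, permutation p-value, validity), the power-law
#' fits of the mean and percentile curves restricted to the valid size set
#' `M`, and the mean IQR over the valid sizes.
#'
#' @param result an `engine_result`.
#' @param alpha significance level for the permutation screen (default from
#'   the run configuration). When the engine was run without permutation,
#'   every size is treated as valid and p-values are `NA`.
#' @return an object of class `curve_bundle` with elements `summary` (data
#'   frame with columns `n`, `mean_error`, `p25`, `p75`, `iqr`, `p_value`,
#'   `valid`), `fit_mean`, `fit_p25`, `fit_p75` (`power_law_fit` or `NULL`
#'   when `|M| < 3`), `valid_sizes`, `mean_iqr`.
#' @export
curve_bundle <- function(result, alpha = NULL) {
  grid <- as.integer(result$grid)
  if (!is.null(result$null_records)) {
    sig <- significance_table(result, alpha)
    M <- filter_valid_sizes(grid, sig)
  } else {
    sig <- data.frame(n = grid, p_value = NA_real_, valid = TRUE,
                      n_null = 0L)
    M <- grid
  }
  iqr <- iqr_summary(result)$per_size
  s <- merge(result$means, iqr, by = "n")
  s <- merge(s, sig[, c("n", "p_value", "valid")], by = "n")
  names(s)[names(s) == "error"] <- "mean_error"
  s <- s[order(s$n), c("n", "mean_error", "p25", "p75", "iqr", "p_value",
                       "valid")]
  fits <- list(fit_mean = NULL, fit_p25 = NULL, fit_p75 = NULL)
  if (length(M) >= 3L) {
    sv <- s[s$n %in% M, ]
    fits$fit_mean <- fit_power_law(sv$n, sv$mean_error)
    fits$fit_p25 <- fit_power_law(sv$n, sv$p25)
    fits$fit_p75 <- fit_power_law(sv$n, sv$p75)
  }
  structure(
    c(list(summary = s, valid_sizes = M,
           mean_iqr = mean(s$iqr[s$n %in% M]), engine = result$engine),
      fits),
    class = "curve_bundle"
  )
}

#' @export
print.curve_bundle <- function(x, ...) {
  cat("<curve_bundle> ", if (x$engine == "cv") "cross-validated RRS"
      else "traditional RRS", "\n", sep = "")
  print(x$summary, row.names = FALSE, digits = 4)
  cat("  valid sizes M: ", if (length(x$valid_sizes))
    paste(x$valid_sizes, collapse = ", ") else "(none)", "\n", sep = "")
  cat("  mean IQR over M: ", format(x$mean_iqr, digits = 4), "\n", sep = "")
  if (!is.null(x$fit_mean)) {
    cat("  mean curve:  "); print(x$fit_mean)
    cat("  Bayes error estimate b = ", format(x$fit_mean$b, digits = 4),
        "\n", sep = "")
  }
  invisible(x)
}

#' Smallest size at which two fitted curves swap ranking
#'
#' Evaluates both power-law fits on an integer grid and reports the first
#' size where the ordering of predicted errors flips relative to `from`.
#'
#' @param fit1,fit2 `power_law_fit`s.
#' @param from,to integer range to scan.
#' @return the crossover size, or `NA` if the ranking never flips.
#' @export
detect_crossover <- function(fit1, fit2, from, to) {
  ns <- seq(as.integer(from), as.integer(to))
  d <- predict_error(fit1, ns) - predict_error(fit2, ns)
  s0 <- sign(d[1])
  flip <- which(sign(d) != s0 & sign(d) != 0)
  if (length(flip)) ns[flip[1]] else NA_integer_
}

#' Rank classifiers by predicted error at target sizes
#'
#' @param fits named list of `power_law_fit`s (one per classifier).
#' @param sizes target training-set sizes.
#' @return a data.frame (n, classifier, predicted_error, rank), ranked within
#'   each size.
#' @export
rank_classifiers <- function(fits, sizes) {
  stopifnot(length(names(fits)) == length(fits))
  do.call(rbind, lapply(as.integer(sizes), function(nn) {
    pe <- vapply(fits, predict_error, numeric(1), n = nn)
    data.frame(n = nn, classifier = names(fits), predicted_error = pe,
               rank = rank(pe, ties.method = "min"), row.names = NULL)
  }))
}

#' Compare cross-validated RRS against traditional RRS
#'
#' Runs both engines with matched total replicates (`T1*K*R` per size each),
#' assembles their curve bundles, pairs their per-size IQRs, and — when a
#' validation cohort is supplied — computes its leave-one-out error for
#' comparison against the extrapolated band at the corresponding training
#' size.
#'
#' @param data the pilot [feature_dataset()].
#' @param grid a [size_grid()].
#' @param config an [rrs_config()].
#' @param validation optional larger `feature_dataset` for LOO validation.
#' @param target_sizes sizes at which predicted errors are reported (default:
#'   the largest grid size and the validation LOO training size).
#' @param horizon upper bound of the crossover scan between the two mean
#'   curves (default ten times the largest grid size).
#' @return an object of class `comparison_report`: `cv` and `traditional`
#'   curve bundles, `iqr_pairs` (n, iqr_cv, iqr_trad), `mean_iqr_cv`,
#'   `mean_iqr_trad`, `loo` (or `NULL`), `predicted` (per target size), and
#'   `crossover`.
#' @export
compare_methods <- function(data, grid, config = rrs_config(),
                            validation = NULL, target_sizes = NULL,
                            horizon = NULL) {
  grid <- if (inherits(grid, "size_grid")) grid else size_grid(grid)
  cv <- cross_validated_errors(data, grid, config)
  tr <- traditional_rrs_errors(data, grid, config)
  bcv <- curve_bundle(cv)
  btr <- curve_bundle(tr)
  common <- intersect(bcv$valid_sizes, btr$valid_sizes)
  pairs <- data.frame(
    n = common,
    iqr_cv = bcv$summary$iqr[match(common, bcv$summary$n)],
    iqr_trad = btr$summary$iqr[match(common, btr$summary$n)])
  loo <- NULL
  loo_n <- NULL
  if (!is.null(validation)) {
    loo <- loo_error(validation, config$classifier, grouped = config$grouped)
    loo_n <- if (config$grouped)
      length(unique(validation$group_id)) - 1L else n_samples(validation) - 1L
  }
  if (is.null(target_sizes))
    target_sizes <- unique(c(max(grid), loo_n))
  predicted <- if (!is.null(bcv$fit_mean)) {
    data.frame(n = target_sizes,
               predicted_error = predict_error(bcv$fit_mean, target_sizes))
  } else NULL
  crossover <- if (!is.null(bcv$fit_mean) && !is.null(btr$fit_mean)) {
    if (is.null(horizon)) horizon <- 10L * max(grid)
    detect_crossover(bcv$fit_mean, btr$fit_mean, min(grid), horizon)
  } else NA_integer_
  structure(
    list(cv = bcv, traditional = btr, iqr_pairs = pairs,
         # arm-level stability is compared over the full grid so the summary
         # stays defined even when one arm fails the significance screen
         # everywhere (a real outcome for an unlucky fixed split); the
         # bundles carry the filtered per-arm summaries
         mean_iqr_cv = iqr_summary(cv)$mean_iqr,
         mean_iqr_trad = iqr_summary(tr)$mean_iqr,
         loo = loo, loo_n = loo_n, predicted = predicted,
         crossover = crossover, config = config),
    class = "comparison_report"
  )
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report> ", format(x$config$classifier), "\n", sep = "")
  cat(sprintf("  mean IQR: with CV %.4f | traditional %.4f (ratio %.3f)\n",
              x$mean_iqr_cv, x$mean_iqr_trad,
              x$mean_iqr_cv / x$mean_iqr_trad))
  if (!is.null(x$loo))
    cat(sprintf("  validation LOO error: %.4f (at n = %d)\n", x$loo, x$loo_n))
  if (!is.null(x$predicted)) {
    cat("  predicted error (CV mean curve):\n")
    print(x$predicted, row.names = FALSE, digits = 4)
  }
  if (!is.na(x$crossover))
    cat("  mean curves cross at n = ", x$crossover, "\n", sep = "")
  else cat("  no crossover between mean curves in the scanned range\n")
  invisible(x)
}

#' Plot learning curves
#'
#' Mean error rates with the fitted mean and percentile power-law curves,
#' and optionally the validation LOO error as a star marker.
#'
#' @param x a `curve_bundle`.
#' @param loo optional LOO error rate to mark.
#' @param loo_n size at which to place the LOO marker.
#' @param horizon largest size to draw (default `max(n)`, or `loo_n`).
#' @param main plot title.
#' @param ... passed to [plot()].
#' @return invisibly, `x`.
#' @export
plot.curve_bundle <- function(x, loo = NULL, loo_n = NULL, horizon = NULL,
                              main = NULL, ...) {
  s <- x$summary
  if (is.null(horizon)) horizon <- max(c(s$n, loo_n))
  ns <- seq(min(s$n), horizon)
  ylim <- range(c(s$mean_error, s$p25, s$p75, loo), na.rm = TRUE)
  plot(s$n, s$mean_error, pch = 15, xlim = c(min(s$n), horizon),
       ylim = ylim + c(-0.02, 0.02), xlab = "training set size n",
       ylab = "error rate",
       main = if (is.null(main)) "Learning curve" else main, ...)
  if (!is.null(x$fit_mean)) lines(ns, predict_error(x$fit_mean, ns),
                                  col = "blue", lwd = 2)
  if (!is.null(x$fit_p25)) lines(ns, predict_error(x$fit_p25, ns),
                                 col = "darkgreen", lty = 2)
  if (!is.null(x$fit_p75)) lines(ns, predict_error(x$fit_p75, ns),
                                 col = "red", lty = 2)
  if (!is.null(loo)) points(loo_n, loo, pch = 8, col = "goldenrod", cex = 1.5)
  invisible(x)
}

#' Write the per-size summary of a curve bundle to CSV
#'
#' Fixed column order (`n`, `mean_error`, `p25`, `p75`, `iqr`, `p_value`,
#' `valid`) for diffability.
#'
#' @param bundle a `curve_bundle`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_curve_summary <- function(bundle, path) {
  write.csv(bundle$summary[, c("n", "mean_error", "p25", "p75", "iqr",
                               "p_value", "valid")],
            path, row.names = FALSE)
  invisible(path)
}

#' Write a power-law fit record to JSON
#'
#' @param fit a `power_law_fit`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  jsonlite::write_json(
    list(a = fit$a, alpha = fit$alpha, b = fit$b, sse = fit$sse,
         sizes = as.integer(fit$sizes)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Export raw engine records to long-format CSV
#'
#' Actual replicates carry `kind = "actual"` and `j = NA`; null replicates
#' carry `kind = "null"` and their permutation index.
#'
#' @param result an `engine_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_engine_records <- function(result, path) {
  act <- result$records
  act$j <- NA_integer_
  act$kind <- "actual"
  out <- act[, c("n", "k", "r", "i", "j", "kind", "error")]
  if (!is.null(result$null_records)) {
    nul <- result$null_records
    nul$kind <- "null"
    out <- rbind(out, nul[, c("n", "k", "r", "i", "j", "kind", "error")])
  }
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
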