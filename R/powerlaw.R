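# Inverse power-law learning-curve model: ebar(n) = a * n^(-alpha) + b with
# a, alpha, b >= 0. `a` is the learning rate, `alpha` the decay rate, and the
# intercept `b` estimates the Bayes error — the lowest achievable error with
# unlimited training data.

# Constrained least squares over (a, b) for a fixed alpha. The unconstrained
# solution is closed-form linear least squares on the basis [n^-alpha, 1];
# when it violates a >= 0 or b >= 0 the optimum lies on a boundary, each of
# which is itself closed-form.
.inner_fit <- function(alpha, n, e) {
  w <- n^(-alpha)
  sw <- sum(w); sww <- sum(w * w); se <- sum(e); swe <- sum(w * e)
  m <- length(n)
  det <- m * sww - sw * sw
  cand <- list()
  if (det > .Machine$double.eps * m * sww) {
    a <- (m * swe - sw * se) / det
    b <- (se * sww - sw * swe) / det
    if (a >= 0 && b >= 0) cand[[length(cand) + 1L]] <- c(a, b)
  }
  b0 <- max(0, se / m)                       # a = 0
  cand[[length(cand) + 1L]] <- c(0, b0)
  a0 <- if (sww > 0) max(0, swe / sww) else 0  # b = 0
  cand[[length(cand) + 1L]] <- c(a0, 0)
  sse <- vapply(cand, function(p) sum((p[1] * w + p[2] - e)^2), numeric(1))
  best <- which.min(sse)
  c(cand[[best]], sse[best])
}

#' Fit the power-law learning curve
#'
#' Solves the constrained non-linear least-squares problem
#' \deqn{\min_{a,\alpha,b \ge 0} \sum_m (a n_m^{-\alpha} + b - \bar e(n_m))^2}
#' by multi-start optimization: a log-spaced grid of 60 decay rates in
#' \[0.01, 3\], each with a closed-form non-negative inner solve for
#' \eqn{(a, b)}, followed by a bounded one-dimensional refinement of the
#' decay rate between the neighbouring grid points (tolerance 1e-10). Ties
#' in SSE resolve to the smallest decay rate.
#'
#' @param sizes training-set sizes (the valid set `M`; at least 3, distinct).
#' @param errors mean error rates at `sizes`, each in \[0, 1\].
#' @return an object of class `power_law_fit` with elements `a`, `alpha`,
#'   `b`, `sse`, `sizes`, `errors`.
#' @export
fit_power_law <- function(sizes, errors) {
  sizes <- as.numeric(sizes)
  errors <- as.numeric(errors)
  if (length(sizes) != length(errors))
    stop("sizes and errors differ in length")
  if (length(sizes) < 3L)
    stop("insufficient valid sizes: power-law fit needs >= 3, got ",
         length(sizes))
  if (length(unique(sizes)) < 2L) stop("all sizes are equal; cannot fit")
  if (any(sizes <= 0)) stop("sizes must be positive")
  if (any(errors < 0 | errors > 1)) stop("errors must lie in [0, 1]")

  # multi-start: the profiled objective is one-dimensional in alpha (the
  # inner (a, b) solve is closed-form), so each grid start is refined by a
  # bounded minimization between its neighbouring grid points; the profile
  # can be multimodal, hence every start is refined, not just the best
  alphas <- exp(seq(log(0.01), log(3), length.out = 60))
  g <- function(al) .inner_fit(al, sizes, errors)[3]
  best <- NULL
  for (idx in seq_along(alphas)) {
    lo <- if (idx > 1L) alphas[idx - 1L] else 0.005
    hi <- if (idx < length(alphas)) alphas[idx + 1L] else 6
    opt <- stats::optimize(g, interval = c(lo, hi), tol = 1e-10)
    al <- if (opt$objective < g(alphas[idx])) opt$minimum else alphas[idx]
    f <- .inner_fit(al, sizes, errors)
    if (is.null(best) || f[3] < best$sse - 1e-15)
      best <- list(a = f[1], alpha = al, b = f[2], sse = f[3])
  }
  structure(list(a = best$a, alpha = best$alpha, b = best$b, sse = best$sse,
                 sizes = sizes, errors = errors),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf(
    "<power_law_fit> e(n) = %.4g * n^-%.4g + %.4g   (SSE %.3g, %d sizes)\n",
    x$a, x$alpha, x$b, x$sse, length(x$sizes)))
  invisible(x)
}

#' Predict error at a training-set size
#'
#' Evaluates \eqn{a n^{-\alpha} + b}. At `n = Inf` this is the fitted Bayes
#' error `b` (or `a + b` in the degenerate zero-decay case).
#'
#' @param fit a `power_law_fit`.
#' @param n positive training-set size(s); `Inf` allowed.
#' @return predicted error rate(s).
#' @export
predict_error <- function(fit, n) {
  if (any(n <= 0)) stop("n must be positive")
  ifelse(is.infinite(n),
         if (fit$alpha > 0) fit$b else fit$a + fit$b,
         fit$a * n^(-fit$alpha) + fit$b)
}

#' @export
predict.power_law_fit <- function(object, n, ...) predict_error(object, n)

#' Percentile learning curves
#'
#' Computes per-size lower and upper percentiles (default 25th and 75th) of
#' the engine's error distribution and fits a power law to each series, using
#' the same valid size set as the mean curve. Quantiles use linear
#' interpolation between closest ranks (type 7).
#'
#' The distribution summarised depends on the engine: the cross-validated
#' engine's percentiles are taken over the `R` per-repeat comprehensive means
#' (each repeat tests every sample exactly once), the traditional engine's
#' over its raw replicate errors; override with `units`.
#'
#' @param result an `engine_result`.
#' @param quantiles two probabilities, default `c(0.25, 0.75)`.
#' @param sizes sizes to use (default: the full grid; pass the valid set `M`
#'   to mirror the significance screen).
#' @param units `"repeat_mean"` or `"replicate"`; default by engine.
#' @return a list with `power_law_fit`s `lower` and `upper` and the per-size
#'   table `percentiles` (columns `n`, `p_lower`, `p_upper`).
#' @export
percentile_curves <- function(result, quantiles = c(0.25, 0.75), sizes = NULL,
                              units = NULL) {
  stopifnot(length(quantiles) == 2L, quantiles[1] <= quantiles[2])
  tab <- error_quantiles(result, quantiles, units)
  if (!is.null(sizes)) tab <- tab[tab$n %in% as.integer(sizes), ]
  list(lower = fit_power_law(tab$n, pmin(pmax(tab$p_lower, 0), 1)),
       upper = fit_power_law(tab$n, pmin(pmax(tab$p_upper, 0), 1)),
       percentiles = tab)
}

# Per-size quantiles of an engine result's error distribution.
error_quantiles <- function(result, quantiles = c(0.25, 0.75), units = NULL) {
  if (is.null(units))
    units <- if (result$engine == "cv") "repeat_mean" else "replicate"
  units <- match.arg(units, c("repeat_mean", "replicate"))
  src <- if (units == "repeat_mean") result$repeat_means else result$records
  out <- do.call(rbind, lapply(sort(unique(src$n)), function(nn) {
    q <- quantile(src$error[src$n == nn], probs = quantiles, type = 7,
                  names = FALSE)
    data.frame(n = nn, p_lower = q[1], p_upper = q[2])
  }))
  attr(out, "units") <- units
  out
}
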