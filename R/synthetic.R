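# Synthetic two-class Gaussian data and fixture generators.
#
# The default specification — unit-covariance classes with mean separation 2,
# 50 samples per class for the pilot set — is a reconstruction of the kind of
# overlapping two-dimensional Gaussian pair used to validate the framework;
# its analytic Bayes error is pnorm(-1) ~= 0.1587.

#' Specify a two-class 2-D Gaussian generator
#'
#' @param mean1,mean2 class mean vectors (length 2).
#' @param cov1,cov2 2x2 symmetric positive-definite class covariances.
#' @param n_per_class samples per class (default 50, the 100-sample pilot).
#' @param seed RNG seed.
#' @return an object of class `gaussian_spec`.
#' @export
gaussian_spec <- function(mean1 = c(0, 0), mean2 = c(2, 0),
                          cov1 = diag(2), cov2 = diag(2),
                          n_per_class = 50L, seed = 1L) {
  for (S in list(cov1, cov2)) {
    if (!isTRUE(all.equal(S, t(S))) || any(eigen(S, TRUE)$values <= 0))
      stop("covariance matrices must be symmetric positive-definite")
  }
  if (n_per_class < 1L) stop("n_per_class must be >= 1")
  structure(list(mean1 = as.numeric(mean1), mean2 = as.numeric(mean2),
                 cov1 = cov1, cov2 = cov2,
                 n_per_class = as.integer(n_per_class),
                 seed = as.integer(seed)),
            class = "gaussian_spec")
}

#' Generate a two-class Gaussian dataset
#'
#' Draws `n_per_class` samples per class from the specified bivariate
#' Gaussians; deterministic given the spec's seed. The default spec yields
#' the 100-sample pilot set; use `n_per_class = 250` for the 500-sample
#' validation set.
#'
#' @param spec a [gaussian_spec()].
#' @return a [feature_dataset()] with labels `"class1"`, `"class2"`.
#' @export
gaussian_two_class <- function(spec = gaussian_spec()) {
  m <- spec$n_per_class
  x <- with_seed(spec$seed, rbind(
    MASS::mvrnorm(m, spec$mean1, spec$cov1),
    MASS::mvrnorm(m, spec$mean2, spec$cov2)))
  colnames(x) <- c("f1", "f2")
  feature_dataset(x, label = rep(c("class1", "class2"), each = m))
}

# Bivariate normal density, closed form.
.dmvnorm2 <- function(x1, x2, mu, S) {
  det_s <- S[1, 1] * S[2, 2] - S[1, 2] * S[2, 1]
  inv <- matrix(c(S[2, 2], -S[1, 2], -S[2, 1], S[1, 1]), 2) / det_s
  d1 <- x1 - mu[1]; d2 <- x2 - mu[2]
  q <- inv[1, 1] * d1^2 + 2 * inv[1, 2] * d1 * d2 + inv[2, 2] * d2^2
  exp(-q / 2) / (2 * pi * sqrt(det_s))
}

#' Analytic Bayes error of a two-class Gaussian specification
#'
#' Assumes equal class priors. With equal class covariances the Bayes error
#' has the closed form \eqn{\Phi(-\Delta/2)} where \eqn{\Delta} is the
#' Mahalanobis distance between the class means (for spherical covariance
#' \eqn{\sigma^2 I}, \eqn{\Delta = \lVert\mu_1 - \mu_2\rVert / \sigma}).
#' Unequal covariances fall back to numerical integration of
#' \eqn{\tfrac12 \int \min(f_1, f_2)} on a grid.
#'
#' @param spec a [gaussian_spec()].
#' @param grid_points grid resolution per axis for the numerical fallback.
#' @return the Bayes error rate in \[0, 0.5\].
#' @export
analytic_bayes_error <- function(spec = gaussian_spec(), grid_points = 601L) {
  if (isTRUE(all.equal(spec$cov1, spec$cov2))) {
    d <- spec$mean1 - spec$mean2
    if (all(d == 0)) return(0.5)
    delta <- sqrt(drop(t(d) %*% solve(spec$cov1, d)))
    return(pnorm(-delta / 2))
  }
  # quadratic discriminant case: integrate min(f1, f2)/2 over a wide grid
  sds <- sqrt(c(diag(spec$cov1), diag(spec$cov2)))
  lo <- pmin(spec$mean1, spec$mean2) - 8 * max(sds)
  hi <- pmax(spec$mean1, spec$mean2) + 8 * max(sds)
  g1 <- seq(lo[1], hi[1], length.out = grid_points)
  g2 <- seq(lo[2], hi[2], length.out = grid_points)
  xx <- outer(g1, rep(1, grid_points))
  yy <- outer(rep(1, grid_points), g2)
  f1 <- .dmvnorm2(xx, yy, spec$mean1, spec$cov1)
  f2 <- .dmvnorm2(xx, yy, spec$mean2, spec$cov2)
  h1 <- g1[2] - g1[1]; h2 <- g2[2] - g2[1]
  0.5 * sum(pmin(f1, f2)) * h1 * h2
}

#' Noisy power-law error series (fixture generator)
#'
#' Evaluates \eqn{e(n) = a n^{-\alpha} + b}, adds Gaussian noise, and clips
#' to \[0, 1\]; used to exercise the curve-fitting stage with known ground
#' truth.
#'
#' @param a,alpha,b power-law parameters, all >= 0.
#' @param grid a [size_grid()] (or integer vector of sizes).
#' @param noise_sd standard deviation of additive Gaussian noise (>= 0).
#' @param seed RNG seed.
#' @return a list with `sizes` and `errors`.
#' @export
powerlaw_error_oracle <- function(a, alpha, b, grid, noise_sd = 0, seed = 1L) {
  if (any(c(a, alpha, b) < 0)) stop("a, alpha, b must be non-negative")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  sizes <- as.numeric(grid)
  e <- a * sizes^(-alpha) + b
  if (noise_sd > 0)
    e <- with_seed(seed, e + rnorm(length(e), 0, noise_sd))
  list(sizes = sizes, errors = pmin(pmax(e, 0), 1))
}

#' Synthetic grouped (pixel-level) dataset
#'
#' Builds a patient-level dataset in which every patient contributes rows of
#' both classes, emulating pixel- or metavoxel-level cohorts: patient-specific
#' random offsets are added on top of the class Gaussians, inducing the
#' intra-patient correlation that grouped sampling exists to respect.
#'
#' @param n_groups number of patients.
#' @param rows_per_class rows of each class per patient.
#' @param spec a [gaussian_spec()] for the class distributions.
#' @param group_sd standard deviation of the per-patient offset.
#' @param seed RNG seed.
#' @return a [feature_dataset()] with `group_id` set.
#' @export
grouped_two_class <- function(n_groups = 16L, rows_per_class = 10L,
                              spec = gaussian_spec(), group_sd = 0.5,
                              seed = 1L) {
  with_seed(seed, {
    blocks <- lapply(seq_len(n_groups), function(g) {
      off <- rnorm(2, 0, group_sd)
      x <- rbind(
        MASS::mvrnorm(rows_per_class, spec$mean1 + off, spec$cov1),
        MASS::mvrnorm(rows_per_class, spec$mean2 + off, spec$cov2))
      list(x = x, y = rep(c("class1", "class2"), each = rows_per_class),
           g = rep(sprintf("p%02d", g), 2L * rows_per_class))
    })
    x <- do.call(rbind, lapply(blocks, `[[`, "x"))
    colnames(x) <- c("f1", "f2")
    feature_dataset(x,
                    label = unlist(lapply(blocks, `[[`, "y")),
                    group_id = unlist(lapply(blocks, `[[`, "g")))
  })
}
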