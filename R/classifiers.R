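# Classifier adapters behind one train/predict/error contract, so the
# resampling engines are classifier-agnostic. Three families: k-nearest
# neighbour, Gaussian naive Bayes, and a soft-margin SVM with RBF kernel.
#
# kNN and naive Bayes are implemented in-package: the engines need bit-for-bit
# deterministic predictions, so kNN pins its distance and vote tie-breaking
# (ties in the k-th distance go to the lowest training row index; vote ties go
# to the class of the single nearest neighbour) and naive Bayes pins its
# variance floor. The SVM delegates to libsvm via e1071.

#' Specify a classifier
#'
#' @param family one of `"knn"`, `"naive_bayes"`, `"svm_rbf"`.
#' @param k number of neighbours (kNN). Default 3.
#' @param cost soft-margin cost C (SVM). Default 1.
#' @param gamma RBF kernel width (SVM); default `NULL` means
#'   \eqn{1 / (d \cdot \mathrm{Var}(X))} computed on the training features,
#'   where d is the feature dimensionality.
#' @param standardize center/scale features using training-subset statistics
#'   before training and prediction (applied to the test pool with the
#'   training parameters, avoiding leakage). Default off.
#' @return an object of class `classifier_spec`.
#' @export
classifier_spec <- function(family = c("knn", "naive_bayes", "svm_rbf"),
                            k = 3L, cost = 1, gamma = NULL,
                            standardize = FALSE) {
  family <- match.arg(family)
  k <- as.integer(k)
  if (family == "knn" && (is.na(k) || k < 1L))
    stop("k must be a positive integer")
  if (family == "svm_rbf") {
    if (!is.numeric(cost) || cost <= 0) stop("cost must be a positive real")
    if (!is.null(gamma) && (!is.numeric(gamma) || gamma <= 0))
      stop("gamma must be a positive real")
  }
  structure(list(family = family, k = k, cost = cost, gamma = gamma,
                 standardize = isTRUE(standardize)),
            class = "classifier_spec")
}

#' @export
format.classifier_spec <- function(x, ...) {
  switch(x$family,
    knn = paste0("kNN (k=", x$k, ")"),
    naive_bayes = "Gaussian naive Bayes",
    svm_rbf = paste0("SVM-RBF (C=", x$cost, ", gamma=",
                     if (is.null(x$gamma)) "1/(d*var)" else x$gamma, ")"))
}

#' @export
print.classifier_spec <- function(x, ...) {
  cat("<classifier_spec> ", format(x), "\n", sep = "")
  invisible(x)
}

.standardize_fit <- function(x) {
  mu <- colMeans(x)
  sdev <- apply(x, 2, sd)
  sdev[sdev == 0 | !is.finite(sdev)] <- 1
  list(mu = mu, sd = sdev)
}

.standardize_apply <- function(x, p) {
  sweep(sweep(x, 2, p$mu, "-"), 2, p$sd, "/")
}

#' Train a classifier
#'
#' @param spec a [classifier_spec()].
#' @param x numeric training feature matrix.
#' @param y two-level factor of training labels (both levels present).
#' @return an opaque trained model of class `trained_model`.
#' @export
train_classifier <- function(spec, x, y) {
  x <- as.matrix(x)
  if (!is.factor(y) || nlevels(y) != 2L)
    stop("y must be a two-level factor")
  if (length(unique(as.integer(y))) < 2L)
    stop("training set contains a single class")
  std <- NULL
  if (spec$standardize) {
    std <- .standardize_fit(x)
    x <- .standardize_apply(x, std)
  }
  model <- switch(spec$family,
    knn = list(x = x, y = as.integer(y), k = min(spec$k, nrow(x))),
    naive_bayes = {
      yi <- as.integer(y)
      mu <- rbind(colMeans(x[yi == 1L, , drop = FALSE]),
                  colMeans(x[yi == 2L, , drop = FALSE]))
      v <- rbind(apply(x[yi == 1L, , drop = FALSE], 2, var),
                 apply(x[yi == 2L, , drop = FALSE], 2, var))
      v[is.na(v)] <- 0
      floor_v <- 1e-9 * max(apply(x, 2, var), 1e-300)
      v[v < floor_v] <- floor_v
      list(mu = mu, var = v, prior = tabulate(yi, 2L) / length(yi))
    },
    svm_rbf = {
      g <- spec$gamma
      if (is.null(g)) {
        vx <- var(as.vector(x))
        g <- if (is.finite(vx) && vx > 0) 1 / (ncol(x) * vx) else 1 / ncol(x)
      }
      e1071::svm(x, y, type = "C-classification", kernel = "radial",
                 cost = spec$cost, gamma = g, scale = FALSE)
    })
  structure(list(spec = spec, model = model, levels = levels(y), std = std),
            class = c(paste0("rrs_", spec$family), "trained_model"))
}

#' Predict class labels
#'
#' @param object a `trained_model` from [train_classifier()].
#' @param newdata numeric feature matrix with the training dimensionality.
#' @param ... unused.
#' @return a factor of predicted labels with the training levels.
#' @export
predict.trained_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  d <- if (object$spec$family == "svm_rbf") ncol(object$model$SV)
       else ncol(if (object$spec$family == "knn") object$model$x
                 else object$model$mu)
  if (ncol(newdata) != d)
    stop("feature dimensionality mismatch: model has ", d, ", data has ",
         ncol(newdata))
  if (!is.null(object$std)) newdata <- .standardize_apply(newdata, object$std)
  pred <- switch(object$spec$family,
    knn = cpp_knn_predict(object$model$x, object$model$y, newdata,
                          object$model$k),
    naive_bayes = {
      m <- object$model
      ll <- sapply(1:2, function(c) {
        rowSums(-0.5 * log(2 * pi * matrix(m$var[c, ], nrow(newdata),
                                           ncol(newdata), byrow = TRUE)) -
                0.5 * sweep(newdata, 2, m$mu[c, ], "-")^2 /
                  matrix(m$var[c, ], nrow(newdata), ncol(newdata),
                         byrow = TRUE)) + log(m$prior[c])
      })
      ifelse(ll[, 1] >= ll[, 2], 1L, 2L)
    },
    svm_rbf = as.integer(predict(object$model, newdata)))
  factor(object$levels[pred], levels = object$levels)
}

#' Misclassification rate on a test set
#'
#' @param model a `trained_model`.
#' @param x test feature matrix.
#' @param y true labels (factor with the training levels).
#' @return fraction of rows whose predicted label differs from `y`, in
#'   \[0, 1\].
#' @export
error_rate <- function(model, x, y) {
  if (length(y) == 0L) stop("test set is empty")
  mean(as.character(predict(model, x)) != as.character(y))
}
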