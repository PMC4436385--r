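specs <- list(
  knn = classifier_spec("knn", k = 3),
  naive_bayes = classifier_spec("naive_bayes"),
  svm_rbf = classifier_spec("svm_rbf")
)

test_that("1-NN labels a training point with its own class; all families separate easy clusters", {
  data <- separated_clusters()
  m1 <- train_classifier(classifier_spec("knn", k = 1), data$features,
                         data$label)
  expect_equal(as.character(predict(m1, data$features)),
               as.character(data$label))
  for (spec in specs) {
    m <- train_classifier(spec, data$features, data$label)
    expect_equal(error_rate(m, data$features, data$label), 0)
  }
})

test_that("naive Bayes puts the boundary at the midpoint of equal-variance 1-D clusters", {
  # symmetric clusters around 2 and 6: discriminant crosses at 4
  x <- matrix(c(1.5, 2, 2.5, 5.5, 6, 6.5), ncol = 1)
  y <- factor(rep(c("lo", "hi"), each = 3), levels = c("lo", "hi"))
  m <- train_classifier(classifier_spec("naive_bayes"), x, y)
  expect_equal(as.character(predict(m, matrix(c(3.9, 4.1), ncol = 1))),
               c("lo", "hi"))
})

test_that("error_rate counts misclassified fractions exactly", {
  data <- separated_clusters()
  m <- train_classifier(specs$knn, data$features, data$label)
  expect_equal(error_rate(m, data$features, data$label), 0)
  flipped <- factor(ifelse(data$label == "class1", "class2", "class1"),
                    levels = levels(data$label))
  expect_equal(error_rate(m, data$features, flipped), 1)
  mixed <- data$label
  mixed[1:5] <- ifelse(mixed[1:5] == "class1", "class2", "class1")
  expect_equal(error_rate(m, data$features, mixed), 5 / 20)
})

test_that("swapping class names leaves every family's error rate unchanged", {
  data <- default_pilot(seed = 31)
  test <- gaussian_two_class(gaussian_spec(n_per_class = 30, seed = 32))
  sw <- function(y) factor(ifelse(y == "class1", "B", "A"),
                           levels = c("A", "B"))
  for (spec in specs) {
    e1 <- error_rate(train_classifier(spec, data$features, data$label),
                     test$features, test$label)
    e2 <- error_rate(train_classifier(spec, data$features, sw(data$label)),
                     test$features, sw(test$label))
    expect_equal(e1, e2, info = spec$family)
  }
})

test_that("training fails on single-class input and predicting on wrong width", {
  data <- separated_clusters()
  one <- subset_rows(data, which(data$label == "class1"))
  for (spec in specs)
    expect_error(train_classifier(spec, one$features, one$label),
                 "single class")
  m <- train_classifier(specs$knn, data$features, data$label)
  expect_error(predict(m, data$features[, 1, drop = FALSE]), "mismatch")
})

test_that("compiled kNN matches an independent R reference and class::knn", {
  skip_if_not_installed("class")
  set.seed(77)
  for (trial in 1:20) {
    ntr <- sample(5:40, 1)
    k <- sample(c(1, 3, 5), 1)
    xtr <- matrix(rnorm(ntr * 2), ncol = 2)
    ytr <- sample(1:2, ntr, replace = TRUE)
    if (length(unique(ytr)) < 2) ytr[1:2] <- 1:2
    xte <- matrix(rnorm(30), ncol = 2)
    m <- train_classifier(classifier_spec("knn", k = k), xtr,
                          factor(c("c1", "c2"))[ytr])
    got <- as.integer(factor(predict(m, xte), levels = c("c1", "c2")))
    expect_equal(got, unname(ref_knn_predict(xtr, ytr, xte, k)))
    if (k %% 2 == 1 && k <= ntr) {
      # odd k on continuous data: no distance or vote ties, class::knn agrees
      cls <- as.integer(class::knn(xtr, xte, factor(ytr), k = k))
      expect_equal(got, cls)
    }
  }
})

test_that("Gaussian naive Bayes agrees with e1071's on balanced data", {
  data <- default_pilot(seed = 41)
  test <- gaussian_two_class(gaussian_spec(n_per_class = 50, seed = 42))
  m <- train_classifier(specs$naive_bayes, data$features, data$label)
  ours <- predict(m, test$features)
  ref <- e1071::naiveBayes(data$features, data$label)
  theirs <- predict(ref, test$features)
  expect_gt(mean(as.character(ours) == as.character(theirs)), 0.99)
})

test_that("training and prediction are deterministic given the inputs", {
  data <- default_pilot(seed = 51)
  test <- gaussian_two_class(gaussian_spec(n_per_class = 30, seed = 52))
  for (spec in specs) {
    e1 <- error_rate(train_classifier(spec, data$features, data$label),
                     test$features, test$label)
    e2 <- error_rate(train_classifier(spec, data$features, data$label),
                     test$features, test$label)
    expect_identical(e1, e2)
  }
})

test_that("standardization uses training statistics only and NB floors zero variances", {
  data <- default_pilot(seed = 61)
  # scale-sensitive check: blowing up one feature changes plain kNN but not
  # the standardized one
  scaled <- data
  scaled$features[, 2] <- scaled$features[, 2] * 1000
  test <- gaussian_two_class(gaussian_spec(n_per_class = 30, seed = 62))
  stest <- test; stest$features[, 2] <- stest$features[, 2] * 1000
  spec_std <- classifier_spec("knn", k = 3, standardize = TRUE)
  e_plain <- error_rate(train_classifier(specs$knn, data$features, data$label),
                        test$features, test$label)
  e_std <- error_rate(train_classifier(spec_std, scaled$features, scaled$label),
                      stest$features, stest$label)
  expect_lt(abs(e_std - e_plain), 0.05)

  # constant feature must not produce NaN likelihoods
  rows <- c(1:5, 51:55)
  x <- cbind(data$features[rows, 1], rep(2, 10))
  m <- train_classifier(specs$naive_bayes, x, data$label[rows])
  p <- predict(m, x)
  expect_false(anyNA(p))
})
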