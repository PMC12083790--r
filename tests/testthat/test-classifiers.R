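test_that("one-hot least squares separates a trivially separable 1-D problem", {
  x <- matrix(c(-5, -4, -4.5, 4, 4.5, 5), ncol = 1)
  y <- factor(c("lo", "lo", "lo", "hi", "hi", "hi"), levels = c("lo", "hi"))
  fit <- fit_classifier(x, y, model_config("linear_onehot"))
  expect_equal(mean(predict(fit, x) == y), 1)
})

test_that("one-hot least squares matches the closed-form oracle", {
  set.seed(20)
  for (rep in 1:10) {
    n <- 20L; p <- 3L
    x <- matrix(rnorm(n * p), n, p)
    y <- factor(sample(c("a", "b", "c"), n, replace = TRUE))
    while (nlevels(droplevels(y)) < 3L) y <- factor(sample(c("a", "b", "c"), n, TRUE))
    fit <- fit_classifier(x, y, model_config("linear_onehot"))
    Y <- diag(3)[as.integer(y), ]
    oracle <- stats::lm.fit(cbind(1, x), Y)$coefficients
    got <- rbind(fit$state$beta0, fit$state$beta)
    expect_equal(unname(got), unname(oracle), tolerance = 1e-8)
    # predictions are the argmax of the linear scores
    scores <- cbind(1, x) %*% oracle
    expect_identical(as.integer(predict(fit, x)),
                     max.col(scores, ties.method = "first"))
  }
})

test_that("linear argmax ties resolve to the lowest class code", {
  x <- matrix(rnorm(8), 4, 2)
  y <- factor(c("a", "b", "c", "a"))
  fit <- fit_classifier(x, y, model_config("linear_onehot"))
  fit$state$beta <- matrix(0, 2, 3)
  fit$state$beta0 <- c(1, 0, 0)
  expect_equal(as.character(predict(fit, x)), rep("a", 4))
  fit$state$beta0 <- c(0.5, 0.5, 0.5)
  expect_equal(as.character(predict(fit, x)), rep("a", 4))
})

test_that("every classifier kind honours the uniform fit/predict contract", {
  em <- toy_matrix(n_per_class = c(12L, 12L, 12L), p = 6L)
  xs <- standardize(em$values)
  kinds <- c("random_forest", "decision_tree", "linear_onehot", "svm_pca", "lstm")
  for (kind in kinds) {
    cfg <- if (kind == "lstm") model_config(kind, seed = 7L, epochs = 5L)
           else model_config(kind, seed = 7L)
    fit <- fit_classifier(xs, em$labels, cfg)
    pred <- predict(fit, xs)
    expect_s3_class(pred, "factor")
    expect_identical(levels(pred), levels(em$labels))
    expect_length(pred, nrow(xs))
    # same data + same seed -> identical predictions
    refit <- fit_classifier(xs, em$labels, cfg)
    expect_identical(predict(refit, xs), pred)
    # feature-count mismatch is a shape error
    expect_error(predict(fit, xs[, 1:3]), "features")
  }
  expect_error(fit_classifier(xs, factor(rep("a", nrow(xs))),
                              model_config("random_forest")),
               "single-class")
})

test_that("random forest prediction is the majority vote over its trees", {
  em <- toy_matrix(n_per_class = c(15L, 15L), p = 5L)
  xs <- standardize(em$values)
  fit <- fit_classifier(xs, em$labels, model_config("random_forest", seed = 3L))
  per_tree <- predict(fit$state, xs, predict.all = TRUE)$individual
  vote <- apply(per_tree, 1L, function(v) names(which.max(table(v))))
  agreed <- as.character(predict(fit, xs)) == vote
  # modal ties may break differently; the vote must agree wherever unique
  modal_unique <- apply(per_tree, 1L, function(v) {
    tab <- table(v); sum(tab == max(tab)) == 1L
  })
  expect_true(all(agreed[modal_unique]))
})

test_that("PCA retains the minimal component count for the variance target", {
  set.seed(30)
  x <- matrix(rnorm(40 * 6), 40, 6)
  full <- apply_pca(x, variance_fraction = 1.0)
  expect_equal(full$ncomp, 6L)
  recon <- full$scores %*% t(full$rotation)
  expect_equal(sweep(recon, 2L, full$center, "+"), x, tolerance = 1e-8,
               ignore_attr = TRUE)
  # rank-1 data needs exactly one component
  r1 <- outer(rnorm(20), rnorm(4))
  expect_equal(apply_pca(r1, 0.99)$ncomp, 1L)
  # projected training covariance is diagonal
  cv <- cov(full$scores)
  expect_equal(cv, diag(diag(cv)), tolerance = 1e-8, ignore_attr = TRUE)
  expect_error(apply_pca(x, 0), "variance_fraction")
  expect_error(apply_pca(x, 1.5), "variance_fraction")
})

test_that("the LSTM learns a separable problem and records its loss curve", {
  em <- toy_matrix(n_per_class = c(10L, 10L), p = 6L)
  xs <- standardize(em$values)
  fit <- lstm_fit(xs, em$labels, epochs = 30L, seed = 5L)
  expect_s3_class(fit, "lstm_model")
  expect_equal(nrow(fit$history), 30L)
  expect_true(all(diff(fit$history$loss[c(1, 30)]) < 0))  # loss decreased
  expect_gte(tail(fit$history$accuracy, 1L), 0.9)
  pred <- lstm_predict(fit, xs)
  expect_true(all(pred %in% levels(em$labels)))
})

test_that("the LSTM fits the default synthetic task within its 100-epoch budget", {
  sim <- simulate_expression(sim_config(seed = 11))
  em <- sim$matrix
  sel <- separability(em, k = 25L)$selected
  xs <- standardize(em$values[, sel])
  reached <- vapply(1:5, function(s) {
    fit <- lstm_fit(xs, em$labels, seed = s)
    ok <- max(fit$history$accuracy) >= 1
    if (!ok) {
      message("LSTM seed ", s, " did not reach training accuracy 1.0; loss curve:")
      message(paste(sprintf("%.4f", fit$history$loss), collapse = " "))
    }
    ok
  }, logical(1))
  expect_gte(sum(reached), 4L)
})

test_that("hyperparameter validation rejects unknown or out-of-range settings", {
  expect_error(model_config("svm_pca", variance_fraction = 2), "variance_fraction")
  expect_error(model_config("random_forest", bogus = 1), "unknown hyperparameter")
  cfg <- model_config("lstm", hidden = 8L, epochs = 2L)
  expect_equal(cfg$hyperparameters$hidden, 8L)
})
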