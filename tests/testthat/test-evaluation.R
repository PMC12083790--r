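test_that("holdout splits hit the requested sizes and are seed-deterministic", {
  labs <- factor(rep(c("a", "b"), each = 5))
  sp <- make_split(labs, 0.6, seed = 1)
  expect_length(sp$train, 6L)
  expect_length(sp$test, 4L)
  expect_setequal(c(sp$train, sp$test), 1:10)
  expect_identical(make_split(labs, 0.6, seed = 1), sp)
  expect_false(identical(make_split(labs, 0.6, seed = 2)$train, sp$train))
  expect_error(make_split(labs, 1.2), "train_fraction")
  expect_error(make_split(factor(c("a", "b", "b")), 0.5), "'a'.*fewer than 2")
})

test_that("stratified splits keep per-class training counts near the fraction", {
  labs <- factor(rep(paste0("c", 1:5), times = c(8, 10, 26, 10, 10)),
                 levels = paste0("c", 1:5))
  sp <- make_split(labs, 0.6, seed = 9)
  tr_counts <- table(labs[sp$train])
  expected <- 0.6 * c(8, 10, 26, 10, 10)
  expect_true(all(abs(as.numeric(tr_counts) - expected) <= 1))
  te_counts <- table(labs[sp$test])
  expect_true(all(te_counts >= 1))
})

test_that("k-fold plans partition the samples into near-equal stratified folds", {
  labs <- factor(rep(c("a", "b"), each = 5))
  plan <- kfold(labs, K = 5, seed = 3)
  expect_equal(sort(unique(plan$fold)), 1:5)
  expect_equal(as.numeric(table(plan$fold)), rep(2, 5))
  # leave-one-out at K = n (unstratified; classes are smaller than K)
  loo <- kfold(labs, K = 10, seed = 3, stratified = FALSE)
  expect_equal(sort(tabulate(loo$fold, 10)), rep(1L, 10))
  expect_error(kfold(labs, K = 6, seed = 1), "fewer than K")
  # unbalanced stratified folds stay within one sample of each other
  labs2 <- factor(rep(paste0("c", 1:5), times = c(8, 10, 26, 10, 10)))
  plan2 <- kfold(labs2, K = 5, seed = 4)
  sizes <- as.numeric(table(plan2$fold))
  expect_lte(max(sizes) - min(sizes), 1)
  for (lv in levels(labs2)) {
    per_fold <- tabulate(plan2$fold[labs2 == lv], 5)
    expect_lte(max(per_fold) - min(per_fold), 1)
  }
})

test_that("metrics match hand arithmetic on a binary confusion matrix", {
  # confusion [[3,1],[2,4]]: rows true, columns predicted
  truth <- c(rep("x", 4), rep("y", 6))
  pred <- c("x", "x", "x", "y", "x", "x", "y", "y", "y", "y")
  ev <- evaluate_predictions(truth, pred, levels = c("x", "y"))
  expect_equal(unname(ev$confusion), matrix(c(3, 2, 1, 4), 2))
  expect_equal(ev$accuracy, 0.7)
  expect_equal(ev$per_class$precision[1], 3 / 5)
  expect_equal(ev$per_class$recall[1], 3 / 4)
  expect_equal(ev$per_class$f1[1], 2 * (3 / 5) * (3 / 4) / (3 / 5 + 3 / 4))
  # specificity of class x is the recall of class y
  expect_equal(ev$per_class$specificity[1], 4 / 6)
})

test_that("perfect and degenerate predictors hit the metric boundaries", {
  truth <- rep(c("a", "b", "c"), times = c(4, 3, 3))
  ev <- evaluate_predictions(truth, truth)
  expect_equal(ev$accuracy, 1)
  expect_equal(ev$precision, 1)
  expect_equal(ev$recall, 1)
  expect_equal(ev$f1, 1)
  # constant predictor: recall 1 for its class, 0 elsewhere, zero-denominator
  # precision defined as 0
  ev2 <- evaluate_predictions(c("a", "a", "b", "b"), rep("a", 4),
                              levels = c("a", "b"))
  expect_equal(ev2$per_class$recall, c(1, 0))
  expect_equal(ev2$per_class$precision, c(0.5, 0))
  expect_error(evaluate_predictions(c("a", "b"), c("a", "z"),
                                    levels = c("a", "b")), "outside the class set")
})

test_that("micro averages collapse to accuracy and counts are conserved", {
  set.seed(40)
  for (rep in 1:10) {
    lv <- letters[1:sample(2:5, 1)]
    n <- sample(10:60, 1)
    truth <- factor(sample(lv, n, replace = TRUE), levels = lv)
    pred <- factor(sample(lv, n, replace = TRUE), levels = lv)
    ev <- evaluate_predictions(truth, pred, averaging = "micro")
    expect_equal(ev$precision, ev$accuracy, tolerance = 1e-12)
    expect_equal(ev$recall, ev$accuracy, tolerance = 1e-12)
    expect_equal(sum(ev$confusion), n)
    with(ev$per_class, expect_true(all(tp + fp + fn + tn == n)))
  }
})

test_that("weighted and macro averages coincide on balanced classes", {
  truth <- factor(rep(c("a", "b"), each = 10))
  set.seed(41)
  pred <- factor(sample(c("a", "b"), 20, replace = TRUE), levels = levels(truth))
  w <- evaluate_predictions(truth, pred, averaging = "weighted")
  m <- evaluate_predictions(truth, pred, averaging = "macro")
  expect_equal(w$precision, m$precision)
  expect_equal(w$f1, m$f1)
})

test_that("the pipeline emits one configured report per model", {
  em <- toy_matrix(n_per_class = c(12L, 12L, 12L), p = 10L)
  res <- run_pipeline(em, k = 5L,
                      models = c("random_forest", "linear_onehot"),
                      seed = 5L, verbose = FALSE)
  expect_named(res$reports, c("random_forest", "linear_onehot"))
  expect_equal(nrow(res$summary), 2L)
  rep1 <- res$reports$random_forest
  expect_equal(rep1$model$kind, "random_forest")
  expect_equal(rep1$model$hyperparameters$ntree, 100L)
  expect_equal(rep1$split$train_fraction, 0.6)
  expect_equal(sum(rep1$confusion), length(res$split$test))
  expect_true(all(res$summary$accuracy >= 0 & res$summary$accuracy <= 1))
})

test_that("selection inside cross-validation is refitted per fold", {
  em <- toy_matrix(n_per_class = c(10L, 10L, 10L), p = 12L)
  res <- run_pipeline(em, k = 4L, models = "linear_onehot", seed = 6L,
                      kfold_k = 3L, verbose = FALSE)
  expect_true("accuracy_kfold" %in% names(res$summary))
  expect_gte(res$summary$accuracy_kfold, 0)
  expect_lte(res$summary$accuracy_kfold, 1)
})
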