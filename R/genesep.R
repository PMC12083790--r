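#' Fit a separability-filtered expression classifier
#'
#' The package's main modelling interface: ranks every gene by its
#' class-separability score, keeps the top `k`, standardizes them (fitting
#' the transform on the supplied data, which plays the role of the training
#' set), and trains one classifier on the result. The returned object
#' predicts labels for new samples over the full gene set: selection and
#' standardization learned at fit time are replayed on new data.
#'
#' @param x samples-by-genes numeric matrix or [expression_matrix()].
#' @param labels class labels; taken from `x` when it is an `expr_matrix`.
#' @param k number of genes to keep. Default 25.
#' @param classifier classifier kind (see [model_config()]) or a ready-made
#'   `model_config`. Default `"svm_pca"`.
#' @param standardize z-score the selected genes before training. Default
#'   `TRUE`.
#' @param sd_convention `"population"` (default) or `"sample"`.
#' @param standardize_before_select score genes on the standardized matrix
#'   instead of the matrix as given. Default `FALSE` (methods vignette
#'   discusses why).
#' @param direction score sort direction. Default `"descending"`.
#' @param seed integer seed for the classifier. Default 1.
#' @param ... hyperparameter overrides forwarded to [model_config()] when
#'   `classifier` is a kind name.
#' @return An object of class `genesep` with components `selection` (a
#'   `separability` object), `standardizer` (or `NULL`), `model` (a
#'   `fitted_model`), `levels`, `training` (fitted labels and training
#'   accuracy), and `call`.
#' @export
#' @examples
#' sim <- simulate_expression(sim_config(p = 500, seed = 3))
#' fit <- genesep(sim$matrix, k = 10, classifier = "linear_onehot")
#' fit
#' pred <- predict(fit, sim$matrix)
#' mean(pred == sim$matrix$labels)
genesep <- function(x, labels = NULL, k = 25L, classifier = "svm_pca",
                    standardize = TRUE,
                    sd_convention = c("population", "sample"),
                    standardize_before_select = FALSE,
                    direction = c("descending", "ascending"),
                    seed = 1L, ...) {
  sd_convention <- match.arg(sd_convention)
  direction <- match.arg(direction)
  if (inherits(x, "expr_matrix")) {
    labels <- x$labels
    x <- x$values
  }
  stopifnot(is.matrix(x))
  labels <- as.factor(labels)
  check_two_classes(labels)
  cfg <- if (inherits(classifier, "model_config")) classifier else
    model_config(classifier, seed = seed, ...)

  sel_src <- x
  if (standardize_before_select) {
    sel_src <- apply_standardizer(fit_standardizer(x, sd_convention), x)
  }
  sel <- separability(sel_src, labels, k = k, direction = direction)
  sel$gene_ids <- colnames(x)

  xs <- x[, sel$selected, drop = FALSE]
  std <- NULL
  if (standardize) {
    std <- fit_standardizer(xs, sd_convention)
    xs <- apply_standardizer(std, xs)
  }
  model <- fit_classifier(xs, labels, cfg)
  fitted_labels <- predict(model, xs)
  structure(list(selection = sel, standardizer = std, model = model,
                 levels = levels(labels), k = as.integer(k),
                 training = list(labels = labels, fitted = fitted_labels,
                                 accuracy = mean(fitted_labels == labels)),
                 call = match.call()),
            class = "genesep")
}

#' Predict method for genesep fits
#'
#' @param object a `genesep` fit.
#' @param newdata samples-by-genes matrix or [expression_matrix()] with the
#'   same gene count (and order) as the training data.
#' @param ... ignored.
#' @return Factor of predicted class labels.
#' @export
predict.genesep <- function(object, newdata, ...) {
  if (inherits(newdata, "expr_matrix")) newdata <- newdata$values
  stopifnot(is.matrix(newdata))
  if (ncol(newdata) != length(object$selection$scores)) {
    stop(sprintf("fit used %d genes, newdata has %d",
                 length(object$selection$scores), ncol(newdata)), call. = FALSE)
  }
  xs <- newdata[, object$selection$selected, drop = FALSE]
  if (!is.null(object$standardizer)) {
    xs <- apply_standardizer(object$standardizer, xs)
  }
  predict(object$model, xs)
}

#' @export
print.genesep <- function(x, ...) {
  cat("separability-filtered expression classifier\n")
  cat(sprintf("  classifier: %s;  genes kept: %d of %d;  classes: %d\n",
              x$model$config$kind, length(x$selection$selected),
              length(x$selection$scores), length(x$levels)))
  cat(sprintf("  training accuracy: %.4f\n", x$training$accuracy))
  invisible(x)
}

#' @export
summary.genesep <- function(object, ...) {
  ev <- evaluate_predictions(object$training$labels, object$training$fitted,
                             levels = object$levels)
  out <- list(fit = object, training_evaluation = ev)
  class(out) <- "summary.genesep"
  out
}

#' @export
print.summary.genesep <- function(x, ...) {
  print(x$fit)
  cat("\ntop-ranked genes:\n")
  print(x$fit$selection)
  cat("\ntraining-set evaluation (optimistic; use a holdout for honest numbers):\n")
  print(x$training_evaluation)
  invisible(x)
}

#' Coefficients of a genesep fit
#'
#' For the one-hot least-squares classifier, returns the `(k + 1) x c`
#' coefficient matrix (first row: intercepts; remaining rows: per-gene
#' slopes, one column per class). Other classifier kinds have no linear
#' coefficients and return `NULL`.
#'
#' @param object a `genesep` fit.
#' @param ... ignored.
#' @return Numeric matrix or `NULL`.
#' @export
coef.genesep <- function(object, ...) {
  if (object$model$config$kind != "linear_onehot") return(NULL)
  st <- object$model$state
  out <- rbind(`(intercept)` = st$beta0, st$beta)
  colnames(out) <- st$classes
  ids <- object$selection$gene_ids
  if (!is.null(ids)) {
    rownames(out)[-1L] <- ids[object$selection$selected]
  }
  out
}

#' @export
plot.genesep <- function(x, ...) {
  plot(x$selection, ...)
  invisible(x)
}
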