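#' Classifier configuration
#'
#' Builds a validated configuration for one of the five classifier kinds
#' under the uniform fit/predict contract. Unstated hyperparameters default
#' to field-standard values; every report echoes the full configuration.
#'
#' @param kind one of `"random_forest"`, `"decision_tree"`, `"linear_onehot"`,
#'   `"svm_pca"`, `"lstm"`.
#' @param seed integer seed controlling any stochastic element of training.
#' @param ... kind-specific overrides:
#'   * random_forest: `ntree` (100), `mtry` (randomForest default).
#'   * decision_tree: `minsplit` (rpart default 20), `cp` (0.01).
#'   * linear_onehot: `link` — `"identity"` (one-hot least squares, default)
#'     or `"logistic"` (multinomial logistic alternative via [nnet-free]
#'     one-vs-rest IRLS is *not* provided; `"logistic"` fits per-class
#'     binomial GLMs and takes the argmax).
#'   * svm_pca: `variance_fraction` (0.95), `kernel` (`"radial"`), `cost` (1),
#'     `gamma` (e1071 default).
#'   * lstm: `hidden` (64), `epochs` (100), `learning_rate` (1e-3),
#'     `batch_size` (8), `input_mode` (`"per_feature"` — one feature per
#'     timestep — or `"single_step"`).
#' @return A `model_config` list.
#' @export
model_config <- function(kind = c("random_forest", "decision_tree",
                                  "linear_onehot", "svm_pca", "lstm"),
                         seed = 1L, ...) {
  kind <- match.arg(kind)
  defaults <- switch(kind,
    random_forest = list(ntree = 100L, mtry = NULL),
    decision_tree = list(minsplit = 20L, cp = 0.01),
    linear_onehot = list(link = "identity"),
    svm_pca = list(variance_fraction = 0.95, kernel = "radial",
                   cost = 1, gamma = NULL),
    lstm = list(hidden = 64L, epochs = 100L, learning_rate = 1e-3,
                batch_size = 8L, input_mode = "per_feature")
  )
  override <- list(...)
  unknown <- setdiff(names(override), names(defaults))
  if (length(unknown)) {
    stop(sprintf("unknown hyperparameter(s) for %s: %s", kind,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  hp <- utils::modifyList(defaults, override)
  if (kind == "svm_pca") {
    vf <- hp$variance_fraction
    if (!is.numeric(vf) || vf <= 0 || vf > 1) {
      stop("`variance_fraction` must be in (0, 1]", call. = FALSE)
    }
  }
  structure(list(kind = kind, hyperparameters = hp, seed = as.integer(seed)),
            class = "model_config")
}

#' Fit a classifier on selected genes
#'
#' Trains one of the five classifier kinds on a numeric feature matrix and
#' class labels, under a uniform contract: the result always answers
#' [predict()] with one label per row. Training is deterministic given the
#' data and `config$seed`.
#'
#' @param x numeric matrix (samples x features), typically the standardized
#'   expression of the selected genes, or an [expression_matrix()].
#' @param y class labels (factor); taken from `x` when it is an
#'   `expr_matrix`.
#' @param config a [model_config()].
#' @return An object of class `fitted_model` with elements `config`, `state`
#'   (opaque trained parameters), `classes` (level order = class codes), and
#'   `p` (training feature count).
#' @export
fit_classifier <- function(x, y = NULL, config = model_config()) {
  if (inherits(x, "expr_matrix")) {
    y <- x$labels
    x <- x$values
  }
  stopifnot(inherits(config, "model_config"), is.matrix(x))
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2L) stop("single-class training data", call. = FALSE)
  if (nrow(x) != length(y)) stop("x and y disagree on sample count", call. = FALSE)
  hp <- config$hyperparameters
  set.seed(config$seed)
  state <- switch(config$kind,
    random_forest = {
      args <- list(x = x, y = y, ntree = hp$ntree)
      if (!is.null(hp$mtry)) args$mtry <- hp$mtry
      do.call(randomForest::randomForest, args)
    },
    decision_tree = {
      xx <- x
      colnames(xx) <- paste0("F", seq_len(ncol(xx)))  # stable names for predict
      df <- data.frame(.class = y, xx, check.names = FALSE)
      rpart::rpart(.class ~ ., data = df, method = "class",
                   control = rpart::rpart.control(minsplit = hp$minsplit,
                                                  cp = hp$cp, xval = 0))
    },
    linear_onehot = fit_linear_onehot(x, y, link = hp$link),
    svm_pca = fit_svm_pca(x, y, hp),
    lstm = lstm_fit(x, y, hidden = hp$hidden, epochs = hp$epochs,
                    learning_rate = hp$learning_rate,
                    batch_size = hp$batch_size,
                    input_mode = hp$input_mode, seed = config$seed)
  )
  structure(list(config = config, state = state,
                 classes = levels(y), p = ncol(x)),
            class = "fitted_model")
}

#' Predict class labels from a fitted classifier
#'
#' @param object a `fitted_model` from [fit_classifier()].
#' @param newdata numeric matrix with the training feature count, or an
#'   [expression_matrix()].
#' @param ... ignored.
#' @return Factor of predicted labels with the training class levels.
#' @export
predict.fitted_model <- function(object, newdata, ...) {
  if (inherits(newdata, "expr_matrix")) newdata <- newdata$values
  stopifnot(is.matrix(newdata))
  if (ncol(newdata) != object$p) {
    stop(sprintf("model was trained on %d features, got %d",
                 object$p, ncol(newdata)), call. = FALSE)
  }
  out <- switch(object$config$kind,
    random_forest = as.character(predict(object$state, newdata)),
    decision_tree = {
      colnames(newdata) <- paste0("F", seq_len(ncol(newdata)))
      df <- as.data.frame(newdata, check.names = FALSE)
      pr <- predict(object$state, df, type = "prob")
      colnames(pr)[max.col(pr, ties.method = "first")]
    },
    linear_onehot = predict_linear_onehot(object$state, newdata),
    svm_pca = predict_svm_pca(object$state, newdata),
    lstm = lstm_predict(object$state, newdata)
  )
  factor(out, levels = object$classes)
}

#' @export
print.fitted_model <- function(x, ...) {
  cat(sprintf("fitted %s classifier: %d features, %d classes (seed %d)\n",
              x$config$kind, x$p, length(x$classes), x$config$seed))
  invisible(x)
}

# ---- one-hot least-squares linear classifier (from scratch) ----------------

# Minimum-norm least-squares fit of a one-hot indicator matrix on
# [1 | X]: B = pinv([1 X]) Y via SVD, robust to p >= n. Prediction is the
# argmax of the linear scores, ties broken by the lowest class code.
fit_linear_onehot <- function(x, y, link = "identity") {
  classes <- levels(y)
  c_ <- length(classes)
  n <- nrow(x)
  Y <- matrix(0, n, c_)
  Y[cbind(seq_len(n), as.integer(y))] <- 1
  if (identical(link, "logistic")) {
    # clearly-labelled alternative: per-class binomial GLM, argmax of fits
    Xd <- x
    fits <- lapply(seq_len(c_), function(j) {
      stats::glm.fit(cbind(1, Xd), Y[, j], family = stats::binomial())$coefficients
    })
    B <- do.call(cbind, fits)
    B[is.na(B)] <- 0
    return(list(link = "logistic", beta0 = B[1L, ], beta = B[-1L, , drop = FALSE],
                classes = classes))
  }
  Xd <- cbind(1, x)
  sv <- svd(Xd)
  pos <- sv$d > max(dim(Xd)) * .Machine$double.eps * sv$d[1L]
  dinv <- ifelse(pos, 1 / sv$d, 0)
  B <- sv$v %*% (dinv * (t(sv$u) %*% Y))
  list(link = "identity", beta0 = B[1L, ], beta = B[-1L, , drop = FALSE],
       classes = classes)
}

predict_linear_onehot <- function(state, newdata) {
  scores <- sweep(newdata %*% state$beta, 2L, state$beta0, "+")
  state$classes[max.col(scores, ties.method = "first")]
}

# ---- PCA projection + one-vs-rest SVM --------------------------------------

#' Fit a PCA projection retaining a variance fraction
#'
#' Principal components are fitted on the supplied (training) rows only; the
#' returned projection retains the smallest number of components whose
#' cumulative explained variance reaches `variance_fraction`, and can be
#' reused on held-out rows.
#'
#' @param x numeric matrix (samples x features).
#' @param variance_fraction target cumulative variance fraction in (0, 1].
#' @return List with `rotation`, `center`, `ncomp`, `scores` (projected
#'   training rows), and `explained` (per-component variance fractions).
#' @export
apply_pca <- function(x, variance_fraction = 0.95) {
  if (inherits(x, "expr_matrix")) x <- x$values
  if (!is.numeric(variance_fraction) || variance_fraction <= 0 || variance_fraction > 1) {
    stop("`variance_fraction` must be in (0, 1]", call. = FALSE)
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  v <- pc$sdev^2
  frac <- v / sum(v)
  keep <- v > max(v) * 1e-12  # drop numerically-zero components
  cum <- cumsum(frac)
  ncomp <- which(cum >= variance_fraction - 1e-12)[1L]
  if (is.na(ncomp)) ncomp <- sum(keep)
  ncomp <- min(max(ncomp, 1L), sum(keep))
  list(rotation = pc$rotation[, seq_len(ncomp), drop = FALSE],
       center = pc$center, ncomp = ncomp,
       scores = pc$x[, seq_len(ncomp), drop = FALSE],
       explained = frac)
}

project_pca <- function(proj, newdata) {
  sweep(newdata, 2L, proj$center, "-") %*% proj$rotation
}

fit_svm_pca <- function(x, y, hp) {
  proj <- apply_pca(x, hp$variance_fraction)
  z <- proj$scores
  classes <- levels(y)
  machines <- lapply(classes, function(cl) {
    yy <- factor(ifelse(y == cl, cl, ".rest"), levels = c(cl, ".rest"))
    args <- list(x = z, y = yy, kernel = hp$kernel, cost = hp$cost,
                 scale = FALSE)
    if (!is.null(hp$gamma)) args$gamma <- hp$gamma
    do.call(e1071::svm, args)
  })
  list(proj = proj, machines = machines, classes = classes)
}

predict_svm_pca <- function(state, newdata) {
  z <- project_pca(state$proj, newdata)
  dec <- vapply(seq_along(state$machines), function(j) {
    dv <- attr(predict(state$machines[[j]], z, decision.values = TRUE),
               "decision.values")
    # libsvm orients the decision value by order of appearance in the
    # training data; the column name records which class is positive
    sgn <- if (startsWith(colnames(dv)[1L], ".rest/")) -1 else 1
    sgn * as.numeric(dv)
  }, numeric(nrow(z)))
  dec <- matrix(dec, nrow = nrow(z))  # guard n = 1
  state$classes[max.col(dec, ties.method = "first")]
}
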