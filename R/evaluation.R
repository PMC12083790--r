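#' Stratified train/test split plan
#'
#' Deterministic per seed. Stratified (default) allocates
#' `round(train_fraction * n_j)` training samples per class, clamped so every
#' class keeps at least one sample on each side.
#'
#' @param labels factor of class labels (or an [expression_matrix()]).
#' @param train_fraction fraction of samples assigned to training, in (0, 1).
#'   Default 0.6.
#' @param seed integer seed.
#' @param stratified preserve class proportions. Default `TRUE`.
#' @return An object of class `split_plan`: list with `train`, `test`
#'   (disjoint integer index vectors covering all samples), `seed`,
#'   `stratified`, `train_fraction`.
#' @export
make_split <- function(labels, train_fraction = 0.6, seed = 42L,
                       stratified = TRUE) {
  if (inherits(labels, "expr_matrix")) labels <- labels$labels
  labels <- as.factor(labels)
  if (!is.numeric(train_fraction) || train_fraction <= 0 || train_fraction >= 1) {
    stop("`train_fraction` must be in (0, 1)", call. = FALSE)
  }
  n <- length(labels)
  set.seed(seed)
  if (stratified) {
    counts <- table(labels)
    if (any(counts < 2L)) {
      stop(sprintf("class '%s' has fewer than 2 samples; cannot stratify",
                   names(counts)[counts < 2L][1L]), call. = FALSE)
    }
    train <- integer(0)
    for (lv in levels(labels)) {
      idx <- which(labels == lv)
      n_tr <- round(train_fraction * length(idx))
      n_tr <- min(max(n_tr, 1L), length(idx) - 1L)
      train <- c(train, sample(idx, n_tr))
    }
    train <- sort(train)
  } else {
    n_tr <- min(max(round(train_fraction * n), 1L), n - 1L)
    train <- sort(sample.int(n, n_tr))
  }
  structure(list(train = train, test = setdiff(seq_len(n), train),
                 seed = as.integer(seed), stratified = stratified,
                 train_fraction = train_fraction),
            class = "split_plan")
}

#' Stratified k-fold partition
#'
#' Assigns every sample to exactly one of `K` test folds. Under
#' stratification each class is spread evenly over folds; leftover samples
#' go to the currently smallest folds, which keeps overall fold sizes within
#' one of each other.
#'
#' @inheritParams make_split
#' @param K number of folds (>= 2).
#' @return A `split_plan` with element `fold`: integer vector in `1..K`, one
#'   entry per sample.
#' @export
kfold <- function(labels, K = 5L, seed = 42L, stratified = TRUE) {
  if (inherits(labels, "expr_matrix")) labels <- labels$labels
  labels <- as.factor(labels)
  K <- as.integer(K)
  n <- length(labels)
  if (K < 2L || K > n) stop("`K` must be between 2 and the sample count", call. = FALSE)
  set.seed(seed)
  fold <- integer(n)
  if (stratified) {
    counts <- table(labels)
    short <- counts < K
    if (any(short)) {
      stop(sprintf("class '%s' has %d samples, fewer than K = %d folds",
                   names(counts)[short][1L], counts[short][1L], K), call. = FALSE)
    }
    totals <- integer(K)
    for (lv in levels(labels)) {
      idx <- sample(which(labels == lv))
      base <- length(idx) %/% K
      extra <- length(idx) %% K
      alloc <- rep(base, K)
      if (extra > 0L) {
        # give leftovers to the currently smallest folds (ties by index)
        recv <- order(totals, seq_len(K))[seq_len(extra)]
        alloc[recv] <- alloc[recv] + 1L
      }
      fold[idx] <- rep(seq_len(K), times = alloc)
      totals <- totals + alloc
    }
  } else {
    fold <- sample(rep(seq_len(K), length.out = n))
  }
  structure(list(fold = fold, K = K, seed = as.integer(seed),
                 stratified = stratified),
            class = "split_plan")
}

#' Confusion matrix and multiclass metrics
#'
#' Builds the c x c confusion matrix (rows = true class, columns =
#' predicted) and the one-vs-rest TP/FP/FN/TN counts per class, from which
#' accuracy, precision `TP/(TP+FP)`, recall `TP/(TP+FN)`, F1
#' `2PR/(P+R)`, and specificity `TN/(TN+FP)` are computed. Per-class metrics
#' with a zero denominator are defined as 0. Aggregation over classes uses
#' the configured averaging; accuracy is always the fraction of correct
#' predictions (the confusion-matrix trace over its total).
#'
#' @param truth true labels (factor or character).
#' @param predicted predicted labels, same length.
#' @param levels class level order; defaults to the union of factor levels.
#' @param averaging `"weighted"` (by class support; default), `"macro"`, or
#'   `"micro"`.
#' @return An object of class `evaluation_report`: list with `confusion`,
#'   `accuracy`, `precision`, `recall`, `f1`, `specificity`, `per_class`
#'   (data frame), `averaging`, `n`.
#' @export
#' @examples
#' truth <- c("a", "a", "a", "a", "b", "b", "b", "b", "b", "b")
#' pred  <- c("a", "a", "a", "b", "a", "a", "b", "b", "b", "b")
#' evaluate_predictions(truth, pred)
evaluate_predictions <- function(truth, predicted, levels = NULL,
                                 averaging = c("weighted", "macro", "micro")) {
  averaging <- match.arg(averaging)
  if (is.null(levels)) {
    levels <- if (is.factor(truth)) base::levels(truth) else
      sort(unique(c(as.character(truth), as.character(predicted))))
  }
  truth_c <- as.character(truth)
  pred_c <- as.character(predicted)
  if (length(truth_c) != length(pred_c)) {
    stop("label vectors differ in length", call. = FALSE)
  }
  bad <- setdiff(unique(c(truth_c, pred_c)), levels)
  if (length(bad)) {
    stop(sprintf("label(s) outside the class set: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  tf <- factor(truth_c, levels = levels)
  pf <- factor(pred_c, levels = levels)
  confusion <- table(truth = tf, predicted = pf)
  n <- sum(confusion)
  tp <- diag(confusion)
  fp <- colSums(confusion) - tp
  fn <- rowSums(confusion) - tp
  tn <- n - tp - fp - fn
  safe_div <- function(num, den) ifelse(den > 0, num / den, 0)
  prec <- safe_div(tp, tp + fp)
  rec <- safe_div(tp, tp + fn)
  f1 <- safe_div(2 * prec * rec, prec + rec)
  spec <- safe_div(tn, tn + fp)
  support <- rowSums(confusion)
  agg <- function(v) {
    switch(averaging,
           weighted = sum(v * support) / n,
           macro = mean(v),
           micro = NA_real_)  # filled below from pooled counts
  }
  if (averaging == "micro") {
    p_agg <- safe_div(sum(tp), sum(tp) + sum(fp))
    r_agg <- safe_div(sum(tp), sum(tp) + sum(fn))
    f_agg <- safe_div(2 * p_agg * r_agg, p_agg + r_agg)
    s_agg <- safe_div(sum(tn), sum(tn) + sum(fp))
  } else {
    p_agg <- agg(prec); r_agg <- agg(rec); f_agg <- agg(f1); s_agg <- agg(spec)
  }
  structure(list(
    confusion = unclass(confusion),
    accuracy = sum(tp) / n,
    precision = p_agg, recall = r_agg, f1 = f_agg, specificity = s_agg,
    per_class = data.frame(class = levels, support = as.integer(support),
                           tp = as.integer(tp), fp = as.integer(fp),
                           fn = as.integer(fn), tn = as.integer(tn),
                           precision = as.numeric(prec),
                           recall = as.numeric(rec), f1 = as.numeric(f1),
                           specificity = as.numeric(spec),
                           row.names = NULL),
    averaging = averaging, n = as.integer(n)),
    class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("evaluation of %d samples (%s averaging)\n", x$n, x$averaging))
  cat(sprintf("  accuracy  %.4f\n  precision %.4f\n  recall    %.4f\n  f1        %.4f\n",
              x$accuracy, x$precision, x$recall, x$f1))
  cat("confusion matrix (rows = true):\n")
  print(x$confusion)
  invisible(x)
}
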