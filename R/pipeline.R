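#' Run the full selection + classification pipeline
#'
#' Executes the whole workflow on one expression matrix: stratified
#' train/test split, separability-based gene selection on the training rows,
#' per-gene standardization of the selected genes (fitted on training rows),
#' training of each configured classifier, prediction on the held-out rows,
#' and confusion-matrix evaluation. Optionally also runs a stratified k-fold
#' cross-validation in which selection and standardization are re-fitted
#' inside every fold. All randomness derives from `seed` through fixed
#' per-stage offsets, so a rerun with the same arguments is bit-identical.
#'
#' @param em an [expression_matrix()].
#' @param k number of genes to select. Default 25.
#' @param models character vector of classifier kinds (see [model_config()])
#'   and/or a list of ready-made `model_config` objects.
#' @param train_fraction training fraction for the holdout split. Default 0.6.
#' @param seed global integer seed. Default 42.
#' @param stratified stratify the split and folds. Default `TRUE`.
#' @param standardize z-score the selected genes before classification
#'   (parameters fitted on training rows). Default `TRUE`.
#' @param sd_convention `"population"` or `"sample"`.
#' @param abs_transform absolute value after standardization. Default `FALSE`.
#' @param standardize_before_select compute selection scores on the
#'   standardized matrix instead of the matrix as loaded. Default `FALSE`
#'   (see the methods vignette).
#' @param select_on_all fit the selector on all samples instead of training
#'   rows only (fidelity option). Default `FALSE`.
#' @param fit_on_all fit standardization on all samples instead of training
#'   rows only (fidelity option). Default `FALSE`.
#' @param direction score sort direction. Default `"descending"`.
#' @param kfold_k also run K-fold cross-validation with this K (e.g. 5);
#'   `NULL` (default) skips it.
#' @param averaging metric averaging mode. Default `"weighted"`.
#' @param out_dir if non-`NULL`, reports, the summary table, the selection
#'   table, and the resolved configuration are written under this directory
#'   (see [write_reports()]).
#' @param verbose log one line per stage. Default `TRUE`.
#' @return An object of class `pipeline_result`: list with `reports` (one
#'   per model: config echo, metrics, confusion, optional k-fold accuracy),
#'   `summary` (data frame mirroring the metric table), `selection`,
#'   `split`, and `config` (the fully-resolved configuration).
#' @export
run_pipeline <- function(em, k = 25L,
                         models = c("random_forest", "decision_tree",
                                    "linear_onehot", "svm_pca", "lstm"),
                         train_fraction = 0.6, seed = 42L, stratified = TRUE,
                         standardize = TRUE,
                         sd_convention = c("population", "sample"),
                         abs_transform = FALSE,
                         standardize_before_select = FALSE,
                         select_on_all = FALSE, fit_on_all = FALSE,
                         direction = c("descending", "ascending"),
                         kfold_k = NULL,
                         averaging = c("weighted", "macro", "micro"),
                         out_dir = NULL, verbose = TRUE) {
  stopifnot(inherits(em, "expr_matrix"))
  sd_convention <- match.arg(sd_convention)
  direction <- match.arg(direction)
  averaging <- match.arg(averaging)
  seed <- as.integer(seed)
  say <- function(fmt, ...) if (verbose) message(sprintf(fmt, ...))
  t0 <- proc.time()[["elapsed"]]
  elapsed <- function() sprintf("%.2fs", proc.time()[["elapsed"]] - t0)

  configs <- lapply(seq_along(models), function(i) {
    m <- if (is.list(models)) models[[i]] else models[[i]]
    if (inherits(m, "model_config")) m else model_config(m, seed = seed + 100L + i)
  })
  names(configs) <- vapply(configs, `[[`, "", "kind")

  n <- nrow(em$values)
  say("[split] %d samples, train fraction %.2f (%s)", n, train_fraction, elapsed())
  split <- make_split(em$labels, train_fraction, seed = seed + 1L,
                      stratified = stratified)

  run_fold <- function(train_idx, test_idx, model_cfgs) {
    x <- em$values
    sel_rows <- if (select_on_all) seq_len(n) else train_idx
    x_sel_src <- x
    if (standardize_before_select) {
      std_all <- fit_standardizer(x[sel_rows, , drop = FALSE], sd_convention)
      x_sel_src <- apply_standardizer(std_all, x, abs_transform = abs_transform)
    }
    sel <- separability(x_sel_src[sel_rows, , drop = FALSE],
                        em$labels[sel_rows], k = k, direction = direction)
    sel$gene_ids <- em$gene_ids
    xs <- x[, sel$selected, drop = FALSE]
    if (standardize) {
      std_rows <- if (fit_on_all) seq_len(n) else train_idx
      std <- fit_standardizer(xs[std_rows, , drop = FALSE], sd_convention)
      xs <- apply_standardizer(std, xs, abs_transform = abs_transform)
    }
    preds <- lapply(model_cfgs, function(cfg) {
      fit <- fit_classifier(xs[train_idx, , drop = FALSE],
                            em$labels[train_idx], cfg)
      predict(fit, xs[test_idx, , drop = FALSE])
    })
    list(selection = sel, predictions = preds)
  }

  say("[select+fit] k = %d, %d model(s) (%s)", k, length(configs), elapsed())
  holdout <- run_fold(split$train, split$test, configs)

  kfold_acc <- NULL
  if (!is.null(kfold_k)) {
    say("[kfold] K = %d (%s)", kfold_k, elapsed())
    plan <- kfold(em$labels, K = kfold_k, seed = seed + 2L,
                  stratified = stratified)
    pooled <- lapply(configs, function(cfg) factor(rep(NA_character_, n),
                                                   levels = levels(em$labels)))
    for (f in seq_len(plan$K)) {
      te <- which(plan$fold == f)
      tr <- setdiff(seq_len(n), te)
      fold_out <- run_fold(tr, te, configs)
      for (nm in names(configs)) pooled[[nm]][te] <- fold_out$predictions[[nm]]
    }
    kfold_acc <- vapply(pooled, function(p) mean(p == em$labels), numeric(1))
  }

  resolved <- list(
    n_samples = n, n_genes = ncol(em$values),
    class_levels = levels(em$labels), k = as.integer(k),
    models = lapply(configs, function(cfg)
      list(kind = cfg$kind, seed = cfg$seed,
           hyperparameters = cfg$hyperparameters)),
    train_fraction = train_fraction, seed = seed, stratified = stratified,
    standardize = standardize, sd_convention = sd_convention,
    abs_transform = abs_transform,
    standardize_before_select = standardize_before_select,
    select_on_all = select_on_all, fit_on_all = fit_on_all,
    direction = direction, kfold_k = kfold_k, averaging = averaging
  )

  reports <- lapply(names(configs), function(nm) {
    ev <- evaluate_predictions(em$labels[split$test], holdout$predictions[[nm]],
                               levels = levels(em$labels), averaging = averaging)
    list(model = resolved$models[[nm]],
         evaluation_set = sprintf("holdout test (%d of %d samples)",
                                  length(split$test), n),
         metrics = list(accuracy = ev$accuracy, precision = ev$precision,
                        recall = ev$recall, f1 = ev$f1,
                        specificity = ev$specificity,
                        accuracy_kfold = if (is.null(kfold_acc)) NULL else
                          unname(kfold_acc[[nm]])),
         confusion = ev$confusion,
         per_class = ev$per_class,
         split = list(seed = split$seed, stratified = split$stratified,
                      train_fraction = split$train_fraction,
                      n_train = length(split$train),
                      n_test = length(split$test)),
         note = paste("precision is TP/(TP+FP); specificity TN/(TN+FP) is",
                      "reported separately"))
  })
  names(reports) <- names(configs)

  summary_df <- data.frame(
    model = names(reports),
    accuracy = vapply(reports, function(r) r$metrics$accuracy, numeric(1)),
    precision = vapply(reports, function(r) r$metrics$precision, numeric(1)),
    recall = vapply(reports, function(r) r$metrics$recall, numeric(1)),
    f1 = vapply(reports, function(r) r$metrics$f1, numeric(1)),
    row.names = NULL
  )
  if (!is.null(kfold_acc)) summary_df$accuracy_kfold <- as.numeric(kfold_acc)

  res <- structure(list(reports = reports, summary = summary_df,
                        selection = holdout$selection, split = split,
                        config = resolved),
                   class = "pipeline_result")
  if (!is.null(out_dir)) write_reports(res, out_dir)
  say("[done] %d report(s) (%s)", length(reports), elapsed())
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline result\n")
  df <- x$summary
  df[-1L] <- lapply(df[-1L], function(v) sprintf("%.4f", v))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Write pipeline reports to an output directory
#'
#' Creates the stable layout `reports/` (one JSON per model), `selections/`
#' (ranked selection table), `summary.csv` (the metric table), and
#' `resolved_config.json`. JSON is written at full precision and without
#' timestamps, so identical runs produce byte-identical files.
#'
#' @param result a `pipeline_result` from [run_pipeline()].
#' @param out_dir output directory, created if needed.
#' @return `out_dir`, invisibly.
#' @export
write_reports <- function(result, out_dir) {
  stopifnot(inherits(result, "pipeline_result"))
  dir.create(file.path(out_dir, "reports"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "selections"), showWarnings = FALSE)
  for (nm in names(result$reports)) {
    rep <- result$reports[[nm]]
    rep$confusion <- as.data.frame.matrix(rep$confusion)
    jsonlite::write_json(rep, file.path(out_dir, "reports", paste0(nm, ".json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  write_selection(result$selection,
                  file.path(out_dir, "selections", "selection.tsv"),
                  gene_ids = result$selection$gene_ids)
  utils::write.csv(result$summary, file.path(out_dir, "summary.csv"),
                   row.names = FALSE)
  jsonlite::write_json(result$config, file.path(out_dir, "resolved_config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
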