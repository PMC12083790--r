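#' Read an expression matrix from delimited text
#'
#' Reads a CuMiDa-style table: one row per sample, a sample-id column, a
#' class-label column (default `"type"`), and one numeric column per gene
#' probe. Row and gene-column order are preserved.
#'
#' @param path path to a delimited text file with a header row.
#' @param label_column name of the class-label column. Default `"type"`.
#' @param id_column name of the sample-id column; `NULL` takes the first
#'   non-label column. Default `"samples"` falls back to the first column when
#'   no column of that name exists.
#' @param sep field delimiter; `"auto"` (default) lets the reader sniff comma
#'   versus tab.
#' @param class_levels optional character vector fixing the class order; by
#'   default classes are ordered by first appearance in the file.
#' @param missing how to treat missing expression cells: `"error"` (default)
#'   rejects the file, `"impute"` replaces them with the gene mean.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, label_column = "type", id_column = "samples",
                            sep = "auto", class_levels = NULL,
                            missing = c("error", "impute")) {
  missing <- match.arg(missing)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  dt <- data.table::fread(path, sep = if (identical(sep, "auto")) "auto" else sep,
                          header = TRUE, data.table = FALSE,
                          colClasses = "character", na.strings = c("", "NA"))
  cols <- names(dt)
  if (!label_column %in% cols) {
    stop(sprintf("label column '%s' not found in %s", label_column, path),
         call. = FALSE)
  }
  if (!is.null(id_column) && !id_column %in% cols) {
    id_column <- setdiff(cols, label_column)[1L]
  }
  gene_cols <- setdiff(cols, c(label_column, id_column))
  if (!length(gene_cols)) stop("no gene columns found", call. = FALSE)

  n <- nrow(dt)
  values <- matrix(NA_real_, n, length(gene_cols),
                   dimnames = list(NULL, gene_cols))
  for (j in seq_along(gene_cols)) {
    col <- dt[[gene_cols[j]]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num) & !is.na(col))
    if (length(bad)) {
      stop(sprintf("non-numeric expression value '%s' at row %d, column '%s'",
                   col[bad[1L]], bad[1L], gene_cols[j]), call. = FALSE)
    }
    miss <- which(is.na(num))
    if (length(miss)) {
      if (missing == "error") {
        stop(sprintf("missing expression value at row %d, column '%s'",
                     miss[1L], gene_cols[j]), call. = FALSE)
      }
      num[miss] <- mean(num, na.rm = TRUE)
    }
    values[, j] <- num
  }
  sample_ids <- if (is.null(id_column)) paste0("sample_", seq_len(n)) else dt[[id_column]]
  expression_matrix(values, labels = dt[[label_column]],
                    sample_ids = sample_ids, gene_ids = gene_cols,
                    class_levels = class_levels)
}

#' Write an expression matrix as delimited text
#'
#' Inverse of [read_expression()]: writes the sample-id column, the label
#' column, then one column per gene, preserving order. Values are printed at
#' full double precision so a read-back reproduces the matrix.
#'
#' @param em an [expression_matrix()].
#' @param path output file path.
#' @param label_column header name for the class column. Default `"type"`.
#' @param id_column header name for the sample-id column. Default `"samples"`.
#' @param sep field delimiter. Default `","`.
#' @return `path`, invisibly.
#' @export
write_expression <- function(em, path, label_column = "type",
                             id_column = "samples", sep = ",") {
  stopifnot(inherits(em, "expr_matrix"))
  df <- data.frame(id = em$sample_ids, type = as.character(em$labels),
                   stringsAsFactors = FALSE, check.names = FALSE)
  names(df) <- c(id_column, label_column)
  vals <- as.data.frame(em$values, check.names = FALSE)
  # %.17g round-trips IEEE doubles through decimal text
  vals[] <- lapply(vals, function(v) sprintf("%.17g", v))
  out <- cbind(df, vals)
  data.table::fwrite(out, path, sep = sep, quote = FALSE)
  invisible(path)
}

#' Write a ranked feature selection to delimited text
#'
#' Writes one row per selected gene with its rank (1 = best), gene index,
#' gene id, and separability score at full precision, so that
#' [read_selection()] round-trips losslessly.
#'
#' @param result a `separability` object from [rank_and_select()] or
#'   [separability()].
#' @param path output file path.
#' @param gene_ids optional character vector of gene ids to annotate the
#'   indices with.
#' @param index_base base for the printed gene index, 0 or 1. Indices are
#'   held 1-based in R; printed base is a reporting choice. Default 1.
#' @return `path`, invisibly.
#' @export
write_selection <- function(result, path, gene_ids = NULL, index_base = 1L) {
  stopifnot(inherits(result, "separability"))
  sel <- result$selected
  if (!length(sel)) stop("empty selection", call. = FALSE)
  stopifnot(index_base %in% c(0L, 1L))
  df <- data.frame(
    rank = seq_along(sel),
    gene_index = sel - 1L + as.integer(index_base),
    gene_id = if (is.null(gene_ids)) paste0("gene_", sel) else gene_ids[sel],
    score = sprintf("%.17g", result$scores[sel]),
    stringsAsFactors = FALSE
  )
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read a ranked feature selection written by [write_selection()]
#'
#' @param path path to a selection table.
#' @param index_base base the file's `gene_index` column was printed in.
#' @return A data frame with columns `rank`, `gene_index` (1-based integer),
#'   `gene_id`, `score`.
#' @export
read_selection <- function(path, index_base = 1L) {
  df <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  df$gene_index <- as.integer(df$gene_index) + 1L - as.integer(index_base)
  df$score <- as.numeric(df$score)
  df[order(df$rank), , drop = FALSE]
}
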