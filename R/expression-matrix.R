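#' Samples-by-genes expression matrix with class labels
#'
#' The central data container: an `n x m` numeric matrix of expression
#' intensities (rows are samples, columns are gene probes) together with
#' sample identifiers, gene identifiers, and one categorical class label per
#' sample. Class labels are stored as a factor whose level order defines the
#' integer class codes `1..c` used throughout the package (the class map).
#'
#' @param values numeric `n x m` matrix of expression intensities.
#' @param labels character or factor of length `n`; the per-sample class.
#' @param sample_ids character of length `n`; defaults to the row names of
#'   `values`, or `sample_1..n` when those are absent.
#' @param gene_ids character of length `m`; defaults to the column names of
#'   `values`, or `gene_1..m` when those are absent.
#' @param class_levels optional character vector fixing the class order
#'   (the class map). When absent the order of first appearance in `labels`
#'   is used.
#'
#' @return An object of class `expr_matrix`: a list with elements `values`,
#'   `sample_ids`, `gene_ids`, and `labels` (a factor; its levels are the
#'   class map).
#' @export
#' @examples
#' x <- matrix(rnorm(12), 3, 4)
#' em <- expression_matrix(x, labels = c("A", "A", "B"))
#' em
expression_matrix <- function(values, labels, sample_ids = NULL,
                              gene_ids = NULL, class_levels = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (samples x genes)", call. = FALSE)
  }
  n <- nrow(values)
  m <- ncol(values)
  if (n < 2L) stop("an expression matrix needs at least 2 samples", call. = FALSE)
  if (m < 1L) stop("an expression matrix needs at least 1 gene", call. = FALSE)
  if (anyNA(values) || any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite expression value at sample %d, gene %d",
                 bad[["row"]], bad[["col"]]), call. = FALSE)
  }
  if (is.null(sample_ids)) {
    sample_ids <- rownames(values)
    if (is.null(sample_ids)) sample_ids <- paste0("sample_", seq_len(n))
  }
  if (is.null(gene_ids)) {
    gene_ids <- colnames(values)
    if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(m))
  }
  sample_ids <- as.character(sample_ids)
  gene_ids <- as.character(gene_ids)
  if (length(sample_ids) != n) stop("`sample_ids` must have one entry per sample", call. = FALSE)
  if (length(gene_ids) != m) stop("`gene_ids` must have one entry per gene", call. = FALSE)
  if (anyDuplicated(gene_ids)) {
    stop(sprintf("duplicate gene id: '%s'", gene_ids[duplicated(gene_ids)][1L]),
         call. = FALSE)
  }
  if (length(labels) != n) {
    stop("`labels` must have exactly one entry per sample", call. = FALSE)
  }
  if (is.null(class_levels)) {
    class_levels <- if (is.factor(labels)) levels(labels) else unique(as.character(labels))
  }
  lab_chr <- as.character(labels)
  unknown <- setdiff(unique(lab_chr), class_levels)
  if (length(unknown)) {
    stop(sprintf("label(s) outside the declared class set: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  labels <- factor(lab_chr, levels = class_levels)
  rownames(values) <- sample_ids
  colnames(values) <- gene_ids
  structure(
    list(values = values, sample_ids = sample_ids,
         gene_ids = gene_ids, labels = labels),
    class = "expr_matrix"
  )
}

#' @export
print.expr_matrix <- function(x, ...) {
  counts <- table(x$labels)
  cat(sprintf("expression matrix: %d samples x %d genes, %d classes\n",
              nrow(x$values), ncol(x$values), nlevels(x$labels)))
  cat("class counts:\n")
  print(counts)
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Subset an expression matrix by samples and/or genes
#'
#' Row (sample) and column (gene) subsetting that keeps identifiers and
#' labels aligned with the values matrix. Factor levels of the labels (the
#' class map) are preserved even when a class drops out of the subset.
#'
#' @param x an [expression_matrix()] object.
#' @param i sample index vector (integer, logical, or sample ids).
#' @param j gene index vector (integer, logical, or gene ids).
#' @param ... ignored.
#' @return An `expr_matrix` (or plain matrix slice if fewer than 2 samples
#'   would remain, which errors).
#' @export
`[.expr_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$values))
  if (missing(j)) j <- seq_len(ncol(x$values))
  if (is.character(i)) i <- match(i, x$sample_ids)
  if (is.character(j)) j <- match(j, x$gene_ids)
  expression_matrix(x$values[i, j, drop = FALSE],
                    labels = x$labels[i],
                    sample_ids = x$sample_ids[i],
                    gene_ids = x$gene_ids[j],
                    class_levels = levels(x$labels))
}

#' Class map of an expression matrix
#'
#' Returns the ordered class-name-to-integer-code mapping (codes `1..c`).
#'
#' @param em an [expression_matrix()] object.
#' @return Named integer vector: names are class names, values their codes.
#' @export
class_map <- function(em) {
  stopifnot(inherits(em, "expr_matrix"))
  stats::setNames(seq_len(nlevels(em$labels)), levels(em$labels))
}

# Internal sanity check used by selection/classification entry points:
# at least two distinct classes actually present, none empty among present.
check_two_classes <- function(labels) {
  present <- unique(as.character(labels))
  if (length(present) < 2L) {
    stop("at least 2 distinct classes are required", call. = FALSE)
  }
  invisible(TRUE)
}
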