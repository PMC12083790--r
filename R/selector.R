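#' Per-class means of one feature
#'
#' @param values numeric vector, one value per sample, for a single gene.
#' @param labels factor (or coercible) of class labels, same length.
#' @return Numeric vector of per-class means, one per class level, named.
#' @export
class_means <- function(values, labels) {
  labels <- as.factor(labels)
  stopifnot(length(values) == length(labels))
  counts <- table(labels)
  if (any(counts == 0L)) {
    stop(sprintf("empty class: %s",
                 paste(names(counts)[counts == 0L], collapse = ", ")),
         call. = FALSE)
  }
  sums <- rowsum(values, labels)[, 1L]
  sums / as.numeric(counts)
}

#' Absolute deviations of feature values from their own class mean
#'
#' For sample k in class j, returns `|a_k - m_j|`: the within-class absolute
#' deviation used as the elementary separability quantity.
#'
#' @inheritParams class_means
#' @param means optional precomputed per-class means (as from
#'   [class_means()]); computed when absent.
#' @return Numeric vector, one deviation per sample.
#' @export
abs_deviations <- function(values, labels, means = NULL) {
  labels <- as.factor(labels)
  if (is.null(means)) means <- class_means(values, labels)
  abs(values - unname(means)[as.integer(labels)])
}

#' Class-separability score of one feature
#'
#' The ranking statistic: for each class take the maximum within-class
#' absolute deviation of the feature from that class's mean, then take the
#' minimum of those maxima over the classes. The score is non-negative,
#' absolutely homogeneous (`d(a*x) = |a| d(x)`), invariant to per-class
#' shifts, and zero for any feature constant within every class.
#'
#' @inheritParams class_means
#' @return A single non-negative number.
#' @export
#' @examples
#' score_feature(c(1, 3, 10, 10), c("a", "a", "b", "b"))  # min(1, 0) = 0
score_feature <- function(values, labels) {
  labels <- as.factor(labels)
  b <- abs_deviations(values, labels)
  per_class_max <- vapply(split(b, labels), max, numeric(1))
  min(per_class_max)
}

#' Class-separability scores for every gene of a matrix
#'
#' Vectorized, column-independent application of [score_feature()] to every
#' gene of a samples-by-genes matrix.
#'
#' @param x numeric matrix (samples x genes) or [expression_matrix()].
#' @param labels class labels (ignored when `x` is an `expr_matrix`, which
#'   carries its own).
#' @return Numeric vector of scores, one per gene, named by gene id when
#'   available.
#' @export
score_all <- function(x, labels = NULL) {
  if (inherits(x, "expr_matrix")) {
    labels <- x$labels
    x <- x$values
  }
  labels <- as.factor(labels)
  stopifnot(is.matrix(x), nrow(x) == length(labels))
  check_two_classes(labels)
  counts <- table(labels)
  present <- names(counts)[counts > 0L]
  if (length(present) < nlevels(labels)) labels <- droplevels(labels)
  counts <- table(labels)
  # class means: rowsum accumulates within class in row order, matching a
  # sequential per-class sum exactly in double precision
  M <- rowsum(x, labels) / as.numeric(counts)
  B <- abs(x - M[as.integer(labels), , drop = FALSE])
  scores <- rep(Inf, ncol(x))
  for (lv in levels(labels)) {
    rows <- which(labels == lv)
    cmax <- B[rows[1L], ]
    for (r in rows[-1L]) cmax <- pmax(cmax, B[r, ])
    scores <- pmin(scores, cmax)
  }
  names(scores) <- colnames(x)
  scores
}

#' Rank scored genes and select the top k
#'
#' Sorts gene scores in the configured direction (descending by default,
#' i.e. the largest score ranks first) with ties broken by ascending gene
#' index, and selects the first `min(k, m)` genes.
#'
#' @param scores numeric score vector, one entry per gene.
#' @param k number of genes to select. Default 25.
#' @param direction `"descending"` (default) or `"ascending"`.
#' @return An object of class `separability`: list with `scores`, `ranking`
#'   (a permutation of `1..m`), `selected` (first `min(k, m)` of the
#'   ranking), `k`, and `direction`.
#' @export
rank_and_select <- function(scores, k = 25L, direction = c("descending", "ascending")) {
  direction <- match.arg(direction)
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("`k` must be a positive integer", call. = FALSE)
  m <- length(scores)
  key <- if (direction == "descending") -scores else scores
  ranking <- order(key, seq_len(m), method = "radix")
  structure(
    list(scores = scores, ranking = ranking,
         selected = ranking[seq_len(min(k, m))],
         k = k, direction = direction),
    class = "separability"
  )
}

#' Score, rank, and select genes by class separability
#'
#' One-call front end for the filter: computes the per-gene separability
#' score of every gene and returns the ranked top-`k` selection.
#'
#' @inheritParams score_all
#' @inheritParams rank_and_select
#' @return A `separability` object (see [rank_and_select()]) with an
#'   additional `gene_ids` element when `x` carries gene ids.
#' @export
#' @examples
#' sim <- simulate_expression(sim_config(p = 200, seed = 1))
#' sel <- separability(sim$matrix, k = 20)
#' sel
separability <- function(x, labels = NULL, k = 25L,
                         direction = c("descending", "ascending")) {
  gene_ids <- if (inherits(x, "expr_matrix")) x$gene_ids else colnames(x)
  scores <- score_all(x, labels)
  res <- rank_and_select(scores, k = k, direction = direction)
  res$gene_ids <- gene_ids
  res
}

#' @export
print.separability <- function(x, ...) {
  cat(sprintf("separability selection: %d of %d genes (%s scores)\n",
              length(x$selected), length(x$scores), x$direction))
  ids <- if (!is.null(x$gene_ids)) x$gene_ids[x$selected] else paste0("gene_", x$selected)
  top <- utils::head(data.frame(rank = seq_along(x$selected),
                                gene_index = x$selected, gene_id = ids,
                                score = x$scores[x$selected],
                                row.names = NULL), 10L)
  print(top)
  if (length(x$selected) > 10L) cat(sprintf("... and %d more\n", length(x$selected) - 10L))
  invisible(x)
}

#' @export
plot.separability <- function(x, ...) {
  ord <- x$scores[x$ranking]
  graphics::plot(seq_along(ord), ord, type = "l", log = "",
                 xlab = "rank", ylab = "separability score",
                 main = "ranked separability scores", ...)
  kk <- length(x$selected)
  graphics::abline(v = kk + 0.5, lty = 2)
  graphics::points(seq_len(kk), ord[seq_len(kk)], pch = 16, cex = 0.6)
  invisible(x)
}
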