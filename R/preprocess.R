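#' Fit per-gene standardization parameters
#'
#' Computes per-gene centers (means) and scales (standard deviations) from a
#' reference set of samples, typically the training rows only, so the same
#' transform can be applied to held-out samples without leakage.
#'
#' @param x numeric matrix (samples x genes) or [expression_matrix()].
#' @param sd_convention `"population"` (divide by n; default) or `"sample"`
#'   (divide by n - 1).
#' @return An object of class `standardizer`: list with `center`, `scale`,
#'   and `sd_convention`. Zero-variance genes get scale 0 and are mapped to
#'   all-zeros on application.
#' @export
fit_standardizer <- function(x, sd_convention = c("population", "sample")) {
  sd_convention <- match.arg(sd_convention)
  if (inherits(x, "expr_matrix")) x <- x$values
  stopifnot(is.matrix(x), is.numeric(x))
  if (any(!is.finite(x))) {
    bad <- which(!is.finite(x), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite value in gene column %d", bad[["col"]]), call. = FALSE)
  }
  n <- nrow(x)
  ctr <- colMeans(x)
  dev2 <- colMeans(sweep(x, 2L, ctr, "-")^2)
  scl <- if (sd_convention == "population") sqrt(dev2) else sqrt(dev2 * n / (n - 1))
  structure(list(center = ctr, scale = scl, sd_convention = sd_convention),
            class = "standardizer")
}

#' Apply fitted standardization parameters
#'
#' @param std a `standardizer` from [fit_standardizer()].
#' @param x matrix or [expression_matrix()] with the same gene count the
#'   standardizer was fitted on.
#' @param abs_transform take absolute values after standardizing (off by
#'   default; see the methods vignette for why).
#' @return Same container type as `x`, transformed.
#' @export
apply_standardizer <- function(std, x, abs_transform = FALSE) {
  stopifnot(inherits(std, "standardizer"))
  em <- NULL
  if (inherits(x, "expr_matrix")) {
    em <- x
    x <- x$values
  }
  if (ncol(x) != length(std$center)) {
    stop(sprintf("standardizer was fitted on %d genes, got %d",
                 length(std$center), ncol(x)), call. = FALSE)
  }
  z <- sweep(x, 2L, std$center, "-")
  scl <- std$scale
  nz <- scl > 0
  z[, nz] <- sweep(z[, nz, drop = FALSE], 2L, scl[nz], "/")
  z[, !nz] <- 0  # constant genes carry no information; mapped to zero
  if (abs_transform) z <- abs(z)
  if (is.null(em)) return(z)
  expression_matrix(z, labels = em$labels, sample_ids = em$sample_ids,
                    gene_ids = em$gene_ids, class_levels = levels(em$labels))
}

#' Standardize an expression matrix to zero mean and unit standard deviation
#'
#' Convenience wrapper fitting on, and applying to, the same data (the
#' `fit-on-all` mode). In a train/test pipeline prefer [fit_standardizer()]
#' on training rows followed by [apply_standardizer()] on both sets.
#'
#' @inheritParams fit_standardizer
#' @inheritParams apply_standardizer
#' @return Same container type as `x`, with per-gene mean 0 and sd 1
#'   (constant genes map to all-zeros).
#' @export
standardize <- function(x, sd_convention = c("population", "sample"),
                        abs_transform = FALSE) {
  std <- fit_standardizer(x, sd_convention)
  apply_standardizer(std, x, abs_transform = abs_transform)
}
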