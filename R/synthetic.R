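#' Configuration for the synthetic expression simulator
#'
#' Defaults mirror the leukemia microarray study design the package targets:
#' 64 samples in five unbalanced classes (8/10/26/10/10), a few thousand
#' genes, and a small planted set of informative genes whose class means are
#' separated and whose within-class spread exceeds the background noise.
#'
#' @param n_per_class integer vector of class sizes. Default `c(8, 10, 26, 10, 10)`.
#' @param p total number of genes. Default 2000.
#' @param n_informative number of planted informative genes. Default 20.
#' @param delta separation between adjacent class means of an informative
#'   gene (class j has mean `j * delta`). Default 5.
#' @param sd_informative within-class standard deviation of informative
#'   genes. Default 1.
#' @param sd_background standard deviation of background genes (mean 0,
#'   class-independent). Default 0.1.
#' @param class_names names for the classes; defaults to the five leukemia
#'   study groups.
#' @param seed integer seed making the draw reproducible.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_per_class = c(8L, 10L, 26L, 10L, 10L),
                       p = 2000L, n_informative = 20L,
                       delta = 5, sd_informative = 1, sd_background = 0.1,
                       class_names = NULL, seed = 1L) {
  n_per_class <- as.integer(n_per_class)
  p <- as.integer(p)
  n_informative <- as.integer(n_informative)
  if (any(n_per_class < 1L)) stop("class sizes must be positive", call. = FALSE)
  if (length(n_per_class) < 2L) stop("need at least 2 classes", call. = FALSE)
  if (p < 1L || n_informative < 0L || n_informative > p) {
    stop("need 0 <= n_informative <= p and p >= 1", call. = FALSE)
  }
  if (sd_informative <= 0 || sd_background <= 0) {
    stop("standard deviations must be positive", call. = FALSE)
  }
  if (is.null(class_names)) {
    class_names <- c("Bone_Marrow_CD34", "Bone_Marrow", "AML", "PB", "PBSC_CD34")
    if (length(n_per_class) != 5L) {
      class_names <- paste0("Class_", seq_along(n_per_class))
    }
  }
  stopifnot(length(class_names) == length(n_per_class))
  structure(list(n_per_class = n_per_class, p = p,
                 n_informative = n_informative, delta = delta,
                 sd_informative = sd_informative,
                 sd_background = sd_background,
                 class_names = class_names, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate an expression matrix with planted informative genes
#'
#' Background genes are drawn `Normal(0, sd_background^2)` independently of
#' class; each planted informative gene is drawn, for a sample of class `j`,
#' from `Normal(j * delta, sd_informative^2)`. Planted gene positions are
#' drawn without replacement and returned as ground truth. The draw is fully
#' determined by `config$seed`.
#'
#' @param config a [sim_config()].
#' @return A list with elements `matrix` (an [expression_matrix()]) and
#'   `informative` (sorted integer vector of planted gene indices).
#' @export
#' @examples
#' sim <- simulate_expression(sim_config(seed = 7))
#' dim(sim$matrix)
#' length(sim$informative)
simulate_expression <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- sum(config$n_per_class)
  cls <- rep(config$class_names, times = config$n_per_class)
  informative <- sort(sample.int(config$p, config$n_informative))
  values <- matrix(stats::rnorm(n * config$p, mean = 0, sd = config$sd_background),
                   nrow = n, ncol = config$p)
  if (config$n_informative > 0L) {
    cls_idx <- rep(seq_along(config$n_per_class), times = config$n_per_class)
    mu <- cls_idx * config$delta  # per-sample mean for every informative gene
    values[, informative] <- stats::rnorm(n * config$n_informative,
                                          mean = mu, sd = config$sd_informative)
  }
  em <- expression_matrix(values, labels = cls,
                          sample_ids = sprintf("sim_%03d", seq_len(n)),
                          gene_ids = sprintf("g%05d", seq_len(config$p)),
                          class_levels = config$class_names)
  list(matrix = em, informative = informative, config = config)
}

#' Fixed 6 x 4 two-class fixture with hand-computed scores
#'
#' A hard-coded miniature expression matrix whose class means, within-class
#' absolute deviations, per-class maxima, and separability scores are worked
#' out by hand in the test suite and used as the anchor oracle:
#'
#' \preformatted{
#'  gene  class A values  mean  max|dev|   class B values  mean  max|dev|   score
#'  g1    1, 2, 3          2       1       4,  6,  8         6      2         1
#'  g2    0, 4, 8          4       4       10, 13, 10       11      2         2
#'  g3    5, 5, 5          5       0       0, 100, 50       50     50         0
#'  g4    2, 6, 4          4       2       -3, 0,  3         0      3         2
#' }
#'
#' Descending ranking with index tie-break: g2, g4, g1, g3.
#'
#' @return An [expression_matrix()] with 6 samples, 4 genes, classes A/B.
#' @export
fixture_small <- function() {
  values <- cbind(
    g1 = c(1, 2, 3, 4, 6, 8),
    g2 = c(0, 4, 8, 10, 13, 10),
    g3 = c(5, 5, 5, 0, 100, 50),
    g4 = c(2, 6, 4, -3, 0, 3)
  )
  expression_matrix(values,
                    labels = c("A", "A", "A", "B", "B", "B"),
                    sample_ids = paste0("s", 1:6),
                    class_levels = c("A", "B"))
}
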