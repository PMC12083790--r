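# Independent naive oracle for the separability score, written as a plain
# triple loop straight from the definition: per gene, per class, compute the
# class mean (summing values in row order, as the vectorized path does),
# take the maximum absolute deviation within the class, then the minimum of
# those maxima over classes.
naive_separability <- function(x, labels) {
  labels <- as.factor(labels)
  out <- numeric(ncol(x))
  for (g in seq_len(ncol(x))) {
    class_maxima <- numeric(0)
    for (lv in levels(labels)) {
      vals <- x[labels == lv, g]
      mu <- 0
      for (v in vals) mu <- mu + v  # sequential double-precision accumulation
      mu <- mu / length(vals)
      mx <- 0
      for (v in vals) mx <- max(mx, abs(v - mu))
      class_maxima <- c(class_maxima, mx)
    }
    d <- class_maxima[1L]
    for (ck in class_maxima[-1L]) d <- min(d, ck)
    out[g] <- d
  }
  out
}

# Random labelled instance with every class guaranteed non-empty.
random_instance <- function(n_max = 20L, m_max = 50L, c_max = 4L) {
  c_ <- sample(2:c_max, 1L)
  n <- sample(max(c_, 4L):n_max, 1L)
  m <- sample(1:m_max, 1L)
  labels <- factor(c(seq_len(c_), sample(seq_len(c_), n - c_, replace = TRUE)))
  x <- matrix(rnorm(n * m), n, m)
  list(x = x, labels = labels)
}

# Tiny deterministic expression matrix for classifier/evaluation tests.
toy_matrix <- function(n_per_class = c(10L, 10L, 10L), p = 8L, seed = 99L) {
  sim <- simulate_expression(sim_config(
    n_per_class = n_per_class, p = p,
    n_informative = min(4L, p), delta = 3,
    sd_informative = 0.5, sd_background = 0.1,
    class_names = paste0("C", seq_along(n_per_class)), seed = seed))
  sim$matrix
}
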