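test_that("class means are per-class arithmetic means", {
  vals <- c(1, 3, 10, 10, 10)
  labs <- factor(c("a", "a", "b", "b", "b"))
  expect_equal(class_means(vals, labs), c(a = 2, b = 10))
  expect_equal(class_means(rep(7, 5), labs), c(a = 7, b = 7))
  # one sample per class: mean is the sample itself
  expect_equal(class_means(c(4, 9), factor(c("a", "b"))), c(a = 4, b = 9))
  # declared-but-empty class is a domain error
  expect_error(class_means(c(1, 2), factor(c("a", "a"), levels = c("a", "b"))),
               "empty class")
})

test_that("absolute deviations follow |a_k - m_j| and cancel per-class shifts", {
  labs <- factor(c("a", "a"))
  expect_equal(abs_deviations(c(1, 3), labs), c(1, 1))
  expect_equal(abs_deviations(c(5, 5, 5), factor(rep("a", 3))), c(0, 0, 0))
  set.seed(3)
  vals <- rnorm(12)
  labs <- factor(rep(c("a", "b", "c"), each = 4))
  shifted <- vals + c(10, -2, 0.5)[as.integer(labs)]
  expect_equal(abs_deviations(shifted, labs), abs_deviations(vals, labs),
               tolerance = 1e-12)
})

test_that("the score is the min over classes of the max within-class deviation", {
  # class a: values 1,2,3 -> mean 2, max |dev| 1
  # class b: values 10, 10.6 -> mean 10.3, max |dev| 0.3
  vals <- c(1, 2, 3, 10, 10.6)
  labs <- factor(c("a", "a", "a", "b", "b"))
  expect_equal(score_feature(vals, labs), 0.3, tolerance = 1e-12)
  # constant within every class -> zero score
  expect_equal(score_feature(c(5, 5, -1, -1), factor(c("a", "a", "b", "b"))), 0)
})

test_that("scores are column-independent and equivariant to gene permutation", {
  em <- toy_matrix(p = 12L)
  s <- score_all(em)
  one_by_one <- vapply(seq_len(ncol(em$values)),
                       function(g) score_feature(em$values[, g], em$labels),
                       numeric(1))
  expect_equal(unname(s), one_by_one, tolerance = 0)
  perm <- sample(ncol(em$values))
  expect_equal(unname(score_all(em$values[, perm], em$labels)), unname(s)[perm],
               tolerance = 0)
})

test_that("vectorized scores equal the naive triple-loop oracle", {
  set.seed(10)
  for (rep in 1:50) {
    inst <- random_instance()
    expect_equal(unname(score_all(inst$x, inst$labels)),
                 naive_separability(inst$x, inst$labels), tolerance = 0)
  }
})

test_that("ranking sorts in the requested direction with index tie-breaks", {
  sel <- rank_and_select(c(3, 1, 2), k = 2L)
  expect_identical(sel$selected, c(1L, 3L))
  # all-equal scores fall back to ascending gene index
  expect_identical(rank_and_select(rep(1, 4), k = 3L)$selected, 1:3)
  asc <- rank_and_select(c(3, 1, 2), k = 2L, direction = "ascending")
  expect_identical(asc$selected, c(2L, 3L))
  # ascending ranking is the reverse of descending when scores are distinct
  desc <- rank_and_select(c(3, 1, 2), k = 3L)
  expect_identical(asc$ranking, rev(desc$ranking))
  expect_error(rank_and_select(c(1, 2), k = 0L), "positive integer")
  # k beyond m selects everything once
  expect_identical(rank_and_select(c(2, 1), k = 10L)$selected, c(1L, 2L))
})

test_that("scores are invariant to sample permutation and scale with |alpha|", {
  set.seed(11)
  for (rep in 1:20) {
    inst <- random_instance()
    s <- score_all(inst$x, inst$labels)
    perm <- sample(nrow(inst$x))
    # permuting rows reorders the within-class summation, so compare within
    # floating-point rounding rather than bitwise
    expect_equal(score_all(inst$x[perm, , drop = FALSE], inst$labels[perm]), s,
                 tolerance = 1e-12)
    alpha <- rnorm(1)
    expect_equal(unname(score_all(alpha * inst$x, inst$labels)),
                 abs(alpha) * unname(s), tolerance = 1e-12)
    expect_true(all(s >= 0))
  }
})

test_that("selection propagates gene ids and prints a ranked table", {
  em <- toy_matrix(p = 10L)
  sel <- separability(em, k = 4L)
  expect_length(sel$selected, 4L)
  expect_identical(sel$gene_ids, em$gene_ids)
  expect_output(print(sel), "rank")
  expect_error(score_all(em$values, rep("one", nrow(em$values))),
               "at least 2 distinct classes")
})
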