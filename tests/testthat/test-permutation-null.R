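test_that("ensembles preserve class sizes and are seed-deterministic", {
  cv <- toy_labels(27, 11)
  ens <- generate_null_labels(cv, B = 500, seed = 7)
  expect_identical(dim(ens), c(500L, 38L))
  expect_true(all(rowSums(ens) == 27L))
  expect_identical(generate_null_labels(cv, B = 500, seed = 7), ens)
  expect_false(identical(generate_null_labels(cv, B = 500, seed = 8), ens))
})

test_that("draws are uniform over the arrangement space", {
  cv <- toy_labels(2, 2)
  B <- 6000
  ens <- generate_null_labels(cv, B = B, seed = 123)
  keys <- apply(ens, 1, paste, collapse = "")
  freq <- table(keys)
  expect_identical(length(freq), 6L)  # choose(4, 2) arrangements
  p <- 1 / 6
  se <- sqrt(p * (1 - p) / B)
  expect_true(all(abs(freq / B - p) < 5 * se))
})

test_that("full enumeration lists each arrangement once and refuses large designs", {
  cv <- toy_labels(3, 3)
  ens <- enumerate_null_labels(cv)
  expect_identical(nrow(ens), 20L)  # choose(6, 3)
  expect_true(all(rowSums(ens) == 3L))
  expect_identical(anyDuplicated(apply(ens, 1, paste, collapse = "")), 0L)
  expect_error(enumerate_null_labels(toy_labels(27, 11)),
               "generate_null_labels")
})

test_that("exceedance counts are inclusive two-tail counts", {
  s <- c(0.6, -0.3, 0.2, 0.55)
  expect_identical(unname(exceedance_counts(s, 0.5)), c(2L, 0L))
  expect_identical(unname(exceedance_counts(s, 0.3)), c(2L, 1L))
  expect_identical(unname(exceedance_counts(rep(0, 5), 0.1)), c(0L, 0L))
  expect_error(exceedance_counts(s, 0), "positive")
  expect_error(exceedance_counts(s, -0.2), "positive")
})

test_that("right_quantile is the ceil(alpha*B)-th largest order statistic", {
  expect_identical(right_quantile(sample(1:100), 0.05), 96L)
  expect_identical(right_quantile(rep(7, 12), 0.3), 7)
  expect_identical(right_quantile(sample(1:500), 0.05), 476L)  # 25th largest
  expect_error(right_quantile(numeric(0), 0.05), "non-empty")
  expect_error(right_quantile(1:10, 1.2), "in \\(0, 1\\)")
})

test_that("a two-member hand-built table matches direct computation", {
  x <- toy_matrix(c(1, 2, 3, 7,
                    5, 1, 4, 2,
                    2, 2, 9, 1), 3, 4)
  cv <- toy_labels(2, 2)
  perms <- rbind(c(1L, 0L, 1L, 0L), c(0L, 1L, 0L, 1L))
  colnames(perms) <- names(cv)
  ens <- structure(perms, seed = NA_integer_, n1 = 2L, n2 = 2L,
                   class = c("permutation_ensemble", "matrix", "array"))
  grid <- c(0.2, 0.5, 1)
  tab <- null_count_table(x, ens, r_grid = grid)
  oracle <- brute_null_counts(x, perms, grid)
  expect_identical(unname(tab$counts_pos), oracle$counts_pos)
  expect_identical(unname(tab$counts_neg), oracle$counts_neg)
  # the two hand-chosen labelings are mutual swaps: counts mirror exactly
  expect_identical(tab$counts_pos[1, ], tab$counts_neg[2, ])
})

test_that("an all-constant matrix yields zero counts and zero envelopes", {
  x <- toy_matrix(rep(3, 24), 4, 6)
  cv <- toy_labels(3, 3)
  tab <- null_count_table(x, generate_null_labels(cv, B = 10, seed = 1),
                          r_grid = c(0.1, 0.4))
  expect_true(all(tab$counts_pos == 0L))
  expect_true(all(tab$counts_neg == 0L))
  expect_identical(unname(tab$l1), c(0L, 0L))
  expect_identical(unname(tab$l2), c(0L, 0L))
})

test_that("the vectorised table matches the brute-force triple loop exactly", {
  x <- random_matrix(6, 6, seed = 77)
  cv <- toy_labels(3, 3)
  ens <- generate_null_labels(cv, B = 20, seed = 5)
  grid <- seq(0.1, 0.6, by = 0.1)
  tab <- null_count_table(x, ens, r_grid = grid, block_size = 7)
  oracle <- brute_null_counts(x, ens, grid)
  expect_identical(unname(tab$counts_pos), oracle$counts_pos)
  expect_identical(unname(tab$counts_neg), oracle$counts_neg)
  expect_identical(unname(tab$l1),
                   apply(oracle$counts_pos, 2, right_quantile, alpha = 0.05))
})

test_that("count rows and envelope curves are nonincreasing along the grid", {
  x <- random_matrix(30, 10, seed = 2)
  cv <- toy_labels(5, 5)
  tab <- null_count_table(x, generate_null_labels(cv, B = 40, seed = 9),
                          r_grid = seq(0.05, 1, by = 0.05))
  expect_true(all(t(apply(tab$counts_pos, 1, diff)) <= 0))
  expect_true(all(t(apply(tab$counts_neg, 1, diff)) <= 0))
  expect_true(all(diff(tab$l1) <= 0))
  expect_true(all(diff(tab$l2) <= 0))
})

test_that("swapping 1s and 0s in every member exchanges the two count tables", {
  x <- random_matrix(12, 8, seed = 4)
  cv <- toy_labels(5, 3)
  ens <- generate_null_labels(cv, B = 15, seed = 3)
  swapped <- structure(1L - unclass(ens), seed = 3L,
                       n1 = attr(ens, "n2"), n2 = attr(ens, "n1"),
                       class = class(ens))
  colnames(swapped) <- colnames(ens)
  grid <- c(0.1, 0.3, 0.5)
  a <- null_count_table(x, ens, r_grid = grid)
  b <- null_count_table(x, swapped, r_grid = grid)
  expect_identical(a$counts_pos, b$counts_neg)
  expect_identical(a$counts_neg, b$counts_pos)
})

test_that("grid validation rejects non-increasing or non-positive grids", {
  x <- random_matrix(4, 6, seed = 1)
  ens <- generate_null_labels(toy_labels(3, 3), B = 3, seed = 1)
  expect_error(null_count_table(x, ens, r_grid = c(0.3, 0.2)), "increasing")
  expect_error(null_count_table(x, ens, r_grid = c(0, 0.5)), "positive")
})
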