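# Monte-Carlo permutation null: random relabelings preserving the class
# sizes, per-labeling exceedance counts N1/N2 over a threshold grid, and
# the right-tail quantile envelope curves L1^r, L2^r.

#' Generate a Monte-Carlo ensemble of permuted label vectors
#'
#' Draws `B` labelings uniformly (with replacement) from the space of
#' arrangements of the observed 0/1 label vector that preserve the class
#' sizes n1 and n2. Sampling with replacement follows the Monte-Carlo
#' approximation to the full randomization test: for realistic designs the
#' arrangement space is astronomically large (a 27/11 split of 38 samples
#' alone admits `choose(38, 11)` = 1,203,322,288 arrangements), so exact
#' enumeration is infeasible and duplicate draws are harmless.
#'
#' @param labels observed [class_vector()].
#' @param B ensemble size (number of permutation vectors), default 500.
#' @param seed integer seed; the same seed reproduces the ensemble exactly.
#' @return integer matrix of class `permutation_ensemble`, `B` rows x m
#'   sample columns of 0/1, with attributes `seed`, `n1`, `n2`.
#' @export
generate_null_labels <- function(labels, B = 500L, seed = 1L) {
  stopifnot(inherits(labels, "class_vector"))
  B <- as.integer(B)
  if (is.na(B) || B < 1L) stop("`B` must be a positive integer")
  m <- length(labels)
  n1 <- attr(labels, "n1")
  perms <- .with_seed(seed, {
    p <- matrix(0L, nrow = B, ncol = m)
    for (j in seq_len(B)) p[j, sample.int(m, n1)] <- 1L
    p
  })
  colnames(perms) <- names(labels)
  structure(perms, seed = seed, n1 = n1, n2 = attr(labels, "n2"),
            class = c("permutation_ensemble", class(perms)))
}

#' Enumerate every class-size-preserving labeling (toy inputs only)
#'
#' Full-enumeration counterpart of [generate_null_labels()], intended as a
#' testing oracle on small designs where `choose(m, n1)` is manageable.
#' Real designs must use the Monte-Carlo ensemble.
#'
#' @param labels observed [class_vector()].
#' @param max_arrangements refuse to enumerate beyond this many (default
#'   10000, comfortably above `choose(12, 6)` = 924).
#' @return `permutation_ensemble` containing every distinct arrangement
#'   exactly once.
#' @export
enumerate_null_labels <- function(labels, max_arrangements = 10000L) {
  stopifnot(inherits(labels, "class_vector"))
  m <- length(labels)
  n1 <- attr(labels, "n1")
  n_arr <- choose(m, n1)
  if (n_arr > max_arrangements) {
    stop("enumeration would need ", format(n_arr, scientific = FALSE),
         " arrangements; use generate_null_labels() for designs this large")
  }
  sets <- utils::combn(m, n1)
  perms <- matrix(0L, nrow = ncol(sets), ncol = m)
  for (j in seq_len(ncol(sets))) perms[j, sets[, j]] <- 1L
  colnames(perms) <- names(labels)
  structure(perms, seed = NA_integer_, n1 = n1, n2 = attr(labels, "n2"),
            class = c("permutation_ensemble", class(perms)))
}

#' Two-tailed exceedance counts at a threshold
#'
#' For a score vector and threshold `r > 0`, counts the genes scoring at
#' least `r` (`pos`, the N1 count) and at most `-r` (`neg`, the N2 count).
#' Both comparisons are inclusive; infinite sentinel scores count on the
#' side of their sign.
#'
#' @param scores numeric score vector for one labeling.
#' @param r positive threshold (at `r <= 0` the two tails would overlap).
#' @return integer vector `c(pos = N1, neg = N2)`.
#' @export
exceedance_counts <- function(scores, r) {
  .assert_scalar_number(r, "r")
  if (r <= 0) stop("`r` must be positive: the tails overlap at r = 0")
  c(pos = sum(scores >= r), neg = sum(scores <= -r))
}

#' Right-tail quantile as an order statistic
#'
#' The right `alpha` quantile of `B` values is the k-th largest with
#' `k = ceiling(alpha * B)`: the largest attained value with at most a
#' fraction `alpha` of the sample strictly above it. Defined as an order
#' statistic (no interpolation) so it is exact on integer counts; for
#' `B = 500`, `alpha = 0.05` it is the 25th largest.
#'
#' @param values numeric vector (the B permutation counts at one threshold).
#' @param alpha right-tail fraction in (0, 1), default 0.05.
#' @return the order-statistic quantile.
#' @export
right_quantile <- function(values, alpha = 0.05) {
  if (length(values) == 0L) stop("`values` must be non-empty")
  .assert_scalar_number(alpha, "alpha")
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)")
  k <- ceiling(alpha * length(values))
  sort(values, decreasing = TRUE)[k]
}

# Scores of every gene against a block of permuted labelings, via matrix
# algebra: for 0/1 indicator columns P, class means are x P / n and class
# variances follow from x^2 P. Returns genes x members score matrix.
.block_scores <- function(x, x2, perm_block, n1, n2) {
  p1 <- t(perm_block)                    # m x b indicators of class 1
  p0 <- 1 - p1
  mu1 <- (x %*% p1) / n1
  mu0 <- (x %*% p0) / n2
  v1 <- ((x2 %*% p1) - n1 * mu1^2) / (n1 - 1L)
  v0 <- ((x2 %*% p0) - n2 * mu0^2) / (n2 - 1L)
  den <- sqrt(pmax(v1, 0)) + sqrt(pmax(v0, 0))
  .scores_from_summaries(mu1 - mu0, den)
}

#' Null exceedance-count table with quantile envelope curves
#'
#' For every member of a permutation ensemble, scores all genes and counts
#' the threshold exceedances at each grid value; the right `alpha`
#' quantile of each column gives the null envelope curves L1 (positive
#' tail) and L2 (negative tail). The observed labeling is never part of
#' the ensemble statistics. The full member-by-gene score matrix is
#' processed in blocks and discarded, so only the B x |grid| count table
#' is retained.
#'
#' @param x expression matrix (genes x samples).
#' @param ensemble a [generate_null_labels()] or [enumerate_null_labels()]
#'   ensemble whose columns match the matrix samples.
#' @param r_grid strictly increasing vector of positive thresholds,
#'   default `seq(0.1, 0.6, by = 0.1)`.
#' @param alpha right-tail fraction for the envelope, default 0.05.
#' @param block_size ensemble members scored per block (memory knob).
#' @return list of class `null_count_table`: `r_grid`, integer matrices
#'   `counts_pos` and `counts_neg` (B x |grid|), envelope vectors `l1`,
#'   `l2`, plus `alpha` and `B`.
#' @export
null_count_table <- function(x, ensemble, r_grid = seq(0.1, 0.6, by = 0.1),
                             alpha = 0.05, block_size = 200L) {
  stopifnot(inherits(ensemble, "permutation_ensemble"))
  if (ncol(ensemble) != ncol(x)) {
    stop("ensemble sample count does not match the matrix")
  }
  .check_grid(r_grid)
  B <- nrow(ensemble)
  k <- length(r_grid)
  x2 <- x^2
  n1 <- attr(ensemble, "n1")
  n2 <- attr(ensemble, "n2")
  counts_pos <- matrix(0L, nrow = B, ncol = k)
  counts_neg <- matrix(0L, nrow = B, ncol = k)
  for (start in seq(1L, B, by = block_size)) {
    idx <- start:min(start + block_size - 1L, B)
    sc <- .block_scores(x, x2, ensemble[idx, , drop = FALSE], n1, n2)
    for (g in seq_len(k)) {
      counts_pos[idx, g] <- as.integer(colSums(sc >= r_grid[g]))
      counts_neg[idx, g] <- as.integer(colSums(sc <= -r_grid[g]))
    }
  }
  dimnames(counts_pos) <- dimnames(counts_neg) <-
    list(NULL, format(r_grid, trim = TRUE))
  structure(
    list(r_grid = r_grid,
         counts_pos = counts_pos,
         counts_neg = counts_neg,
         l1 = apply(counts_pos, 2L, right_quantile, alpha = alpha),
         l2 = apply(counts_neg, 2L, right_quantile, alpha = alpha),
         alpha = alpha, B = B),
    class = "null_count_table"
  )
}

.check_grid <- function(r_grid) {
  if (length(r_grid) < 1L || any(!is.finite(r_grid)) || any(r_grid <= 0)) {
    stop("`r_grid` must contain positive finite thresholds")
  }
  if (length(r_grid) > 1L && any(diff(r_grid) <= 0)) {
    stop("`r_grid` must be strictly increasing")
  }
  invisible(r_grid)
}

#' @export
print.null_count_table <- function(x, ...) {
  cat("Permutation null count table: B = ", x$B, ", right ",
      format(100 * x$alpha), "% envelope\n", sep = "")
  print(data.frame(r = x$r_grid, l1 = x$l1, l2 = x$l2, row.names = NULL))
  invisible(x)
}
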