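# Per-gene class summaries and the signal-to-noise score
# P(g, c) = (mu_A - mu_B) / (sigma_A + sigma_B).

# Row-wise mean and sample (n-1 denominator) standard deviation of the
# columns selected by `idx`.
.row_stats <- function(x, idx) {
  n <- length(idx)
  sub <- x[, idx, drop = FALSE]
  mu <- rowMeans(sub)
  ss <- rowSums((sub - mu)^2)
  list(mu = mu, sigma = sqrt(pmax(ss, 0) / (n - 1L)))
}

.check_aligned <- function(x, labels) {
  stopifnot(inherits(labels, "class_vector"))
  if (length(labels) != ncol(x)) {
    stop("label vector length (", length(labels),
         ") does not match sample count (", ncol(x), ")")
  }
  if (!is.null(colnames(x)) && !identical(names(labels), colnames(x))) {
    stop("label sample identifiers do not match matrix column order")
  }
  invisible(TRUE)
}

#' Per-gene class means and standard deviations
#'
#' Computes, for every gene, the mean and standard deviation of its
#' expression within each class. Standard deviations use the sample
#' (n - 1) denominator, which is why each class must have at least two
#' members.
#'
#' @param x expression matrix (genes x samples).
#' @param labels a [class_vector()] aligned with the matrix columns.
#' @return list with per-gene numeric vectors `mu_a`, `sigma_a` (class
#'   labelled 1) and `mu_b`, `sigma_b` (class labelled 0).
#' @export
class_summaries <- function(x, labels) {
  .check_aligned(x, labels)
  a <- .row_stats(x, which(unclass(labels) == 1L))
  b <- .row_stats(x, which(unclass(labels) == 0L))
  list(mu_a = a$mu, sigma_a = a$sigma, mu_b = b$mu, sigma_b = b$sigma)
}

# Scores from precomputed summaries, applying the zero-denominator rule:
# a gene constant within both classes but with different class means is
# maximally discriminative (signed infinite sentinel); a fully constant
# gene is uninformative (score 0).
.scores_from_summaries <- function(num, den) {
  s <- num / den
  zero <- den == 0
  if (any(zero)) {
    s[zero] <- sign(num[zero]) * Inf
    s[zero & num == 0] <- 0
  }
  s
}

#' Signal-to-noise scores for one labeling
#'
#' The per-gene score is `(mu_A - mu_B) / (sigma_A + sigma_B)`: the
#' between-class mean separation relative to the summed within-class
#' spread. Its sign gives the direction of the shift (positive = higher in
#' the class labelled 1) and, unlike a product-moment correlation, it is
#' unbounded. Genes with zero spread in both classes get a signed infinite
#' sentinel when their class means differ (they compare greater in
#' magnitude than any finite threshold) and 0 when they do not.
#'
#' @inheritParams class_summaries
#' @return named numeric vector of per-gene scores.
#' @export
snr_scores <- function(x, labels) {
  cs <- class_summaries(x, labels)
  stats::setNames(
    .scores_from_summaries(cs$mu_a - cs$mu_b, cs$sigma_a + cs$sigma_b),
    rownames(x)
  )
}
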