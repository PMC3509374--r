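# Intersecting observed exceedance-count curves with the null envelope to
# calibrate the selection threshold r* = max{r0, |t0|} (+ optional
# adjustment), and applying it.

#' Observed exceedance-count curve over a threshold grid
#'
#' Counts, at every grid threshold, the genes whose observed score lies in
#' the requested tail: scores `>= r` for the positive tail (the N1 curve)
#' or `<= -r` for the negative tail (the N2 curve).
#'
#' @param scores observed score vector ([snr_scores()]).
#' @param r_grid strictly increasing positive thresholds.
#' @param tail `"positive"` or `"negative"`.
#' @return integer vector of counts, named by threshold.
#' @export
observed_count_curve <- function(scores, r_grid = seq(0.1, 0.6, by = 0.1),
                                 tail = c("positive", "negative")) {
  tail <- match.arg(tail)
  .check_grid(r_grid)
  side <- if (tail == "positive") "pos" else "neg"
  stats::setNames(
    vapply(r_grid, function(r) exceedance_counts(scores, r)[[side]],
           integer(1L)),
    format(r_grid, trim = TRUE)
  )
}

#' Abscissa where the observed curve crosses the null envelope
#'
#' Both curves are nonincreasing in the threshold; with real signal the
#' observed curve starts below the null envelope (the permutation noise
#' floor dominates at small thresholds) and rises above it as the
#' threshold grows. The crossing abscissa is found by piecewise-linear
#' interpolation of the difference `d(r) = observed - null_quantile`
#' between adjacent grid points: the first transition of `d` from
#' negative-or-zero to positive is returned (a grid point where `d` is
#' exactly zero is returned as-is). Multiple transitions trigger a warning
#' listing them all; no transition is an error suggesting a wider or finer
#' grid.
#'
#' @param r_grid strictly increasing positive thresholds.
#' @param observed observed counts at each threshold.
#' @param null_quantile envelope values (L1 or L2) at each threshold.
#' @return the interpolated crossing abscissa (always within the grid
#'   interval that brackets the sign change).
#' @export
curve_intersection <- function(r_grid, observed, null_quantile) {
  .check_grid(r_grid)
  if (length(observed) != length(r_grid) ||
      length(null_quantile) != length(r_grid)) {
    stop("`observed` and `null_quantile` must match `r_grid` in length")
  }
  d <- as.numeric(observed) - as.numeric(null_quantile)
  k <- length(d)
  if (d[1L] > 0) {
    stop("observed curve already exceeds the null envelope at the smallest ",
         "threshold; widen `r_grid` downwards")
  }
  trans <- which(d[-1L] > 0 & d[-k] <= 0)
  if (length(trans) == 0L) {
    if (d[k] == 0) return(r_grid[k])
    stop("observed and null envelope curves do not cross on this grid; ",
         "widen or refine `r_grid`")
  }
  if (length(trans) > 1L) {
    warning("curves cross more than once (between grid points ",
            paste(sprintf("%g-%g", r_grid[trans], r_grid[trans + 1L]),
                  collapse = ", "),
            "); returning the first crossing")
  }
  j <- trans[1L]
  r_grid[j] + (r_grid[j + 1L] - r_grid[j]) * (-d[j]) / (d[j + 1L] - d[j])
}

#' Combine the two tail crossings into the selection threshold
#'
#' `r_star = max(r0, |t0|) + adjustment_a`. The negative-tail crossing
#' `t0` is conventionally reported as a negative abscissa; its absolute
#' value is taken internally. The nonnegative adjustment `a` is an
#' explicit user parameter for tightening an over-generous selection; no
#' automatic rule is provided, its effect being judged by retrospective
#' assessment of the downstream classifier.
#'
#' @param r0 positive-tail crossing abscissa (> 0).
#' @param t0 negative-tail crossing abscissa (negative by convention).
#' @param adjustment_a nonnegative additive adjustment, default 0.
#' @return list of class `threshold_result`: `r0`, `t0`, `adjustment_a`,
#'   `r_star`.
#' @export
combine_threshold <- function(r0, t0, adjustment_a = 0) {
  .assert_scalar_number(r0, "r0")
  .assert_scalar_number(t0, "t0")
  .assert_scalar_number(adjustment_a, "adjustment_a")
  if (r0 <= 0) stop("`r0` must be positive")
  if (adjustment_a < 0) stop("`adjustment_a` must be nonnegative")
  structure(
    list(r0 = r0, t0 = -abs(t0), adjustment_a = adjustment_a,
         r_star = max(r0, abs(t0)) + adjustment_a),
    class = "threshold_result"
  )
}

#' @export
print.threshold_result <- function(x, ...) {
  # full precision is kept in the object; the display rounds to 2 decimals
  cat(sprintf(
    "Threshold: r0 = %.2f, t0 = %.2f, a = %g  =>  r* = %.2f (exact %.6g)\n",
    x$r0, x$t0, x$adjustment_a, x$r_star, x$r_star))
  invisible(x)
}

#' Select the genes whose scores clear the threshold
#'
#' A gene discriminates the two classes when `|score| >= r_star`
#' (inclusive). Selected genes carry direction +1 (`score >= r_star`,
#' higher in the positive class) or -1 (`score <= -r_star`). The selection
#' size always equals the sum of the two tail counts at `r_star`.
#'
#' @param scores named observed score vector.
#' @param r_star positive selection threshold (see [combine_threshold()]).
#' @param gene_ids gene identifiers aligned with `scores`; defaults to
#'   `names(scores)`.
#' @return a `gene_selection` data frame (`gene_id`, `score`, `direction`)
#'   sorted by descending `|score|`, with attribute `threshold`.
#' @export
select_genes <- function(scores, r_star, gene_ids = names(scores)) {
  .assert_scalar_number(r_star, "r_star")
  if (r_star <= 0) stop("`r_star` must be positive")
  if (is.null(gene_ids)) stop("gene identifiers required")
  if (length(gene_ids) != length(scores)) {
    stop("`gene_ids` and `scores` differ in length")
  }
  keep <- abs(scores) >= r_star
  new_gene_selection(gene_ids[keep], scores[keep], r_star)
}
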