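# Synthetic two-class expression data with planted informative genes, so
# the whole pipeline is testable at desk scale without any download. The
# default shape emulates a classic unbalanced leukemia design: 27 vs 11
# samples and a few thousand genes of which a minority carry a
# class-shifted mean.

#' Simulate a two-class expression matrix with planted signal
#'
#' Uninformative genes are drawn i.i.d. normal with the same mean
#' (`baseline`) and standard deviation (`sigma`) in both classes.
#' Informative genes receive a between-class mean separation of
#' `effect * sigma`: class means `baseline +/- effect * sigma / 2`, with
#' the shift sign alternating gene by gene so that both score tails (and
#' hence both crossing abscissas r0 and t0) are populated. Under this
#' model the population signal-to-noise score of an informative gene is
#' `effect / 2`. No microarray-specific noise (probe effects,
#' intensity-dependent variance) is modelled.
#'
#' @param n1,n2 class sizes (positive class first), defaults 27 and 11.
#' @param n_genes total genes, default 2000.
#' @param n_informative planted discriminative genes, default 100.
#' @param effect between-class mean shift in within-class standard
#'   deviation units, default 2.
#' @param sigma within-class standard deviation (expression units),
#'   default 1.
#' @param baseline grand mean expression, default 0.
#' @param seed integer seed; identical seeds give identical datasets.
#' @param class_names the two class names, positive first.
#' @return list with `matrix` (genes x samples), `labels` (a
#'   [class_vector()]), and `truth` (data frame `gene_id`, `informative`,
#'   `direction` where direction is +1 / -1 for planted genes, 0
#'   otherwise).
#' @export
simulate_expression <- function(n1 = 27L, n2 = 11L, n_genes = 2000L,
                                n_informative = 100L, effect = 2,
                                sigma = 1, baseline = 0, seed = 1L,
                                class_names = c("A", "B")) {
  stopifnot(n1 >= 2L, n2 >= 2L, n_genes >= 1L,
            n_informative >= 0L, n_informative <= n_genes,
            effect >= 0, sigma > 0, length(class_names) == 2L)
  m <- n1 + n2
  gene_ids <- sprintf("g%0*d", nchar(n_genes), seq_len(n_genes))
  sample_ids <- sprintf("s%0*d", nchar(m), seq_len(m))
  direction <- integer(n_genes)
  if (n_informative > 0L) {
    direction[seq_len(n_informative)] <-
      ifelse(seq_len(n_informative) %% 2L == 1L, 1L, -1L)
  }
  shift <- direction * effect * sigma / 2
  mean_mat <- baseline +
    cbind(matrix(shift, n_genes, n1), matrix(-shift, n_genes, n2))
  values <- .with_seed(seed, {
    mean_mat + matrix(stats::rnorm(n_genes * m, sd = sigma), n_genes, m)
  })
  labels <- class_vector(rep(class_names, c(n1, n2)),
                         positive_class = class_names[1L],
                         sample_ids = sample_ids)
  list(
    matrix = expression_matrix(values, gene_ids, sample_ids),
    labels = labels,
    truth = data.frame(gene_id = gene_ids,
                       informative = direction != 0L,
                       direction = direction,
                       stringsAsFactors = FALSE)
  )
}

#' Simulate a global-null two-class expression matrix
#'
#' Convenience wrapper of [simulate_expression()] with no informative
#' genes: every gene has the same distribution in both classes, so the
#' observed labeling is exchangeable with the permutation ensemble. Used
#' for calibration checks of the null envelope.
#'
#' @inheritParams simulate_expression
#' @return list with `matrix` and `labels` (no `truth` table is needed:
#'   no gene is informative).
#' @export
simulate_null <- function(n1 = 27L, n2 = 11L, n_genes = 500L, sigma = 1,
                          baseline = 0, seed = 1L,
                          class_names = c("A", "B")) {
  sim <- simulate_expression(n1 = n1, n2 = n2, n_genes = n_genes,
                             n_informative = 0L, effect = 0, sigma = sigma,
                             baseline = baseline, seed = seed,
                             class_names = class_names)
  sim[c("matrix", "labels")]
}

#' Write a simulated dataset to delimited files
#'
#' Writes `matrix.tsv` (expression), `labels.tsv` (sample_id, class) and,
#' when present, `truth.tsv` (gene_id, informative, direction) into a
#' directory.
#'
#' @param sim a [simulate_expression()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(matrix = file.path(dir, "matrix.tsv"),
             labels = file.path(dir, "labels.tsv"))
  write_expression_matrix(sim$matrix, paths[["matrix"]])
  cls <- attr(sim$labels, "classes_ab")
  utils::write.table(
    data.frame(sample_id = names(sim$labels),
               class = ifelse(unclass(sim$labels) == 1L, cls[1L], cls[2L])),
    paths[["labels"]], sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(sim$truth)) {
    paths <- c(paths, truth = file.path(dir, "truth.tsv"))
    utils::write.table(sim$truth, paths[["truth"]], sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(paths)
}
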