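# Two-class discrimination stage: a signal-to-noise-weighted vote toward
# the nearer class centroid, used for retrospective (training-set) and
# prospective (independent-cohort) assessment of a gene selection. The
# functional form of the discriminant is this package's declared default
# (the classical companion of the signal-to-noise score); the stage is a
# plain S3 surface so an alternative linear rule can be dropped in.

#' Fit the weighted-vote centroid classifier on a gene selection
#'
#' Stores, for each selected gene, the two class centroids (training class
#' means) and a vote weight equal to the absolute signal-to-noise score
#' from the selection. Only selected genes enter the model; all other
#' genes are ignored entirely. Infinite sentinel scores (zero within-class
#' spread) are capped at the largest finite weight so that a single
#' degenerate gene cannot silence the rest of the vote.
#'
#' @param x training expression matrix (genes x samples).
#' @param labels training [class_vector()].
#' @param selection a non-empty `gene_selection` (see [select_genes()]).
#' @return list of class `centroid_model`: `gene_ids`, `centroid_a`,
#'   `centroid_b`, `weights`, `classes` (positive then negative class
#'   name).
#' @export
fit_classifier <- function(x, labels, selection) {
  stopifnot(inherits(selection, "gene_selection"))
  .check_aligned(x, labels)
  if (nrow(selection) == 0L) stop("cannot fit a classifier on an empty selection")
  missing <- setdiff(selection$gene_id, rownames(x))
  if (length(missing)) {
    stop("selected gene(s) absent from the matrix: ",
         paste(missing, collapse = ", "))
  }
  sub <- x[selection$gene_id, , drop = FALSE]
  cs <- class_summaries(sub, labels)
  w <- abs(selection$score)
  if (any(is.infinite(w))) {
    cap <- if (any(is.finite(w))) max(w[is.finite(w)]) else 1
    w[is.infinite(w)] <- cap
  }
  structure(
    list(gene_ids = selection$gene_id,
         centroid_a = cs$mu_a, centroid_b = cs$mu_b,
         weights = w,
         classes = attr(labels, "classes_ab")),
    class = "centroid_model"
  )
}

#' Classify samples with a fitted centroid model
#'
#' Each gene casts its weight toward the class whose centroid is nearer to
#' the sample's expression value (half a weight to each side on a per-gene
#' tie); the class with the larger total vote wins. An overall tie is
#' broken deterministically toward the positive class (A) and reported via
#' a message. The margin is `|vote_a - vote_b| / (vote_a + vote_b)`.
#'
#' @param model a [fit_classifier()] model.
#' @param newdata expression matrix (genes x samples) or a single named
#'   per-gene vector; must cover every model gene.
#' @return data frame: `sample_id`, `class`, `margin`.
#' @export
classify <- function(model, newdata) {
  stopifnot(inherits(model, "centroid_model"))
  if (is.null(dim(newdata))) {
    newdata <- matrix(newdata, ncol = 1L,
                      dimnames = list(names(newdata), "sample_1"))
  }
  missing <- setdiff(model$gene_ids, rownames(newdata))
  if (length(missing)) {
    stop("sample(s) lack selected gene(s): ", paste(missing, collapse = ", "))
  }
  sub <- newdata[model$gene_ids, , drop = FALSE]
  da <- abs(sub - model$centroid_a)
  db <- abs(sub - model$centroid_b)
  w <- model$weights
  vote_a <- colSums(w * (da < db)) + colSums(w * (da == db)) / 2
  vote_b <- colSums(w * (db < da)) + colSums(w * (da == db)) / 2
  tie <- vote_a == vote_b
  if (any(tie)) {
    message("vote tie for sample(s) ",
            paste(colnames(sub)[tie], collapse = ", "),
            "; assigned to class ", model$classes[1L])
  }
  total <- vote_a + vote_b
  margin <- ifelse(total > 0, abs(vote_a - vote_b) / total, 0)
  data.frame(
    sample_id = colnames(sub),
    class = ifelse(vote_a >= vote_b, model$classes[1L], model$classes[2L]),
    margin = as.numeric(margin),
    stringsAsFactors = FALSE
  )
}

#' Misclassification fraction of a model on labelled data
#'
#' Used both retrospectively (evaluating on the training cohort) and
#' prospectively (on an independent test cohort).
#'
#' @param model a [fit_classifier()] model.
#' @param x expression matrix to classify.
#' @param labels true [class_vector()] for those samples; its class names
#'   must match the model's.
#' @return fraction of samples misclassified, in `[0, 1]`.
#' @export
error_rate <- function(model, x, labels) {
  stopifnot(inherits(model, "centroid_model"))
  .check_aligned(x, labels)
  if (!setequal(attr(labels, "classes_ab"), model$classes)) {
    stop("label class names do not match the model's classes")
  }
  pred <- classify(model, x)$class
  truth <- ifelse(unclass(labels) == 1L,
                  attr(labels, "classes_ab")[1L],
                  attr(labels, "classes_ab")[2L])
  mean(pred != truth)
}

#' @export
print.centroid_model <- function(x, ...) {
  cat("Weighted-vote centroid model: ", length(x$gene_ids), " gene(s), ",
      "classes ", x$classes[1L], " vs ", x$classes[2L], "\n", sep = "")
  invisible(x)
}

#' Write a centroid model to delimited text
#'
#' Tab-separated columns `gene_id`, `centroid_a`, `centroid_b`, `weight`.
#'
#' @param model a [fit_classifier()] model.
#' @param path output path.
#' @export
write_classifier <- function(model, path) {
  stopifnot(inherits(model, "centroid_model"))
  df <- data.frame(gene_id = model$gene_ids,
                   centroid_a = model$centroid_a,
                   centroid_b = model$centroid_b,
                   weight = model$weights,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
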