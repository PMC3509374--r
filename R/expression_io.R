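# Reading/writing expression matrices, class labels and selection reports,
# plus the shared data types (expression matrix, class vector, gene
# selection) used by every downstream stage.

#' Construct a validated expression matrix
#'
#' An expression matrix is a plain numeric matrix with genes in rows and
#' samples in columns; row names are gene identifiers, column names are
#' sample identifiers. Values are treated as opaque real intensities: the
#' signal-to-noise statistic is invariant to per-gene affine rescaling, so
#' no unit convention or normalisation is assumed.
#'
#' @param values numeric matrix, genes x samples.
#' @param gene_ids character vector of unique gene identifiers (defaults to
#'   existing row names).
#' @param sample_ids character vector of unique sample identifiers (defaults
#'   to existing column names).
#' @return the validated matrix with dimnames set.
#' @export
expression_matrix <- function(values,
                              gene_ids = rownames(values),
                              sample_ids = colnames(values)) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (genes x samples)")
  }
  if (nrow(values) < 1L) stop("expression matrix needs at least 1 gene")
  if (ncol(values) < 2L) stop("expression matrix needs at least 2 samples")
  if (is.null(gene_ids) || is.null(sample_ids)) {
    stop("gene and sample identifiers are required")
  }
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (length(gene_ids) != nrow(values)) stop("gene_ids length != row count")
  if (length(sample_ids) != ncol(values)) stop("sample_ids length != column count")
  dup <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup)) stop("duplicated gene identifier(s): ",
                        paste(dup, collapse = ", "))
  dup <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup)) stop("duplicated sample identifier(s): ",
                        paste(dup, collapse = ", "))
  bad <- which(!is.finite(values))
  if (length(bad)) {
    i <- ((bad[1L] - 1L) %% nrow(values)) + 1L
    j <- ((bad[1L] - 1L) %/% nrow(values)) + 1L
    stop("non-finite or missing expression value at gene '", gene_ids[i],
         "', sample '", sample_ids[j], "' (", length(bad), " such cell(s))")
  }
  dimnames(values) <- list(gene_ids, sample_ids)
  values
}

#' Read an expression matrix from delimited text
#'
#' The expected layout is a header row of sample identifiers and a first
#' column of gene identifiers (the transposed layout is accepted with
#' `genes_in_rows = FALSE`; the result is always normalised to
#' genes-in-rows). The delimiter is auto-detected among tab and comma
#' unless given. Missing or non-numeric cells are rejected with their
#' location: the selection statistic has no missing-data provision.
#'
#' @param path path to the text file.
#' @param delimiter field separator; `NULL` (default) auto-detects.
#' @param genes_in_rows logical; `FALSE` means the file stores samples in
#'   rows and genes in columns.
#' @return numeric matrix, genes x samples, validated.
#' @export
read_expression_matrix <- function(path, delimiter = NULL,
                                   genes_in_rows = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (is.null(delimiter)) .detect_delimiter(path) else delimiter
  header <- utils::read.table(path, sep = sep, header = FALSE, nrows = 1L,
                              colClasses = "character",
                              comment.char = "", quote = "\"")
  body <- utils::read.table(path, sep = sep, header = FALSE, skip = 1L,
                            colClasses = "character",
                            comment.char = "", quote = "\"")
  header <- as.character(header[1L, ])
  if (ncol(body) < 2L) stop("expected an identifier column plus data columns")
  # header may or may not carry a leading corner cell above the id column
  col_ids <- if (length(header) == ncol(body)) header[-1L] else header
  if (length(col_ids) != ncol(body) - 1L) {
    stop("header has ", length(header), " fields but data rows have ",
         ncol(body), " columns")
  }
  row_ids <- body[[1L]]
  raw <- as.matrix(body[, -1L, drop = FALSE])
  values <- suppressWarnings(array(as.numeric(raw), dim = dim(raw)))
  bad <- which(is.na(values) | !is.finite(values))
  if (length(bad)) {
    i <- ((bad[1L] - 1L) %% nrow(values)) + 1L
    j <- ((bad[1L] - 1L) %/% nrow(values)) + 1L
    stop("non-numeric or missing cell at row '", row_ids[i],
         "', column '", col_ids[j], "' in ", path)
  }
  if (genes_in_rows) {
    expression_matrix(values, gene_ids = row_ids, sample_ids = col_ids)
  } else {
    expression_matrix(t(values), gene_ids = col_ids, sample_ids = row_ids)
  }
}

#' Write an expression matrix to delimited text
#'
#' Inverse of [read_expression_matrix()]: header row of sample identifiers
#' (with a `gene_id` corner cell), one row per gene. Values are written at
#' full precision so a read/write/read round trip is exact.
#'
#' @param x expression matrix (genes x samples, dimnames set).
#' @param path output path.
#' @param delimiter field separator, default tab.
#' @export
write_expression_matrix <- function(x, path, delimiter = "\t") {
  x <- expression_matrix(x)
  df <- data.frame(gene_id = rownames(x),
                   format(x, digits = 17, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("gene_id", colnames(x))
  utils::write.table(df, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Construct a two-class label vector
#'
#' Encodes class membership of the samples as a 0/1 vector: 1 for the
#' positive class (type A, listed first in the classic layout
#' `c = (1,...,1, 0,...,0)`), 0 for the other class. Both classes need at
#' least two members because the per-class standard deviations in the
#' selection statistic require it.
#'
#' @param labels character or factor vector of class names, one per sample,
#'   named by sample identifier (or use `sample_ids`).
#' @param positive_class class name mapped to 1; defaults to the first class
#'   encountered.
#' @param sample_ids sample identifiers aligned with `labels`.
#' @return integer 0/1 vector of class `class_vector`, named by sample, with
#'   attributes `classes` (positive then negative class name), `n1`, `n2`.
#' @export
class_vector <- function(labels, positive_class = NULL, sample_ids = NULL) {
  if (is.null(sample_ids)) sample_ids <- names(labels)
  if (is.null(sample_ids)) {
    stop("sample identifiers required (names of `labels` or `sample_ids`)")
  }
  labels <- as.character(labels)
  if (length(labels) != length(sample_ids)) {
    stop("labels and sample_ids differ in length")
  }
  dup <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup)) stop("duplicated sample identifier(s): ",
                        paste(dup, collapse = ", "))
  classes <- unique(labels)
  if (length(classes) != 2L) {
    stop("expected exactly 2 classes, found ", length(classes), ": ",
         paste(classes, collapse = ", "))
  }
  if (is.null(positive_class)) positive_class <- classes[1L]
  if (!positive_class %in% classes) {
    stop("positive_class '", positive_class, "' not among the classes (",
         paste(classes, collapse = ", "), ")")
  }
  negative_class <- setdiff(classes, positive_class)
  v <- as.integer(labels == positive_class)
  n1 <- sum(v)
  n2 <- length(v) - n1
  if (n1 < 2L || n2 < 2L) {
    small <- if (n1 < 2L) positive_class else negative_class
    stop("class '", small, "' has fewer than 2 members; per-class standard ",
         "deviations are undefined")
  }
  structure(stats::setNames(v, sample_ids),
            classes_ab = c(positive_class, negative_class),
            n1 = n1, n2 = n2, class = "class_vector")
}

#' Read a two-column sample/class label file
#'
#' The file holds one row per sample: sample identifier, class name
#' (delimiter auto-detected; an optional header row is skipped when its
#' first field matches no sample). When `sample_ids` is supplied (the
#' matrix's sample order, the canonical order), every sample must appear
#' exactly once and the result is reordered to match.
#'
#' @param path label file path.
#' @param positive_class class name mapped to 1.
#' @param sample_ids optional canonical sample ordering to align to.
#' @param delimiter field separator; `NULL` auto-detects.
#' @return a [class_vector()].
#' @export
read_labels <- function(path, positive_class = NULL, sample_ids = NULL,
                        delimiter = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (is.null(delimiter)) .detect_delimiter(path) else delimiter
  tab <- utils::read.table(path, sep = sep, header = FALSE,
                           colClasses = "character", comment.char = "",
                           quote = "\"")
  if (ncol(tab) < 2L) stop("label file must have two columns: sample_id, class")
  # tolerate a header line
  if (nrow(tab) > 1L &&
      (identical(tolower(tab[1L, 1L]), "sample_id") ||
       (!is.null(sample_ids) && !tab[1L, 1L] %in% sample_ids &&
        all(tab[-1L, 1L] %in% sample_ids)))) {
    tab <- tab[-1L, , drop = FALSE]
  }
  ids <- tab[[1L]]
  cls <- tab[[2L]]
  if (!is.null(sample_ids)) {
    missing <- setdiff(sample_ids, ids)
    if (length(missing)) stop("label file is missing sample(s): ",
                              paste(missing, collapse = ", "))
    unknown <- setdiff(ids, sample_ids)
    if (length(unknown)) stop("label file has unknown sample(s): ",
                              paste(unknown, collapse = ", "))
    dup <- unique(ids[duplicated(ids)])
    if (length(dup)) stop("label file lists sample(s) more than once: ",
                          paste(dup, collapse = ", "))
    ord <- match(sample_ids, ids)
    ids <- ids[ord]
    cls <- cls[ord]
  }
  class_vector(cls, positive_class = positive_class, sample_ids = ids)
}

#' Swap the two classes of a label vector
#'
#' Exchanges the 0s and 1s (and the class-name attribute order). The
#' selection statistic is antisymmetric under this operation.
#'
#' @param labels a [class_vector()].
#' @return the swapped `class_vector`.
#' @export
swap_classes <- function(labels) {
  stopifnot(inherits(labels, "class_vector"))
  cls <- attr(labels, "classes_ab")
  class_vector(ifelse(unclass(labels) == 1L, cls[1L], cls[2L]),
               positive_class = cls[2L], sample_ids = names(labels))
}

#' @export
print.class_vector <- function(x, ...) {
  cls <- attr(x, "classes_ab")
  cat("Two-class label vector: ", length(x), " samples (",
      cls[1L], " = 1: n1 = ", attr(x, "n1"), "; ",
      cls[2L], " = 0: n2 = ", attr(x, "n2"), ")\n", sep = "")
  invisible(x)
}

#' Construct a gene selection
#'
#' @param gene_ids selected gene identifiers.
#' @param scores their signal-to-noise scores.
#' @param threshold the selection threshold r* used.
#' @return data frame (`gene_id`, `score`, `direction`) of class
#'   `gene_selection`, sorted by descending absolute score (ties broken by
#'   gene identifier), with attribute `threshold`.
#' @keywords internal
new_gene_selection <- function(gene_ids, scores, threshold) {
  stopifnot(length(gene_ids) == length(scores), threshold > 0)
  if (any(abs(scores) < threshold)) {
    stop("every selected gene must satisfy |score| >= threshold")
  }
  direction <- ifelse(scores >= threshold, 1L, -1L)
  ord <- order(-abs(scores), gene_ids)
  out <- data.frame(gene_id = as.character(gene_ids)[ord],
                    score = as.numeric(scores)[ord],
                    direction = direction[ord],
                    stringsAsFactors = FALSE)
  structure(out, threshold = threshold,
            class = c("gene_selection", "data.frame"))
}

# Infinite sentinel scores (zero within-class spread, shifted means) are
# printed as "inf"/"-inf" tokens in delimited reports.
.format_score <- function(s) {
  ifelse(is.infinite(s), ifelse(s > 0, "inf", "-inf"),
         sprintf("%.10g", s))
}

.parse_score <- function(tok) {
  out <- suppressWarnings(as.numeric(tok))
  out[tok == "inf"] <- Inf
  out[tok == "-inf"] <- -Inf
  out
}

#' Write a gene selection report
#'
#' Tab-separated columns `gene_id`, `score`, `direction`, `threshold`,
#' ordered by descending absolute score with ties broken lexicographically
#' by gene identifier. Infinite sentinel scores appear as `inf` / `-inf`.
#'
#' @param selection a `gene_selection` (see [select_genes()]).
#' @param path output path.
#' @export
write_selection <- function(selection, path) {
  stopifnot(inherits(selection, "gene_selection"))
  df <- data.frame(gene_id = selection$gene_id,
                   score = .format_score(selection$score),
                   direction = selection$direction,
                   threshold = rep(attr(selection, "threshold"),
                                   length.out = nrow(selection)),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene selection report written by [write_selection()]
#'
#' @param path report path.
#' @return a `gene_selection` data frame.
#' @export
read_selection <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = "character")
  need <- c("gene_id", "score", "direction", "threshold")
  if (!all(need %in% colnames(tab))) {
    stop("selection report must have columns: ", paste(need, collapse = ", "))
  }
  if (nrow(tab) == 0L) {
    stop("selection report is empty; the threshold cannot be recovered")
  }
  new_gene_selection(tab$gene_id, .parse_score(tab$score),
                     as.numeric(tab$threshold[1L]))
}

#' @export
print.gene_selection <- function(x, ...) {
  cat("Gene selection: ", nrow(x), " gene(s) with |score| >= ",
      format(attr(x, "threshold")), "\n", sep = "")
  if (nrow(x)) print.data.frame(utils::head(x, 10L), row.names = FALSE)
  if (nrow(x) > 10L) cat("... and", nrow(x) - 10L, "more\n")
  invisible(x)
}
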