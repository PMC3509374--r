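# Test helpers: tiny fixture builders and literal brute-force oracles kept
# deliberately independent of the package's vectorised code paths.

toy_matrix <- function(values, n_genes, m,
                       gene_ids = paste0("g", seq_len(n_genes)),
                       sample_ids = paste0("s", seq_len(m))) {
  matrix(values, nrow = n_genes, ncol = m,
         dimnames = list(gene_ids, sample_ids))
}

toy_labels <- function(n1, n2, positive = "A") {
  class_vector(rep(c("A", "B"), c(n1, n2)), positive_class = positive,
               sample_ids = paste0("s", seq_len(n1 + n2)))
}

random_matrix <- function(n_genes, m, seed) {
  set.seed(seed)
  toy_matrix(rnorm(n_genes * m), n_genes, m)
}

# Literal per-gene two-loop computation of the signal-to-noise score from
# its definition: class means and n-1 standard deviations, ratio of mean
# difference to summed deviations.
brute_snr <- function(x, labels01) {
  out <- numeric(nrow(x))
  for (i in seq_len(nrow(x))) {
    a <- c()
    b <- c()
    for (j in seq_len(ncol(x))) {
      if (labels01[j] == 1) a <- c(a, x[i, j]) else b <- c(b, x[i, j])
    }
    num <- mean(a) - mean(b)
    den <- sd(a) + sd(b)
    out[i] <- if (den == 0) {
      if (num == 0) 0 else sign(num) * Inf
    } else {
      num / den
    }
  }
  out
}

# Brute-force null count table: triple loop over (member, gene, threshold).
brute_null_counts <- function(x, perms, r_grid) {
  B <- nrow(perms)
  cp <- matrix(0L, B, length(r_grid))
  cn <- matrix(0L, B, length(r_grid))
  for (j in seq_len(B)) {
    s <- brute_snr(x, perms[j, ])
    for (g in seq_along(r_grid)) {
      for (i in seq_along(s)) {
        if (s[i] >= r_grid[g]) cp[j, g] <- cp[j, g] + 1L
        if (s[i] <= -r_grid[g]) cn[j, g] <- cn[j, g] + 1L
      }
    }
  }
  list(counts_pos = cp, counts_neg = cn)
}

# Write a genes-x-samples matrix as delimited text for IO tests.
write_matrix_file <- function(x, path, sep = "\t", transpose = FALSE) {
  if (transpose) {
    lines <- c(paste(c("sample_id", rownames(x)), collapse = sep),
               vapply(seq_len(ncol(x)), function(j) {
                 paste(c(colnames(x)[j], format(x[, j], digits = 17)),
                       collapse = sep)
               }, character(1)))
  } else {
    lines <- c(paste(c("gene_id", colnames(x)), collapse = sep),
               vapply(seq_len(nrow(x)), function(i) {
                 paste(c(rownames(x)[i], format(x[i, ], digits = 17)),
                       collapse = sep)
               }, character(1)))
  }
  writeLines(lines, path)
  path
}

write_labels_file <- function(ids, classes, path, sep = "\t") {
  writeLines(paste(ids, classes, sep = sep), path)
  path
}
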