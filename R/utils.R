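# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state. All randomness in the package funnels through this.
.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        },
        add = TRUE
      )
    }
    set.seed(as.integer(seed))
  }
  expr
}

# Guess the field separator of a delimited text file from its first line:
# tab wins over comma when both occur (gene annotations may contain commas).
.detect_delimiter <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stop("file is empty: ", path)
  n_tab <- lengths(regmatches(first, gregexpr("\t", first, fixed = TRUE)))
  n_com <- lengths(regmatches(first, gregexpr(",", first, fixed = TRUE)))
  if (n_tab == 0L && n_com == 0L) {
    stop("could not detect a tab or comma delimiter in ", path,
         "; pass `delimiter` explicitly")
  }
  if (n_tab >= n_com) "\t" else ","
}

.assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop("`", name, "` must be a single finite number")
  }
  invisible(x)
}
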