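# internal helpers shared across modules

# default labels when a time-course file carries no header
default_region_ids <- function(n) sprintf("r%03d", seq_len(n))

# upper-triangle (i < j) index pairs of an n x n matrix, column by column
upper_pairs <- function(n) {
  idx <- which(upper.tri(diag(n)), arr.ind = TRUE)
  idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
}

assert_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (x < min || x > max)
    stop(sprintf("'%s' must be in [%s, %s], got %s", name, min, max, x),
         call. = FALSE)
  invisible(x)
}

is_symmetric_num <- function(M, tol = 1e-10) {
  is.matrix(M) && nrow(M) == ncol(M) && is.numeric(M) &&
    max(abs(M - t(M))) <= tol
}
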