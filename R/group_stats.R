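#' Two-sample t-test for one property at one density
#'
#' Pooled-variance (Student) two-sided test by default, the historical
#' default for group comparisons of network properties; Welch's unequal
#' variance form is available via `welch = TRUE`.  Degenerate inputs are
#' resolved explicitly rather than erroring: when both samples have zero
#' pooled variance the test returns `t = 0, p = 1` for equal means and
#' `p = 0` (infinite t) for unequal means.
#'
#' @param a,b numeric samples, each of size >= 2, finite.
#' @param welch use the Welch test instead of pooled variance.
#' @return List with `t`, `p` (two-sided), `df`.
#' @export
two_sample_ttest <- function(a, b, welch = FALSE) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2)
    stop("each sample needs at least 2 observations", call. = FALSE)
  if (!all(is.finite(a)) || !all(is.finite(b)))
    stop("samples must be finite", call. = FALSE)
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b))
      return(list(t = 0, p = 1, df = length(a) + length(b) - 2))
    return(list(t = sign(mean(a) - mean(b)) * Inf, p = 0,
                df = length(a) + length(b) - 2))
  }
  ht <- stats::t.test(a, b, var.equal = !welch)
  list(t = unname(ht$statistic), p = ht$p.value, df = unname(ht$parameter))
}

#' Benjamini-Hochberg FDR rejection flags
#'
#' Step-up procedure at level `q`: sort the m p-values ascending, find the
#' largest k with \eqn{p_{(k)} \le k q / m}, reject ranks 1..k.  Flags are
#' returned in the input order.
#'
#' @param pvals numeric vector of p-values in \[0, 1\].
#' @param q FDR level in (0, 1).
#' @return Logical vector of rejections, same length and order as `pvals`.
#' @export
fdr_bh <- function(pvals, q = 0.05) {
  assert_scalar_number(q, "q", min = 1e-12, max = 1 - 1e-12)
  if (length(pvals) == 0) return(logical(0))
  if (anyNA(pvals) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(pvals, method = "BH") <= q
}

#' Paired sign-flip permutation test
#'
#' Tests whether the first member of each pair is systematically larger
#' than the second.  The statistic is the mean paired difference
#' `mean(a - b)`; the null distribution is built by independently flipping
#' the sign of every paired difference `n_perm` times.  The one-sided
#' p-value uses the add-one rule `(1 + #[null >= observed]) / (1 + n_perm)`,
#' so it can never be exactly zero.
#'
#' @param a,b paired numeric vectors of equal length >= 2 (e.g. per-cell
#'   p-values of two construction methods across the density grid; then a
#'   small p here means the second method's values are systematically
#'   smaller).
#' @param n_perm number of sign-flip draws.
#' @param seed integer seed; the result is deterministic given it.
#' @return List with `statistic` (observed mean difference) and `p`.
#' @export
paired_permutation_test <- function(a, b, n_perm = 10000, seed = 1L) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b) || length(a) < 2)
    stop("a and b must be paired vectors of equal length >= 2", call. = FALSE)
  d <- a - b
  obs <- mean(d)
  if (all(d == 0)) return(list(statistic = 0, p = 1))
  m <- length(d)
  null <- withr::with_seed(as.integer(seed), {
    signs <- matrix(sample(c(-1, 1), n_perm * m, replace = TRUE), n_perm, m)
    as.numeric(signs %*% d) / m
  })
  list(statistic = obs, p = (1 + sum(null >= obs)) / (1 + n_perm))
}

#' Long-format property grid over a cohort
#'
#' Runs one construction method over every subject and every density of the
#' grid, computes the five topological properties, and returns the
#' long-format table consumed by [compare_methods()] and the classifier
#' drivers.
#'
#' @param ch a [cohort()].
#' @param regions a [region_table()].
#' @param method `"classic"` or `"snv"`.
#' @param densities numeric vector of densities in percent (default 8:16).
#' @param window_width window width for `"snv"` (recorded as `NA` for
#'   classic).
#' @param long_edge_mm,n_null,seed metric configuration (see
#'   [network_metrics()]); the small-world seed is offset per subject so
#'   surrogate draws differ across subjects yet stay reproducible.
#' @return Data frame with columns `subject`, `group`, `property`,
#'   `density`, `window`, `value`.
#' @export
property_grid <- function(ch, regions, method = c("classic", "snv"),
                          densities = 8:16, window_width = NULL,
                          long_edge_mm = 75, n_null = 100, seed = 1L) {
  method <- match.arg(method)
  stopifnot(inherits(ch, "cohort"))
  props <- c("global_efficiency", "mean_clustering", "transfer_coefficient",
             "small_world_value", "long_edge_count")
  rows <- list()
  for (si in seq_along(ch$subjects)) {
    subj <- ch$subjects[[si]]
    for (nd in densities) {
      net <- construct_network(subj$tc, method, nd, window_width)
      met <- network_metrics(net, regions, long_edge_mm = long_edge_mm,
                             n_null = n_null, seed = as.integer(seed) + si)
      rows[[length(rows) + 1L]] <- data.frame(
        subject = subj$subject_id, group = subj$group, property = props,
        density = nd,
        window = if (method == "snv") as.integer(window_width) else NA_integer_,
        value = unlist(met[props], use.names = FALSE))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# per-(property, density, window) group t-tests of one long-format grid
grid_cell_tests <- function(grid, welch = FALSE) {
  win_key <- ifelse(is.na(grid$window), "full", as.character(grid$window))
  key <- paste(grid$property, grid$density, win_key, sep = "|")
  cells <- split(grid, key)
  out <- do.call(rbind, lapply(cells, function(cell) {
    gl <- sort(unique(cell$group))
    if (length(gl) != 2) stop("each cell needs two groups", call. = FALSE)
    ht <- two_sample_ttest(cell$value[cell$group == gl[1]],
                           cell$value[cell$group == gl[2]], welch = welch)
    data.frame(property = cell$property[1], density = cell$density[1],
               window = cell$window[1], t = ht$t, p = ht$p)
  }))
  rownames(out) <- NULL
  out[order(out$property, out$density, out$window), , drop = FALSE]
}

#' Compare two construction methods' group-difference profiles
#'
#' For each method's property grid, runs the group t-test in every
#' (property, density, window) cell, counts cells significant at
#' `p < alpha`, applies BH-FDR across the method's full cell family at
#' level `q`, and — per property — runs the paired sign-flip permutation
#' test on the two methods' p-value profiles (paired by density and window)
#' to ask whether the second method's p-values are systematically smaller.
#'
#' @param grid_a,grid_b long-format grids from [property_grid()] for the two
#'   methods (conventionally classic and SNV); they must cover the same
#'   subjects, properties and densities.
#' @param q FDR level.
#' @param alpha uncorrected significance threshold for cell counting.
#' @param n_perm,seed permutation-test configuration.
#' @param welch passed to the cell t-tests.
#' @return List of class `method_comparison`: per-cell tables `cells_a`,
#'   `cells_b` (with uncorrected p and FDR flags), counts `n_sig_a/b` and
#'   `n_fdr_a/b`, the number of paired cells where method B's p-value is
#'   lower (`n_p_decreased`), and `perm` (per-property permutation
#'   p-values).
#' @export
compare_methods <- function(grid_a, grid_b, q = 0.05, alpha = 0.05,
                            n_perm = 10000, seed = 1L, welch = FALSE) {
  ca <- grid_cell_tests(grid_a, welch = welch)
  cb <- grid_cell_tests(grid_b, welch = welch)
  ca$fdr_reject <- fdr_bh(ca$p, q)
  cb$fdr_reject <- fdr_bh(cb$p, q)
  key <- function(d) paste(d$property, d$density, sep = "|")
  merged <- merge(ca[, c("property", "density", "window", "p")],
                  cb[, c("property", "density", "window", "p")],
                  by = c("property", "density"),
                  suffixes = c("_a", "_b"))
  perm <- lapply(split(merged, merged$property), function(mp)
    paired_permutation_test(mp$p_a, mp$p_b, n_perm = n_perm, seed = seed))
  structure(list(
    cells_a = ca, cells_b = cb,
    n_sig_a = sum(ca$p < alpha), n_sig_b = sum(cb$p < alpha),
    n_fdr_a = sum(ca$fdr_reject), n_fdr_b = sum(cb$fdr_reject),
    n_p_decreased = sum(merged$p_b < merged$p_a),
    n_paired_cells = nrow(merged),
    perm = perm, q = q, alpha = alpha),
    class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, ...) {
  cat(sprintf("method comparison over %d cells per method\n", nrow(x$cells_a)))
  cat(sprintf("  significant (p < %g): A = %d, B = %d\n",
              x$alpha, x$n_sig_a, x$n_sig_b))
  cat(sprintf("  FDR-significant (q = %g): A = %d, B = %d\n",
              x$q, x$n_fdr_a, x$n_fdr_b))
  cat(sprintf("  p-value decreased in B for %d / %d paired cells\n",
              x$n_p_decreased, x$n_paired_cells))
  for (pr in names(x$perm))
    cat(sprintf("  permutation p (B lower) [%s]: %.4g\n", pr, x$perm[[pr]]$p))
  invisible(x)
}
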