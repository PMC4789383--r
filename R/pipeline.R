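#' Window-width sweep of group-difference p-values
#'
#' Rebuilds the SNV networks of a cohort at each candidate window width and
#' one density, and records the group t-test p-value per property: the
#' diagnostic used to pick a sensible window width (too-narrow windows make
#' unreliable per-window correlations, too-wide ones leave too few
#' subnetworks to vote).
#'
#' @param ch a [cohort()].
#' @param regions a [region_table()].
#' @param widths integer vector of window widths to try.
#' @param density_pct single density in percent (a mid-grid value is
#'   customary).
#' @param long_edge_mm,n_null,seed metric configuration.
#' @return Data frame with columns `window`, `property`, `t`, `p` and
#'   `n_subnetworks` (`L - W + 1`).
#' @export
sweep_window_widths <- function(ch, regions, widths, density_pct = 12,
                                long_edge_mm = 75, n_null = 100, seed = 1L) {
  stopifnot(inherits(ch, "cohort"))
  L <- nrow(ch$subjects[[1]]$tc)
  out <- lapply(widths, function(W) {
    grid <- property_grid(ch, regions, method = "snv",
                          densities = density_pct, window_width = W,
                          long_edge_mm = long_edge_mm, n_null = n_null,
                          seed = seed)
    cells <- grid_cell_tests(grid)
    data.frame(window = W, property = cells$property, t = cells$t,
               p = cells$p, n_subnetworks = L - W + 1L)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
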