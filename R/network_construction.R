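#' Number of edges implied by a proportional density
#'
#' The density grid used throughout is expressed in percent of the
#' \eqn{N(N-1)/2} possible undirected edges.  The realized count is rounded
#' half-up so that the network's density stays as close as possible to the
#' nominal value.
#'
#' @param n_regions number of regions `N`.
#' @param density_pct density in percent, `0 < density_pct <= 100`.
#' @return Integer edge count; an error if the count would be zero.
#' @examples
#' target_edges(90, 8)   # 8% of 4005 pairs -> 320 edges
#' @export
target_edges <- function(n_regions, density_pct) {
  assert_scalar_number(n_regions, "n_regions", min = 2)
  assert_scalar_number(density_pct, "density_pct", min = .Machine$double.eps,
                       max = 100)
  n_pairs <- n_regions * (n_regions - 1) / 2
  k <- floor(density_pct / 100 * n_pairs + 0.5)  # round half-up
  if (k < 1)
    stop(sprintf("density %g%% yields 0 edges for %d regions",
                 density_pct, n_regions), call. = FALSE)
  as.integer(k)
}

#' Extract all sliding-window subseries of a time-course matrix
#'
#' Windows slide with stride 1, so a series of length `L` yields
#' `K = L - W + 1` windows; window `i` covers time rows `i ... i+W-1` and
#' the same boundaries apply to every region.
#'
#' @param tc a [timecourse_matrix()].
#' @param window_width window width `W`, `3 <= W <= L`.
#' @return List of `K` [timecourse_matrix()] objects in window order.
#' @examples
#' tc <- timecourse_matrix(matrix(rnorm(40), 10, 4))
#' length(extract_subseries(tc, 4))   # 7 windows
#' @export
extract_subseries <- function(tc, window_width) {
  stopifnot(inherits(tc, "timecourse_matrix"))
  L <- nrow(tc)
  assert_scalar_number(window_width, "window_width", min = 3, max = L)
  W <- as.integer(window_width)
  K <- L - W + 1L
  sid <- attr(tc, "subject_id")
  lapply(seq_len(K), function(i) {
    win <- unclass(tc)[i:(i + W - 1L), , drop = FALSE]
    timecourse_matrix(win, region_ids = colnames(tc),
                      subject_id = sprintf("%s[w%d]", sid, i),
                      check_variance = FALSE)
  })
}

#' Pearson correlation matrix of regional time courses
#'
#' Standard sample Pearson coefficient for every pair of regions, using only
#' the samples present in `tc` (so a windowed subseries uses only its own
#' `W` time points).
#'
#' @param tc a [timecourse_matrix()] (full series or one window).
#' @return `correlation_matrix`: symmetric N x N matrix with unit diagonal,
#'   entries in \[-1, 1\], region labels as dimnames.
#' @export
pearson_correlation <- function(tc) {
  stopifnot(inherits(tc, "timecourse_matrix"))
  vals <- unclass(tc)
  sds <- apply(vals, 2, stats::sd)
  if (any(sds == 0))
    stop(sprintf("zero-variance region(s) %s in series '%s'",
                 paste(colnames(tc)[sds == 0], collapse = ", "),
                 attr(tc, "subject_id")), call. = FALSE)
  C <- stats::cor(vals)
  C[C > 1] <- 1; C[C < -1] <- -1
  diag(C) <- 1
  C <- (C + t(C)) / 2
  structure(C, class = c("correlation_matrix", "matrix"))
}

#' Threshold a symmetric score matrix to an exact edge density
#'
#' Ranks the upper-triangle entries by absolute value (descending) and keeps
#' the top [target_edges()] of them as edges.  When several entries share the
#' marginal score, the tie is resolved by the larger `tie_weights` entry
#' (for the voting matrix this is the accumulated correlation magnitude); any
#' residual tie is broken by ascending (row, column) index so the output is
#' deterministic.
#'
#' @param M symmetric numeric matrix of scores; the diagonal is ignored.
#' @param density_pct target density in percent.
#' @param tie_weights optional symmetric numeric matrix of the same size used
#'   to order tied scores (larger wins).
#' @param region_ids optional region labels; default from `M`'s dimnames.
#' @param window source annotation stored on the result (unused by the
#'   algorithm).
#' @return A [binary_network()] with exactly `target_edges(N, density_pct)`
#'   edges.
#' @export
threshold_to_density <- function(M, density_pct, tie_weights = NULL,
                                 region_ids = NULL, window = "full") {
  if (!is_symmetric_num(M))
    stop("score matrix must be numeric, square and symmetric", call. = FALSE)
  n <- nrow(M)
  if (is.null(region_ids)) {
    region_ids <- rownames(M)
    if (is.null(region_ids)) region_ids <- default_region_ids(n)
  }
  if (!is.null(tie_weights)) {
    if (!is_symmetric_num(tie_weights) || nrow(tie_weights) != n)
      stop("tie_weights must be a symmetric matrix matching M", call. = FALSE)
  } else {
    tie_weights <- matrix(0, n, n)
  }
  k <- target_edges(n, density_pct)
  pairs <- upper_pairs(n)
  score <- abs(M[pairs])
  tw <- tie_weights[pairs]
  ord <- order(-score, -tw, pairs[, 1], pairs[, 2])
  keep <- pairs[ord[seq_len(k)], , drop = FALSE]
  adj <- matrix(0, n, n)
  adj[keep] <- 1
  adj <- adj + t(adj)
  net <- binary_network(adj, region_ids = region_ids,
                        density_target = density_pct)
  attr(net, "window") <- window
  net
}

#' Classic full-length correlation network
#'
#' The conventional construction: one Pearson correlation matrix over the
#' whole series, thresholded to the requested proportional density (ties by
#' correlation magnitude, which coincides with the score itself).
#'
#' @param tc a [timecourse_matrix()].
#' @param density_pct target density in percent (the usual grid is 8-16%).
#' @return A [binary_network()].
#' @export
classic_construct <- function(tc, density_pct) {
  C <- pearson_correlation(tc)
  threshold_to_density(unclass(C), density_pct, tie_weights = abs(unclass(C)),
                       region_ids = colnames(tc), window = "full")
}

#' Subnetwork-voting (SNV) sliding-window network
#'
#' Builds one binary subnetwork per sliding window at the target density,
#' sums them into a voting matrix `S` (entry = number of windows in which
#' that pair was selected, between 0 and `K = L - W + 1`), and thresholds
#' `S` itself to the same density.  Pairs tied at the marginal vote count
#' are resolved by the summed correlation magnitude
#' `C = |C_1| + ... + |C_K|`: among equally voted pairs, the one with the
#' larger accumulated weight wins.
#'
#' @param tc a [timecourse_matrix()] of length `L`.
#' @param window_width sliding-window width `W`, `3 <= W <= L`; with
#'   `W = L` there is a single window and the result reduces exactly to
#'   [classic_construct()].
#' @param density_pct target density in percent.
#' @return A [binary_network()] whose `"voting_state"` attribute records the
#'   intermediate state: `votes` (S), `weight_sum` (C), `window_count` (K)
#'   and `window_width` (W).  Retrieve it with [voting_state()].
#' @examples
#' tc <- timecourse_matrix(matrix(rnorm(60 * 10), 60, 10))
#' net <- snv_construct(tc, window_width = 42, density_pct = 12)
#' max(voting_state(net)$votes)  # <= 19 windows
#' @export
snv_construct <- function(tc, window_width, density_pct) {
  stopifnot(inherits(tc, "timecourse_matrix"))
  n <- ncol(tc)
  windows <- extract_subseries(tc, window_width)
  K <- length(windows)
  votes <- matrix(0, n, n)
  weight_sum <- matrix(0, n, n)
  for (i in seq_len(K)) {
    Ci <- tryCatch(pearson_correlation(windows[[i]]), error = function(e)
      stop(sprintf("window %d of %d: %s", i, K, conditionMessage(e)),
           call. = FALSE))
    Ci <- unclass(Ci)
    Si <- threshold_to_density(Ci, density_pct, tie_weights = abs(Ci),
                               region_ids = colnames(tc),
                               window = sprintf("w%d", i))
    votes <- votes + Si$adjacency
    absCi <- abs(Ci); diag(absCi) <- 0
    weight_sum <- weight_sum + absCi
  }
  dimnames(votes) <- list(colnames(tc), colnames(tc))
  net <- threshold_to_density(votes, density_pct, tie_weights = weight_sum,
                              region_ids = colnames(tc), window = "voting")
  attr(net, "voting_state") <- structure(
    list(votes = votes, weight_sum = weight_sum,
         window_count = K, window_width = as.integer(window_width)),
    class = "voting_state")
  net
}

#' Voting state of an SNV-constructed network
#'
#' @param net a network returned by [snv_construct()].
#' @return The `voting_state` attached to it (`votes`, `weight_sum`,
#'   `window_count`, `window_width`), or an error for networks built by
#'   other means.
#' @export
voting_state <- function(net) {
  vs <- attr(net, "voting_state")
  if (is.null(vs))
    stop("network carries no voting state (not built by snv_construct)",
         call. = FALSE)
  vs
}

#' Construct a network by either method
#'
#' Dispatch helper used by the grid/classification drivers and the CLI.
#'
#' @param tc a [timecourse_matrix()].
#' @param method `"classic"` or `"snv"`.
#' @param density_pct target density in percent.
#' @param window_width window width (required for `"snv"`, ignored
#'   otherwise).
#' @return A [binary_network()].
#' @export
construct_network <- function(tc, method = c("classic", "snv"), density_pct,
                              window_width = NULL) {
  method <- match.arg(method)
  if (method == "classic") classic_construct(tc, density_pct)
  else {
    if (is.null(window_width))
      stop("window_width is required for the snv method", call. = FALSE)
    snv_construct(tc, window_width, density_pct)
  }
}
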