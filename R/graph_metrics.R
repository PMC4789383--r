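#' Global efficiency of a binary network
#'
#' Mean inverse shortest-path length over all ordered node pairs,
#' \eqn{E = \frac{1}{N(N-1)} \sum_{i \ne j} 1/d(i,j)}, with unweighted
#' (hop-count) distances; a disconnected pair contributes 0, so the value
#' stays finite on fragmented networks.
#'
#' @param net a [binary_network()].
#' @return Efficiency in \[0, 1\]: 1 for a complete graph, 0 for an empty
#'   one.
#' @export
global_efficiency <- function(net) {
  g <- as_igraph(net)
  e <- igraph::global_efficiency(g)
  if (is.nan(e)) 0 else e
}

#' Mean clustering coefficient
#'
#' Watts-Strogatz local clustering, averaged over all `N` nodes: node `i`
#' contributes \eqn{2 t_i / (k_i (k_i - 1))} where `t_i` is the number of
#' triangles through `i`; nodes with degree below 2 contribute 0 (they are
#' averaged in, not excluded).
#'
#' @param net a [binary_network()].
#' @return Mean clustering in \[0, 1\].
#' @export
mean_clustering <- function(net) {
  g <- as_igraph(net)
  igraph::transitivity(g, type = "localaverage", isolates = "zero")
}

#' Transfer coefficient (network transitivity)
#'
#' Ratio of triangles to connected triplets over the whole network:
#' 3 x (number of triangles) / (number of paths of length 2).  Returns 0
#' when the network has no triplets at all.
#'
#' @param net a [binary_network()].
#' @return Transitivity in \[0, 1\].
#' @export
transfer_coefficient <- function(net) {
  g <- as_igraph(net)
  tr <- igraph::transitivity(g, type = "global")
  if (is.nan(tr)) 0 else tr
}

#' Small-world value against degree-preserving null networks
#'
#' The small-world coefficient
#' \eqn{\sigma = (C/C_{rand}) / (\Lambda/\Lambda_{rand})}, where `C` is
#' [mean_clustering()], `Lambda` the characteristic path length averaged
#' over connected pairs only, and the null values are means over `n_null`
#' degree-preserving surrogates obtained by double-edge swaps (10 x m swap
#' attempts each).  Values above 1 indicate small-world organization.
#'
#' @param net a [binary_network()] with at least one edge.
#' @param n_null number of null surrogates (default 100).
#' @param seed integer seed; the result is deterministic given
#'   `(net, n_null, seed)`.
#' @return `sigma` as a positive scalar, with attributes `C`, `Lambda`,
#'   `C_rand`, `Lambda_rand`, `n_null`, `seed` recording the configuration.
#' @export
small_world_value <- function(net, n_null = 100, seed = 1L) {
  stopifnot(inherits(net, "binary_network"))
  assert_scalar_number(n_null, "n_null", min = 1)
  g <- as_igraph(net)
  m <- igraph::ecount(g)
  if (m < 1) stop("small_world_value needs a network with >= 1 edge",
                  call. = FALSE)
  C <- mean_clustering(net)
  Lambda <- igraph::mean_distance(g, unconnected = TRUE)
  nulls <- withr::with_seed(as.integer(seed), {
    lapply(seq_len(n_null), function(i) {
      rg <- igraph::rewire(g, igraph::keeping_degseq(niter = 10 * m))
      c(C = igraph::transitivity(rg, type = "localaverage", isolates = "zero"),
        L = igraph::mean_distance(rg, unconnected = TRUE))
    })
  })
  C_rand <- mean(vapply(nulls, `[[`, 0, "C"))
  L_rand <- mean(vapply(nulls, `[[`, 0, "L"))
  if (!is.finite(C_rand) || C_rand == 0 || !is.finite(L_rand) || L_rand == 0)
    stop("null ensemble has zero clustering or path length; increase n_null",
         call. = FALSE)
  sigma <- (C / C_rand) / (Lambda / L_rand)
  structure(sigma, C = C, Lambda = Lambda, C_rand = C_rand,
            Lambda_rand = L_rand, n_null = n_null, seed = as.integer(seed))
}

#' Count long edges by centroid distance
#'
#' An edge is "long" when the Euclidean distance between its endpoint
#' centroids strictly exceeds `threshold_mm`.  The distance criterion is a
#' configurable parameter of this package (default 75 mm), not a fixed
#' anatomical constant.
#'
#' @param net a [binary_network()].
#' @param regions a [region_table()] resolving every region of `net`.
#' @param threshold_mm nonnegative distance threshold in millimetres.
#' @return Integer count of long edges.
#' @export
count_long_edges <- function(net, regions, threshold_mm = 75) {
  stopifnot(inherits(net, "binary_network"), inherits(regions, "region_table"))
  assert_scalar_number(threshold_mm, "threshold_mm", min = 0)
  missing_r <- setdiff(net$region_ids, regions$region_id)
  if (length(missing_r))
    stop(sprintf("region(s) missing from region table: %s",
                 paste(missing_r, collapse = ", ")), call. = FALSE)
  xyz <- as.matrix(regions[match(net$region_ids, regions$region_id),
                           c("x", "y", "z")])
  edges <- which(upper.tri(net$adjacency) & net$adjacency == 1, arr.ind = TRUE)
  if (nrow(edges) == 0) return(0L)
  d <- sqrt(rowSums((xyz[edges[, 1], , drop = FALSE] -
                       xyz[edges[, 2], , drop = FALSE])^2))
  sum(d > threshold_mm)
}

#' Node degrees of a binary network
#'
#' @param net a [binary_network()].
#' @return Named integer vector of degrees; their sum is twice the edge
#'   count (handshake identity).
#' @export
node_degrees <- function(net) {
  stopifnot(inherits(net, "binary_network"))
  d <- rowSums(net$adjacency)
  storage.mode(d) <- "integer"
  d
}

#' All five topological properties of one network
#'
#' Convenience wrapper collecting [global_efficiency()], [mean_clustering()],
#' [transfer_coefficient()], [small_world_value()] and [count_long_edges()]
#' with their configuration.
#'
#' @param net a [binary_network()].
#' @param regions a [region_table()] (required for the long-edge count).
#' @param long_edge_mm long-edge distance threshold in mm.
#' @param n_null,seed null-model configuration passed to
#'   [small_world_value()].
#' @return A named list of class `network_metrics` with the five values plus
#'   a `config` record.
#' @export
network_metrics <- function(net, regions, long_edge_mm = 75, n_null = 100,
                            seed = 1L) {
  structure(list(
    global_efficiency = global_efficiency(net),
    mean_clustering = mean_clustering(net),
    transfer_coefficient = transfer_coefficient(net),
    small_world_value = as.numeric(small_world_value(net, n_null, seed)),
    long_edge_count = count_long_edges(net, regions, long_edge_mm),
    config = list(long_edge_mm = long_edge_mm, n_null = n_null,
                  seed = as.integer(seed))),
    class = "network_metrics")
}

#' @export
print.network_metrics <- function(x, ...) {
  cat(sprintf(paste0("network_metrics: efficiency=%.4f clustering=%.4f ",
                     "transfer=%.4f sigma=%.3f long_edges=%d\n"),
              x$global_efficiency, x$mean_clustering, x$transfer_coefficient,
              x$small_world_value, x$long_edge_count))
  invisible(x)
}
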