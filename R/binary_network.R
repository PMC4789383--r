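#' Binary network at a fixed edge density
#'
#' The common currency of the package: an undirected, unweighted graph over
#' `N` named regions, stored as a symmetric 0/1 adjacency matrix with zero
#' diagonal.  Networks produced by [classic_construct()] and
#' [snv_construct()] carry the nominal edge density they were thresholded to;
#' their realized edge count always equals [target_edges()] exactly.
#'
#' @param adjacency symmetric numeric matrix of 0s and 1s with zero diagonal.
#' @param region_ids character vector of region labels, one per row/column.
#'   Defaults to the adjacency dimnames, or generated labels `r001...`.
#' @param density_target nominal density in percent (`NA` when the network
#'   was not produced by proportional thresholding).
#' @return An object of class `binary_network`: a list with elements
#'   `adjacency` (named 0/1 matrix), `region_ids`, `density_target` and
#'   `edge_count`.
#' @examples
#' a <- matrix(0, 3, 3); a[1, 2] <- a[2, 1] <- 1
#' net <- binary_network(a, region_ids = c("A", "B", "C"))
#' net$edge_count
#' @export
binary_network <- function(adjacency, region_ids = NULL, density_target = NA_real_) {
  if (!is.matrix(adjacency) || nrow(adjacency) != ncol(adjacency))
    stop("adjacency must be a square matrix", call. = FALSE)
  n <- nrow(adjacency)
  if (is.null(region_ids)) {
    region_ids <- rownames(adjacency)
    if (is.null(region_ids)) region_ids <- default_region_ids(n)
  }
  region_ids <- as.character(region_ids)
  if (length(region_ids) != n || anyDuplicated(region_ids))
    stop("region_ids must be unique and match the adjacency dimension",
         call. = FALSE)
  storage.mode(adjacency) <- "double"
  if (anyNA(adjacency) || !all(adjacency %in% c(0, 1)))
    stop("adjacency entries must be 0 or 1", call. = FALSE)
  if (!isTRUE(all.equal(adjacency, t(adjacency))))
    stop("adjacency must be symmetric", call. = FALSE)
  if (any(diag(adjacency) != 0))
    stop("self-loops are not allowed (diagonal must be zero)", call. = FALSE)
  dimnames(adjacency) <- list(region_ids, region_ids)
  structure(
    list(adjacency = adjacency,
         region_ids = region_ids,
         density_target = density_target,
         edge_count = sum(adjacency) / 2),
    class = "binary_network")
}

#' @export
print.binary_network <- function(x, ...) {
  n <- length(x$region_ids)
  dens <- 100 * x$edge_count / (n * (n - 1) / 2)
  cat(sprintf("binary_network: %d regions, %d edges (density %.2f%%",
              n, x$edge_count, dens))
  if (!is.na(x$density_target))
    cat(sprintf(", target %g%%", x$density_target))
  cat(")\n")
  invisible(x)
}

#' @export
`==.binary_network` <- function(e1, e2) {
  identical(e1$region_ids, e2$region_ids) &&
    identical(unname(e1$adjacency), unname(e2$adjacency))
}

#' Edge list of a binary network
#'
#' Each undirected edge once, endpoints in region order, rows ordered
#' lexicographically: the canonical form used for file output and for
#' edge-set comparisons such as [edge_recovery_score()].
#'
#' @param net a [binary_network()].
#' @return Two-column character matrix (`from`, `to`); zero rows for an
#'   empty network.
#' @export
network_edges <- function(net) {
  stopifnot(inherits(net, "binary_network"))
  idx <- which(upper.tri(net$adjacency) & net$adjacency == 1, arr.ind = TRUE)
  out <- cbind(from = net$region_ids[idx[, 1]], to = net$region_ids[idx[, 2]])
  out[order(out[, 1], out[, 2]), , drop = FALSE]
}

# igraph view of a binary_network (shared by the metrics module)
as_igraph <- function(net) {
  stopifnot(inherits(net, "binary_network"))
  igraph::graph_from_adjacency_matrix(net$adjacency, mode = "undirected",
                                      diag = FALSE)
}
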