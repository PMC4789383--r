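#' Generate a planted ground-truth network
#'
#' Seeded generator for the connectivity structure a synthetic subject's
#' signals are drawn from.  `"random"` samples edges uniformly;
#' `"modular"` plants `n_blocks` communities and favours within-block pairs
#' (higher clustering, lower efficiency — the profile of the less integrated
#' group); `"smallworld"` starts from a ring lattice and rewires a small
#' fraction of edges.  All styles are repaired by random edge addition or
#' removal to hit [target_edges()] exactly.
#'
#' @param n_regions number of regions.
#' @param density_pct target density in percent.
#' @param style `"random"`, `"modular"` or `"smallworld"`.
#' @param seed integer seed; the network is deterministic given it.
#' @param n_blocks number of planted blocks for `"modular"`.
#' @param within_weight sampling weight of within-block pairs relative to
#'   between-block pairs for `"modular"`.
#' @param rewire_p rewiring probability for `"smallworld"`.
#' @return A [binary_network()] with region ids `r001...`.
#' @export
make_ground_truth <- function(n_regions, density_pct,
                              style = c("random", "modular", "smallworld"),
                              seed = 1L, n_blocks = 2, within_weight = 8,
                              rewire_p = 0.05) {
  style <- match.arg(style)
  m <- target_edges(n_regions, density_pct)   # errors on infeasible density
  ids <- default_region_ids(n_regions)
  pairs <- upper_pairs(n_regions)
  adj <- withr::with_seed(as.integer(seed), {
    a <- matrix(0, n_regions, n_regions)
    if (style == "random") {
      pick <- sample(nrow(pairs), m)
      a[pairs[pick, , drop = FALSE]] <- 1
    } else if (style == "modular") {
      block <- rep(seq_len(n_blocks), length.out = n_regions)
      w <- ifelse(block[pairs[, 1]] == block[pairs[, 2]], within_weight, 1)
      pick <- sample(nrow(pairs), m, prob = w)
      a[pairs[pick, , drop = FALSE]] <- 1
    } else {
      nei <- max(1, round(m / n_regions))
      g <- igraph::sample_smallworld(1, n_regions, nei, rewire_p)
      g <- igraph::simplify(g)
      a[igraph::as_edgelist(g, names = FALSE)] <- 1
      a[lower.tri(a)] <- 0
      a <- (a + t(a)) > 0
      a <- a * 1
      a[lower.tri(a)] <- 0
      # repair to the exact edge count
      on_idx <- which(a[pairs] == 1)
      off_idx <- which(a[pairs] == 0)
      if (length(on_idx) > m) {
        drop <- sample(on_idx, length(on_idx) - m)
        a[pairs[drop, , drop = FALSE]] <- 0
      } else if (length(on_idx) < m) {
        add <- sample(off_idx, m - length(on_idx))
        a[pairs[add, , drop = FALSE]] <- 1
      }
    }
    a + t(a)
  })
  binary_network(adj, region_ids = ids, density_target = density_pct)
}

#' Specification of one synthetic subject's signal model
#'
#' Signals are zero-mean multivariate normal with covariance
#' \eqn{\Sigma = I + c A} (`A` the ground-truth adjacency, `c` the coupling
#' strength), so a planted edge shows up as a population correlation of
#' about `c / (1 + noise_sd^2)` after independent observation noise is
#' added.  Optional bursts inject transient shared noise into a random
#' subset of regions: within each burst window the affected regions receive
#' the same noise sequence, creating the spurious transient correlations
#' that motivate window voting.  `Sigma` is repaired to positive definite by
#' flooring eigenvalues at 1e-6 when dense ground truths at high coupling
#' push it indefinite.
#'
#' @param ground_truth a [binary_network()].
#' @param n_timepoints series length `L`.
#' @param coupling_strength `c >= 0`.
#' @param noise_sd standard deviation of independent observation noise.
#' @param burst `NULL` or a list with `n_bursts`, `burst_length`,
#'   `burst_sd` (and optionally `frac_regions`, default 0.5).
#' @param seed integer seed.
#' @return A `synthetic_spec` carrying the validated covariance.
#' @export
synthetic_spec <- function(ground_truth, n_timepoints, coupling_strength = 0.6,
                           noise_sd = 0.3, burst = NULL, seed = 1L) {
  stopifnot(inherits(ground_truth, "binary_network"))
  assert_scalar_number(n_timepoints, "n_timepoints", min = 3)
  assert_scalar_number(coupling_strength, "coupling_strength", min = 0)
  assert_scalar_number(noise_sd, "noise_sd", min = 0)
  n <- length(ground_truth$region_ids)
  Sigma <- diag(n) + coupling_strength * ground_truth$adjacency
  ev <- eigen(Sigma, symmetric = TRUE)
  if (min(ev$values) < 1e-6) {
    vals <- pmax(ev$values, 1e-6)
    Sigma <- ev$vectors %*% diag(vals) %*% t(ev$vectors)
    Sigma <- (Sigma + t(Sigma)) / 2
    if (min(eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values) <= 0)
      stop(sprintf("covariance not positive definite after repair (min eigenvalue %g)",
                   min(ev$values)), call. = FALSE)
  }
  if (!is.null(burst)) {
    stopifnot(all(c("n_bursts", "burst_length", "burst_sd") %in% names(burst)))
    if (is.null(burst$frac_regions)) burst$frac_regions <- 0.5
    if (burst$burst_length > n_timepoints)
      stop("burst_length exceeds the series length", call. = FALSE)
  }
  structure(list(ground_truth = ground_truth, n_regions = n,
                 n_timepoints = as.integer(n_timepoints),
                 coupling_strength = coupling_strength, noise_sd = noise_sd,
                 burst = burst, Sigma = Sigma, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Simulate one subject's regional time courses
#'
#' @param spec a [synthetic_spec()].
#' @param subject_id subject identifier.
#' @param seed overrides the spec's seed (used by [simulate_cohort()] to
#'   vary subjects while keeping the cohort deterministic).
#' @return A [timecourse_matrix()], `L` rows x `N` regions, fully
#'   deterministic given `(spec, seed)`.
#' @export
simulate_subject <- function(spec, subject_id = "synthetic", seed = spec$seed) {
  stopifnot(inherits(spec, "synthetic_spec"))
  L <- spec$n_timepoints; n <- spec$n_regions
  X <- withr::with_seed(as.integer(seed), {
    x <- MASS::mvrnorm(L, mu = rep(0, n), Sigma = spec$Sigma)
    if (spec$noise_sd > 0)
      x <- x + matrix(stats::rnorm(L * n, sd = spec$noise_sd), L, n)
    if (!is.null(spec$burst)) {
      b <- spec$burst
      for (bi in seq_len(b$n_bursts)) {
        start <- sample(L - b$burst_length + 1L, 1)
        rows <- start:(start + b$burst_length - 1L)
        regs <- sample(n, max(2, ceiling(b$frac_regions * n)))
        shared <- stats::rnorm(b$burst_length, sd = b$burst_sd)
        x[rows, regs] <- x[rows, regs] + shared
      }
    }
    x
  })
  timecourse_matrix(X, region_ids = spec$ground_truth$region_ids,
                    subject_id = subject_id)
}

#' Simulate a balanced two-group cohort
#'
#' Each group's subjects share that group's ground-truth network and spec;
#' per-subject noise (and bursts) differ through per-subject seeds derived
#' from `seed`.
#'
#' @param spec_a,spec_b [synthetic_spec()]s for groups A and B; must share
#'   `n_regions` and `n_timepoints`.
#' @param n_per_group subjects per group.
#' @param seed integer cohort seed.
#' @return List with `cohort` (a [cohort()]), and `truth` (the two
#'   ground-truth networks, named by group).
#' @export
simulate_cohort <- function(spec_a, spec_b, n_per_group, seed = 1L) {
  stopifnot(inherits(spec_a, "synthetic_spec"), inherits(spec_b, "synthetic_spec"))
  if (spec_a$n_regions != spec_b$n_regions ||
      spec_a$n_timepoints != spec_b$n_timepoints)
    stop("group specs must share n_regions and n_timepoints", call. = FALSE)
  seed <- as.integer(seed)
  tcs <- list(); groups <- character(0)
  for (i in seq_len(n_per_group)) {
    tcs[[length(tcs) + 1L]] <- simulate_subject(
      spec_a, sprintf("A%02d", i), seed = seed + i)
    groups <- c(groups, "A")
    tcs[[length(tcs) + 1L]] <- simulate_subject(
      spec_b, sprintf("B%02d", i), seed = seed + n_per_group + i)
    groups <- c(groups, "B")
  }
  list(cohort = cohort(tcs, groups),
       truth = list(A = spec_a$ground_truth, B = spec_b$ground_truth))
}

#' Synthetic region table on a 3-D grid
#'
#' Centroids are laid out on a regular 3-D lattice with `spacing_mm`
#' between neighbours, giving the long-edge counter honest geometry without
#' any anatomical claim.
#'
#' @param region_ids character vector of region labels.
#' @param spacing_mm lattice spacing in millimetres.
#' @return A [region_table()].
#' @export
synthetic_regions <- function(region_ids, spacing_mm = 20) {
  n <- length(region_ids)
  side <- ceiling(n^(1 / 3))
  coords <- expand.grid(x = seq_len(side), y = seq_len(side), z = seq_len(side))
  coords <- coords[seq_len(n), ] * spacing_mm
  region_table(data.frame(
    region_id = region_ids, name = paste0("synthetic_", region_ids),
    hemisphere = rep(c("left", "right"), length.out = n),
    x = coords$x, y = coords$y, z = coords$z,
    stringsAsFactors = FALSE))
}

#' Write a synthetic cohort to disk
#'
#' Emits one TSV of time courses per subject, a `manifest.csv`
#' (subject_id, group, path), a `regions.csv` with synthetic centroids and
#' the ground-truth edge lists — the on-disk layout the CLI and
#' [load_cohort()] consume.
#'
#' @param sim result of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(sim$cohort$subjects, function(s) {
    fn <- paste0(s$subject_id, ".tsv")
    utils::write.table(unclass(s$tc), file.path(dir, fn), sep = "\t",
                       row.names = FALSE, col.names = colnames(s$tc),
                       quote = FALSE)
    data.frame(subject_id = s$subject_id, group = s$group, path = fn)
  })
  utils::write.csv(do.call(rbind, rows), file.path(dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  ids <- sim$truth$A$region_ids
  utils::write.csv(synthetic_regions(ids), file.path(dir, "regions.csv"),
                   row.names = FALSE, quote = FALSE)
  for (g in names(sim$truth))
    save_network(sim$truth[[g]], file.path(dir, sprintf("truth_%s.edgelist", g)),
                 format = "edgelist")
  invisible(dir)
}

#' Jaccard similarity between recovered and planted edge sets
#'
#' \eqn{|E_{rec} \cap E_{true}| / |E_{rec} \cup E_{true}|}; 1 when both
#' edge sets are identical (including both empty), 0 when disjoint.
#'
#' @param recovered,truth [binary_network()]s over the same regions.
#' @return Jaccard index in \[0, 1\].
#' @export
edge_recovery_score <- function(recovered, truth) {
  stopifnot(inherits(recovered, "binary_network"),
            inherits(truth, "binary_network"))
  if (!identical(recovered$region_ids, truth$region_ids))
    stop("networks must share the same regions in the same order",
         call. = FALSE)
  up <- upper.tri(truth$adjacency)
  inter <- sum(recovered$adjacency[up] == 1 & truth$adjacency[up] == 1)
  union <- sum(recovered$adjacency[up] == 1 | truth$adjacency[up] == 1)
  if (union == 0) return(1)
  inter / union
}
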