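# Independent brute-force oracles and small fixtures.  Everything here is
# deliberately written from first principles (definitional sums, explicit
# BFS, exhaustive enumeration) so the oracles never share code with the
# package paths they check.

random_tc <- function(L, N, seed) {
  withr::with_seed(seed,
    timecourse_matrix(matrix(rnorm(L * N), L, N),
                      subject_id = sprintf("rtc%d", seed)))
}

random_adjacency <- function(n, p, seed) {
  withr::with_seed(seed, {
    a <- matrix(0, n, n)
    up <- which(upper.tri(a))
    a[up] <- rbinom(length(up), 1, p)
    a + t(a)
  })
}

net_from_edges <- function(ids, edges) {
  n <- length(ids)
  a <- matrix(0, n, n, dimnames = list(ids, ids))
  for (e in edges) a[e[1], e[2]] <- a[e[2], e[1]] <- 1
  binary_network(a, region_ids = ids)
}

# textbook Pearson coefficient from definitional sums
oracle_pearson <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

# all-pairs hop distances by explicit breadth-first search
oracle_distances <- function(adj) {
  n <- nrow(adj)
  D <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    dist <- rep(Inf, n); dist[s] <- 0
    frontier <- s
    while (length(frontier)) {
      nxt <- integer(0)
      for (v in frontier) {
        for (w in which(adj[v, ] == 1)) {
          if (dist[w] > dist[v] + 1) { dist[w] <- dist[v] + 1; nxt <- c(nxt, w) }
        }
      }
      frontier <- unique(nxt)
    }
    D[s, ] <- dist
  }
  D
}

oracle_efficiency <- function(adj) {
  n <- nrow(adj)
  D <- oracle_distances(adj)
  inv <- 1 / D
  diag(inv) <- 0
  inv[is.infinite(D)] <- 0
  sum(inv) / (n * (n - 1))
}

oracle_clustering <- function(adj) {
  n <- nrow(adj)
  cc <- vapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] == 1)
    k <- length(nb)
    if (k < 2) return(0)
    links <- 0
    for (a in seq_along(nb)) for (b in seq_along(nb)) {
      if (a < b && adj[nb[a], nb[b]] == 1) links <- links + 1
    }
    2 * links / (k * (k - 1))
  }, 0)
  mean(cc)
}

oracle_transitivity <- function(adj) {
  n <- nrow(adj)
  triangles <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n)) {
    if (i < j && j < k &&
        adj[i, j] == 1 && adj[j, k] == 1 && adj[i, k] == 1)
      triangles <- triangles + 1
  }
  # connected triplets = paths of length 2 centred at each node
  triplets <- sum(vapply(seq_len(n), function(v) {
    k <- sum(adj[v, ]); k * (k - 1) / 2
  }, 0))
  if (triplets == 0) return(0)
  3 * triangles / triplets
}

# Benjamini-Hochberg step-up by exhaustive search over k
oracle_bh <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  kmax <- 0
  for (k in seq_len(m)) if (ps[k] <= k * q / m) kmax <- k
  rej <- rep(FALSE, m)
  if (kmax > 0) rej[ord[seq_len(kmax)]] <- TRUE
  rej
}

# step-by-step SNV re-implementation: window loop, per-window ranking by a
# sorted pair table, vote accumulation, final ranking with |C| tie-break
oracle_snv <- function(tc, W, nd_pct) {
  vals <- unclass(tc)
  L <- nrow(vals); n <- ncol(vals)
  k_edges <- floor(nd_pct / 100 * n * (n - 1) / 2 + 0.5)
  pair_tab <- expand.grid(i = seq_len(n), j = seq_len(n))
  pair_tab <- pair_tab[pair_tab$i < pair_tab$j, ]
  votes <- rep(0, nrow(pair_tab))
  wsum <- rep(0, nrow(pair_tab))
  for (s in 1:(L - W + 1)) {
    win <- vals[s:(s + W - 1), , drop = FALSE]
    r <- mapply(function(i, j) oracle_pearson(win[, i], win[, j]),
                pair_tab$i, pair_tab$j)
    ord <- order(-abs(r), -abs(r), pair_tab$i, pair_tab$j)
    sel <- ord[seq_len(k_edges)]
    votes[sel] <- votes[sel] + 1
    wsum <- wsum + abs(r)
  }
  ord <- order(-votes, -wsum, pair_tab$i, pair_tab$j)
  sel <- ord[seq_len(k_edges)]
  a <- matrix(0, n, n, dimnames = list(colnames(tc), colnames(tc)))
  a[cbind(pair_tab$i[sel], pair_tab$j[sel])] <- 1
  binary_network(a + t(a), region_ids = colnames(tc))
}

# shared small fixtures
fixture_regions <- function(ids) synthetic_regions(ids)
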