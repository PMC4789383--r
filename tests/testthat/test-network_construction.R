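test_that("sliding windows have the forced count, span and stride", {
  tc128 <- random_tc(128, 4, seed = 1)
  expect_length(extract_subseries(tc128, 90), 39)   # 128 - 90 + 1

  strip <- function(x) { x <- unclass(x); attr(x, "subject_id") <- NULL; x }
  tc10 <- random_tc(10, 3, seed = 2)
  wins <- extract_subseries(tc10, 4)
  expect_length(wins, 7)
  expect_equal(strip(wins[[3]]), strip(tc10)[3:6, ])  # rows 3-6, 1-based

  # W = L is a single window equal to the input
  whole <- extract_subseries(tc10, 10)
  expect_length(whole, 1)
  expect_equal(strip(whole[[1]]), strip(tc10))

  expect_error(extract_subseries(tc10, 11), "window_width")
  expect_error(extract_subseries(tc10, 2), "window_width")
})

test_that("pearson_correlation matches the definitional sum formula", {
  x <- c(1, 2, 3, 5); y <- c(2, 4, 6, 9)
  tc <- timecourse_matrix(cbind(a = x, b = y, c = c(9, 1, 4, 7)))
  C <- pearson_correlation(tc)
  expect_equal(C["a", "b"], oracle_pearson(x, y), tolerance = 1e-12)
  expect_equal(C["a", "c"], oracle_pearson(x, c(9, 1, 4, 7)), tolerance = 1e-12)
  expect_equal(diag(unclass(C)), c(a = 1, b = 1, c = 1))
  expect_equal(unclass(C), t(unclass(C)))

  # identical and sign-flipped columns hit the extremes
  tc2 <- timecourse_matrix(cbind(p = x, q = x + 0, r = -x), )
  C2 <- pearson_correlation(tc2)
  expect_equal(C2["p", "q"], 1)
  expect_equal(C2["p", "r"], -1)

  # a window-level zero-variance region names subject and region
  tcw <- timecourse_matrix(cbind(u = c(1, 1, 1, 2), v = c(4, 2, 7, 1)),
                           subject_id = "subj9")
  win <- extract_subseries(tcw, 3)[[1]]
  expect_error(pearson_correlation(win), "u.*subj9")
})

test_that("density thresholding keeps exactly the top-ranked pairs", {
  # 4 regions with upper-triangle |values| {0.9,0.8,0.7,0.3,0.2,0.1}:
  # at 50% exactly the three largest survive
  M <- matrix(0, 4, 4)
  M[1, 2] <- 0.9; M[1, 3] <- -0.8; M[1, 4] <- 0.7
  M[2, 3] <- 0.3; M[2, 4] <- -0.2; M[3, 4] <- 0.1
  M <- M + t(M); diag(M) <- 1
  net <- threshold_to_density(M, 50)
  expect_equal(net$edge_count, 3)
  expect_equal(net$adjacency[1, 2], 1)
  expect_equal(net$adjacency[1, 3], 1)   # |-0.8| ranks by magnitude
  expect_equal(net$adjacency[1, 4], 1)
  expect_equal(net$adjacency[2, 3], 0)

  # full density gives the complete graph
  expect_equal(threshold_to_density(M, 100)$edge_count, 6)

  # marginal tie resolved by the larger tie weight
  Mt <- matrix(0, 3, 3)
  Mt[1, 2] <- 0.9; Mt[1, 3] <- 0.5; Mt[2, 3] <- 0.5
  Mt <- Mt + t(Mt)
  tw <- matrix(0, 3, 3); tw[1, 3] <- 4; tw[2, 3] <- 5
  tw <- tw + t(tw)
  net_t <- threshold_to_density(Mt, 67, tie_weights = tw)  # 2 of 3 pairs
  expect_equal(net_t$edge_count, 2)
  expect_equal(net_t$adjacency[2, 3], 1)   # weight 5 beats weight 4
  expect_equal(net_t$adjacency[1, 3], 0)

  expect_error(threshold_to_density(matrix(rnorm(9), 3, 3), 50), "symmetric")
  expect_error(threshold_to_density(Mt, 0.1), "0 edges")
})

test_that("rounding of the proportional edge count is half-up", {
  expect_equal(target_edges(90, 8), 320L)     # 0.08 * 4005 = 320.4
  expect_equal(target_edges(90, 10), 401L)    # 400.5 rounds up
  expect_equal(target_edges(4, 50), 3L)
  expect_error(target_edges(90, 0.001), "0 edges")
})

test_that("both methods hit the target density exactly across the grid", {
  tc <- random_tc(40, 12, seed = 7)
  for (nd in 8:16) {
    expect_equal(classic_construct(tc, nd)$edge_count, target_edges(12, nd))
    expect_equal(snv_construct(tc, 20, nd)$edge_count, target_edges(12, nd))
  }
})

test_that("SNV with a full-length window degenerates to the classic method", {
  for (seed in 1:10) {
    tc <- random_tc(30, 10, seed = 100 + seed)
    for (nd in c(8, 12, 16)) {
      expect_true(snv_construct(tc, 30, nd) == classic_construct(tc, nd))
    }
  }
})

test_that("the SNV pipeline equals an independent step-by-step oracle", {
  # hand-traceable scale: L=20, N=5, W=10, density 20%
  tc <- random_tc(20, 5, seed = 42)
  expect_true(snv_construct(tc, 10, 20) == oracle_snv(tc, 10, 20))
  # and at other scales/densities
  for (seed in c(3, 9)) {
    tc2 <- random_tc(24, 7, seed = seed)
    for (nd in c(10, 25))
      expect_true(snv_construct(tc2, 12, nd) == oracle_snv(tc2, 12, nd))
  }
})

test_that("the voting state is bounded, symmetric and exposed", {
  tc <- random_tc(30, 8, seed = 5)
  net <- snv_construct(tc, 21, 12)
  vs <- voting_state(net)
  K <- 30 - 21 + 1
  expect_equal(vs$window_count, K)
  expect_true(all(vs$votes >= 0 & vs$votes <= K))
  expect_true(all(vs$weight_sum >= 0 & vs$weight_sum <= K + 1e-9))
  expect_equal(vs$votes, t(vs$votes))
  expect_equal(diag(vs$votes), setNames(rep(0, 8), colnames(tc)))
  expect_error(voting_state(classic_construct(tc, 12)), "voting state")
})

test_that("networks are invariant to affine rescaling of any region", {
  tc <- random_tc(36, 6, seed = 13)
  scaled <- unclass(tc)
  scaled[, 2] <- 3.7 * scaled[, 2] + 11
  scaled[, 5] <- 0.01 * scaled[, 5] - 4
  tc2 <- timecourse_matrix(scaled, subject_id = "scaled")
  expect_true(classic_construct(tc, 12) == classic_construct(tc2, 12))
  expect_true(snv_construct(tc, 18, 12) == snv_construct(tc2, 18, 12))
})

test_that("edge sets nest monotonically across densities", {
  for (seed in 1:50) {
    M <- withr::with_seed(seed, {
      m <- matrix(runif(100), 10, 10) * random_adjacency(10, 0.5, seed = seed)
      (m + t(m)) / 2
    })
    diag(M) <- 1
    lo <- threshold_to_density(M, 8)$adjacency
    hi <- threshold_to_density(M, 16)$adjacency
    expect_true(all(hi[lo == 1] == 1))
  }
})
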