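# shared synthetic feature fixture: 2 x n_per balanced cohort summaries
make_summaries <- function(n_per, shift = 0, seed = 1, n_regions = 8,
                           shift_node = NULL, node_shift = 0) {
  withr::with_seed(seed, {
    ids <- c(sprintf("A%02d", 1:n_per), sprintf("B%02d", 1:n_per))
    groups <- setNames(rep(c("A", "B"), each = n_per), ids)
    props <- c("global_efficiency", "mean_clustering", "transfer_coefficient",
               "small_world_value", "long_edge_count")
    metrics <- matrix(rnorm(2 * n_per * 5), ncol = 5,
                      dimnames = list(ids, props))
    metrics[groups == "B", "global_efficiency"] <-
      metrics[groups == "B", "global_efficiency"] + shift
    degrees <- matrix(rpois(2 * n_per * n_regions, 5), ncol = n_regions,
                      dimnames = list(ids, sprintf("r%03d", 1:n_regions)))
    if (!is.null(shift_node))
      degrees[groups == "B", shift_node] <-
        degrees[groups == "B", shift_node] + node_shift
    list(metrics = metrics, degrees = degrees, groups = groups)
  })
}

test_that("fold plans pair one subject per group, deterministically", {
  tcs <- lapply(1:28, function(i) random_tc(10, 3, seed = 400 + i))
  ch <- cohort(tcs, rep(c("A", "B"), 14))
  plan <- make_fold_plan(ch, 14, seed = 6)
  expect_length(plan$folds, 14)
  for (f in plan$folds)
    expect_setequal(unname(plan$groups[f]), c("A", "B"))
  # partition: every subject in exactly one fold
  expect_setequal(unlist(plan$folds), names(plan$groups))
  expect_identical(plan$folds, make_fold_plan(ch, 14, seed = 6)$folds)
  expect_false(identical(plan$folds, make_fold_plan(ch, 14, seed = 7)$folds))
  ch_bad <- cohort(tcs[1:7], c(rep("A", 3), rep("B", 4)))
  expect_error(make_fold_plan(ch_bad, 4), "per group")
})

test_that("min-max scaling uses training bounds only, with clipping", {
  train <- cbind(f1 = c(2, 4, 6), f2 = c(1, 1, 1))
  test <- cbind(f1 = c(0, 5, 10), f2 = c(0, 1, 2))
  sc <- scale_features(train, test)
  expect_equal(unname(sc$train[, "f1"]), c(0, 0.5, 1))
  expect_equal(unname(sc$test[, "f1"]), c(0, 0.75, 1))  # clipped at both ends
  expect_equal(unname(sc$train[, "f2"]), rep(0.5, 3))   # constant feature
  expect_equal(unname(sc$test[, "f2"]), rep(0.5, 3))
})

test_that("feature assembly follows the canonical order and the fallback", {
  s <- make_summaries(5, seed = 2)
  g5 <- build_features(s$metrics, s$degrees, "global5")
  expect_equal(colnames(g5),
               c("global_efficiency", "mean_clustering", "transfer_coefficient",
                 "small_world_value", "long_edge_count"))
  opt <- build_features(s$metrics, s$degrees, "optimized",
                        selected_nodes = c("r003", "r001"))
  expect_equal(colnames(opt),
               c("global_efficiency", "mean_clustering", "transfer_coefficient",
                 "long_edge_count", "r001", "r003"))   # degrees sorted by id
  expect_message(fb <- build_features(s$metrics, s$degrees, "optimized",
                                      selected_nodes = character(0)),
                 "falling back")
  expect_equal(ncol(fb), 4)
})

test_that("degree-node selection recovers a planted single-node difference", {
  s <- make_summaries(10, seed = 5, shift_node = "r004", node_shift = 12)
  sel <- select_degree_nodes(s$degrees, s$groups, q = 0.05)
  expect_equal(sel, "r004")
  # identical training groups select nothing
  s0 <- make_summaries(10, seed = 8)
  expect_length(select_degree_nodes(s0$degrees, s0$groups, q = 0.05), 0)
})

# cohort whose subject ids match make_summaries (A01.., B01..)
summary_cohort <- function(n_per, seed0 = 500) {
  ids <- as.vector(rbind(sprintf("A%02d", 1:n_per), sprintf("B%02d", 1:n_per)))
  tcs <- lapply(seq_along(ids), function(i) {
    tc <- random_tc(10, 3, seed = seed0 + i)
    attr(tc, "subject_id") <- ids[i]
    tc
  })
  cohort(tcs, rep(c("A", "B"), n_per))
}

test_that("cross-validation is perfect on separable data, chance on null data", {
  ch <- summary_cohort(10)
  plan <- make_fold_plan(ch, 10, seed = 1)

  # group means 3+ SDs apart on one feature: accuracy 1
  sep <- make_summaries(10, shift = 6, seed = 3)
  sc <- svm_crossval(sep$metrics, sep$degrees, sep$groups, plan, "global5")
  expect_equal(sc$accuracy, 1)
  expect_equal(sc$sensitivity, 1)
  expect_equal(sc$specificity, 1)

  # no group signal: mean accuracy near 0.5 across seeds
  accs <- vapply(1:50, function(seed) {
    nul <- make_summaries(10, shift = 0, seed = 100 + seed)
    svm_crossval(nul$metrics, nul$degrees, nul$groups, plan,
                 "global5")$accuracy
  }, 0)
  expect_gt(mean(accs), 0.4)
  expect_lt(mean(accs), 0.6)
})

test_that("balanced folds tie accuracy to (sensitivity + specificity) / 2", {
  s <- make_summaries(8, shift = 1.2, seed = 12)
  plan <- make_fold_plan(summary_cohort(8, seed0 = 600), 8, seed = 2)
  sc <- svm_crossval(s$metrics, s$degrees, s$groups, plan, "global5")
  expect_equal(sc$accuracy, (sc$sensitivity + sc$specificity) / 2)
  expect_true(all(sc$folds$accuracy >= 0 & sc$folds$accuracy <= 1))
})

test_that("nothing leaks from the test fold into selection or scaling", {
  s <- make_summaries(8, shift = 1, seed = 30, shift_node = "r002",
                      node_shift = 10)
  test_ids <- c("A01", "B01")
  train_ids <- setdiff(rownames(s$metrics), test_ids)
  sel_before <- select_degree_nodes(s$degrees[train_ids, ], s$groups[train_ids])
  ftr <- build_features(s$metrics, s$degrees, "global5")
  sc_before <- scale_features(ftr[train_ids, ], ftr[test_ids, ])$bounds

  # perturb the held-out subjects wildly
  s$metrics[test_ids, ] <- s$metrics[test_ids, ] + 1e3
  s$degrees[test_ids, ] <- s$degrees[test_ids, ] + 1e3
  sel_after <- select_degree_nodes(s$degrees[train_ids, ], s$groups[train_ids])
  ftr2 <- build_features(s$metrics, s$degrees, "global5")
  sc_after <- scale_features(ftr2[train_ids, ], ftr2[test_ids, ])$bounds
  expect_identical(sel_before, sel_after)
  expect_identical(sc_before, sc_after)
})

test_that("score permutation test is oriented for higher-is-better", {
  # uniform +0.1 advantage over 9 densities: matches the 2^9 enumeration
  res <- permutation_test_scores(rep(0.6, 9), rep(0.7, 9),
                                 n_perm = 20000, seed = 2)
  expect_lt(abs(res$p - (1 + 20000 / 512) / 20001), 1.5e-3)
  expect_equal(permutation_test_scores(rep(0.7, 9), rep(0.7, 9))$p, 1)
  r1 <- permutation_test_scores(1:5 / 10, 5:1 / 10, n_perm = 1000, seed = 5)
  r2 <- permutation_test_scores(1:5 / 10, 5:1 / 10, n_perm = 1000, seed = 5)
  expect_identical(r1$p, r2$p)
})
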