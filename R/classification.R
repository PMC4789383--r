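#' Paired fold plan for balanced two-group cross-validation
#'
#' Randomly pairs one subject of each group into every fold, so training
#' sets stay perfectly balanced in every loop.
#'
#' @param ch a [cohort()] with exactly `n_folds` subjects per group.
#' @param n_folds number of folds `K` (14 for a 14+14 cohort).
#' @param seed integer seed; the plan is deterministic given it.
#' @return `fold_plan`: list with `folds` (each a character vector of the
#'   two subject ids), `groups` (named group labels) and `seed`.
#' @export
make_fold_plan <- function(ch, n_folds, seed = 1L) {
  stopifnot(inherits(ch, "cohort"))
  groups <- cohort_groups(ch)
  gl <- sort(unique(groups))
  ids_a <- names(groups)[groups == gl[1]]
  ids_b <- names(groups)[groups == gl[2]]
  if (length(ids_a) != n_folds || length(ids_b) != n_folds)
    stop(sprintf("need exactly %d subjects per group, got %d + %d",
                 n_folds, length(ids_a), length(ids_b)), call. = FALSE)
  pairs <- withr::with_seed(as.integer(seed),
                            cbind(sample(ids_a), sample(ids_b)))
  folds <- lapply(seq_len(n_folds), function(i) unname(pairs[i, ]))
  structure(list(folds = folds, groups = groups, seed = as.integer(seed)),
            class = "fold_plan")
}

#' Select degree features that differ between groups
#'
#' Per-node two-sample t-test of degrees between the two groups, BH-FDR
#' across nodes at level `q`; the surviving nodes' degrees become extra
#' classification features.  Run on training subjects only, never on the
#' held-out fold.
#'
#' @param degrees numeric matrix, subjects x regions (rownames = subject
#'   ids, colnames = region ids).
#' @param groups named group labels for the rows of `degrees`.
#' @param q FDR level.
#' @param welch use Welch t-tests.
#' @return Character vector of selected region ids (possibly empty).
#' @export
select_degree_nodes <- function(degrees, groups, q = 0.05, welch = FALSE) {
  groups <- groups[rownames(degrees)]
  gl <- sort(unique(groups))
  stopifnot(length(gl) == 2)
  p <- apply(degrees, 2, function(col) {
    a <- col[groups == gl[1]]; b <- col[groups == gl[2]]
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      if (mean(a) == mean(b)) 1 else 0
    } else two_sample_ttest(a, b, welch = welch)$p
  })
  colnames(degrees)[fdr_bh(p, q)]
}

#' Assemble a feature matrix from per-subject network summaries
#'
#' Two feature sets are supported.  `"global5"` uses the five global
#' properties in canonical order (efficiency, clustering, transfer,
#' small-world, long edges).  `"optimized"` drops the small-world value
#' (the property that shows no group difference) and appends the degrees of
#' `selected_nodes`, sorted by region id; with an empty selection it falls
#' back to the four global features with a notice.
#'
#' @param metrics numeric matrix, subjects x 5 global properties (columns
#'   `global_efficiency`, `mean_clustering`, `transfer_coefficient`,
#'   `small_world_value`, `long_edge_count`).
#' @param degrees numeric matrix, subjects x regions.
#' @param kind `"global5"` or `"optimized"`.
#' @param selected_nodes region ids whose degrees are appended (optimized
#'   only; typically from [select_degree_nodes()] on the training split).
#' @return Numeric feature matrix with subjects as rows.
#' @export
build_features <- function(metrics, degrees = NULL,
                           kind = c("global5", "optimized"),
                           selected_nodes = NULL) {
  kind <- match.arg(kind)
  canon <- c("global_efficiency", "mean_clustering", "transfer_coefficient",
             "small_world_value", "long_edge_count")
  stopifnot(all(canon %in% colnames(metrics)))
  if (kind == "global5") return(metrics[, canon, drop = FALSE])
  base4 <- metrics[, setdiff(canon, "small_world_value"), drop = FALSE]
  if (is.null(selected_nodes) || length(selected_nodes) == 0) {
    message("no significant degree nodes; falling back to 4 global features")
    return(base4)
  }
  stopifnot(!is.null(degrees), all(selected_nodes %in% colnames(degrees)))
  sel <- sort(selected_nodes)
  cbind(base4, degrees[rownames(metrics), sel, drop = FALSE])
}

#' Min-max scale features from training bounds
#'
#' Each feature is mapped to \[0, 1\] using the minimum and maximum of the
#' TRAINING rows only; test values are transformed with the training bounds
#' and clipped to \[0, 1\].  A constant training feature maps to 0.5
#' everywhere (it carries no information, and 0.5 keeps it neutral).
#'
#' @param train,test numeric feature matrices with identical columns;
#'   `train` needs >= 2 rows.
#' @return List with scaled `train` and `test` matrices and the `bounds`
#'   used (rows `min`, `max`).
#' @export
scale_features <- function(train, test) {
  stopifnot(is.matrix(train), nrow(train) >= 2,
            is.matrix(test), ncol(test) == ncol(train))
  lo <- apply(train, 2, min)
  hi <- apply(train, 2, max)
  rng <- hi - lo
  sc <- function(m) {
    out <- sweep(sweep(m, 2, lo, "-"), 2, ifelse(rng == 0, 1, rng), "/")
    out[, rng == 0] <- 0.5
    out[out < 0] <- 0; out[out > 1] <- 1
    out
  }
  list(train = sc(train), test = sc(test), bounds = rbind(min = lo, max = hi))
}

#' Linear-SVM cross-validation over a paired fold plan
#'
#' In each of the `K` loops, one fold (one subject per group) is held out;
#' features are assembled from the remaining training subjects — for the
#' optimized set the degree-node selection is recomputed inside every loop
#' from training subjects only, so no information leaks from the test fold —
#' min-max scaled with training bounds, and a linear SVM (cost 1, no class
#' weighting) is fit and applied to the held-out pair.  Accuracy,
#' sensitivity and specificity are computed per loop on its two subjects and
#' averaged over loops.
#'
#' @param metrics numeric matrix, subjects x 5 global properties.
#' @param degrees numeric matrix, subjects x regions (needed for
#'   `"optimized"`).
#' @param groups named group labels for all subjects.
#' @param plan a [make_fold_plan()].
#' @param kind feature set, `"global5"` or `"optimized"`.
#' @param q FDR level for the degree-node selection.
#' @param positive group treated as positive for sensitivity (default the
#'   second group label in sort order, i.e. "B" = elderly in the package's
#'   convention; this is a convention, not a property of the data).
#' @param cost SVM regularization parameter.
#' @return `classifier_score`: list with `accuracy`, `sensitivity`,
#'   `specificity` (fold averages), per-fold table `folds`, the feature
#'   `kind` and `positive` class.
#' @export
svm_crossval <- function(metrics, degrees = NULL, groups, plan,
                         kind = c("global5", "optimized"), q = 0.05,
                         positive = NULL, cost = 1) {
  kind <- match.arg(kind)
  stopifnot(inherits(plan, "fold_plan"))
  gl <- sort(unique(groups))
  stopifnot(length(gl) == 2)
  if (is.null(positive)) positive <- gl[2]
  stopifnot(positive %in% gl)
  negative <- setdiff(gl, positive)
  all_ids <- rownames(metrics)
  per_fold <- lapply(seq_along(plan$folds), function(fi) {
    test_ids <- plan$folds[[fi]]
    train_ids <- setdiff(all_ids, test_ids)
    sel <- NULL
    if (kind == "optimized")
      sel <- select_degree_nodes(degrees[train_ids, , drop = FALSE],
                                 groups[train_ids], q = q)
    ftr_train <- build_features(metrics[train_ids, , drop = FALSE], degrees,
                                kind, selected_nodes = sel)
    ftr_test <- build_features(metrics[test_ids, , drop = FALSE], degrees,
                               kind, selected_nodes = sel)
    sc <- scale_features(as.matrix(ftr_train), as.matrix(ftr_test))
    y <- factor(groups[train_ids], levels = gl)
    fit <- e1071::svm(x = sc$train, y = y, kernel = "linear", cost = cost,
                      scale = FALSE)
    pred <- as.character(stats::predict(fit, sc$test))
    truth <- groups[test_ids]
    tp <- sum(pred == positive & truth == positive)
    tn <- sum(pred == negative & truth == negative)
    data.frame(fold = fi,
               accuracy = mean(pred == truth),
               sensitivity = tp / sum(truth == positive),
               specificity = tn / sum(truth == negative),
               n_selected = length(sel))
  })
  folds <- do.call(rbind, per_fold)
  structure(list(accuracy = mean(folds$accuracy),
                 sensitivity = mean(folds$sensitivity),
                 specificity = mean(folds$specificity),
                 folds = folds, kind = kind, positive = positive),
            class = "classifier_score")
}

#' @export
print.classifier_score <- function(x, ...) {
  cat(sprintf("linear-SVM CV (%s, positive = %s): acc %.3f, sens %.3f, spec %.3f\n",
              x$kind, x$positive, x$accuracy, x$sensitivity, x$specificity))
  invisible(x)
}

#' Per-subject metrics and degrees for classification
#'
#' Constructs one network per subject by the chosen method at one
#' (window, density) setting and collects the five global properties and the
#' node degrees: the raw material for [svm_crossval()].
#'
#' @inheritParams property_grid
#' @param density_pct single density in percent.
#' @return List with `metrics` (subjects x 5 matrix), `degrees`
#'   (subjects x regions matrix) and `groups`.
#' @export
cohort_features <- function(ch, regions, method = c("classic", "snv"),
                            density_pct, window_width = NULL,
                            long_edge_mm = 75, n_null = 100, seed = 1L) {
  method <- match.arg(method)
  props <- c("global_efficiency", "mean_clustering", "transfer_coefficient",
             "small_world_value", "long_edge_count")
  ids <- names(ch$subjects)
  met <- matrix(NA_real_, length(ids), 5, dimnames = list(ids, props))
  deg <- NULL
  for (si in seq_along(ch$subjects)) {
    subj <- ch$subjects[[si]]
    net <- construct_network(subj$tc, method, density_pct, window_width)
    m <- network_metrics(net, regions, long_edge_mm = long_edge_mm,
                         n_null = n_null, seed = as.integer(seed) + si)
    met[si, ] <- unlist(m[props])
    d <- node_degrees(net)
    if (is.null(deg))
      deg <- matrix(NA_real_, length(ids), length(d),
                    dimnames = list(ids, names(d)))
    deg[si, ] <- d
  }
  list(metrics = met, degrees = deg, groups = cohort_groups(ch))
}

#' Permutation test for paired classification scores
#'
#' Sign-flip test on paired per-density score differences, oriented so a
#' small p means the SECOND score set is systematically HIGHER (scores are
#' higher-is-better, the mirror image of p-value profiles).
#'
#' @param score_a,score_b paired numeric score vectors (e.g. accuracy per
#'   density for the classic and SNV methods).
#' @param n_perm,seed see [paired_permutation_test()].
#' @return List with `statistic` (mean of `score_b - score_a`) and `p`.
#' @export
permutation_test_scores <- function(score_a, score_b, n_perm = 10000,
                                    seed = 1L) {
  paired_permutation_test(score_b, score_a, n_perm = n_perm, seed = seed)
}
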