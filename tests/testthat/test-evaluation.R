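test_that("stratified folds reproduce the canonical 1482-sample arithmetic", {
  labels <- rep(c(0, 1), each = 741)
  plan <- make_folds(labels, n_folds = 10, seed = 1)
  sizes <- tabulate(plan$assignments, 10)
  expect_equal(sort(sizes), c(rep(148, 8), rep(149, 2)))
  # training on the complement of a floor-size fold uses 1334 samples
  floor_fold <- which(sizes == 148)[1]
  expect_equal(sum(plan$assignments != floor_fold), 1334)
  # stratification: per-class fold counts differ by at most 1
  for (cls in 0:1) {
    per <- tabulate(plan$assignments[labels == cls], 10)
    expect_lte(diff(range(per)), 1)
  }
  # every sample tested exactly once, folds disjoint and exhaustive
  expect_equal(sort(unique(plan$assignments)), 1:10)
  expect_equal(length(plan$assignments), 1482)
})

test_that("fold assignment is deterministic and validates inputs", {
  labels <- rep(c(0, 1), 30)
  expect_identical(make_folds(labels, 10, seed = 4), make_folds(labels, 10, seed = 4))
  expect_false(identical(make_folds(labels, 10, seed = 4)$assignments,
                         make_folds(labels, 10, seed = 5)$assignments))
  # 10 samples in 10 folds degenerates to leave-one-out
  plan <- make_folds(rep(c(0, 1), 5), n_folds = 5, seed = 2)
  expect_equal(sort(tabulate(plan$assignments, 5)), rep(2, 5))
  expect_error(make_folds(c(0, 1), 3), "at least")
})

test_that("metrics match brute-force pair counting and sum to one", {
  m <- classification_metrics(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1))
  expect_equal(m$auc, 1.0)
  expect_equal(m$accuracy, 1.0)
  m2 <- classification_metrics(c(1, 0, 1, 0), rep(0.5, 4))
  expect_equal(m2$auc, 0.5)
  for (seed in 1:10) {
    set.seed(seed)
    y <- c(1, 1, rbinom(8, 1, 0.5), 0, 0)
    p <- round(runif(12), 1)   # coarse grid to force ties
    m <- classification_metrics(y, p)
    expect_equal(m$auc, oracle_auc(y, p))
    expect_equal(m$error_rate + m$accuracy, 1.0)
  }
  expect_error(classification_metrics(c(1, 1), c(0.2, 0.3)), "single class")
})

test_that("cross-validation separates an easy synthetic task and reports all folds", {
  ds <- simulate_dataset(tiny_sim_config(seed = 21))
  fm <- featurize_sim(ds)
  plan <- make_folds(fm$labels, n_folds = 5, seed = 21)
  rep <- cross_validate(fm, config = fast_model_config(seed = 21), fold_plan = plan)
  expect_equal(nrow(rep$per_fold), 5)
  expect_equal(sum(rep$per_fold$n_test), nrow(fm$X))
  expect_lte(rep$mean_error_rate, 0.02)
  expect_gt(rep$auc, 0.99)
  expect_equal(rep$per_fold$error_rate, 1 - rep$per_fold$accuracy)
})

test_that("permuted labels drive accuracy to chance", {
  ds <- simulate_dataset(tiny_sim_config(seed = 31))
  fm <- featurize_sim(ds)
  accs <- vapply(c(31, 32), function(s) {
    fm_null <- fm
    fm_null$labels <- with_seed_helper(s, sample(fm$labels))
    plan <- make_folds(fm_null$labels, n_folds = 5, seed = s)
    cross_validate(fm_null, config = fast_model_config(seed = s, bp_epochs = 30),
                   fold_plan = plan)$mean_accuracy
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 0.08)
})

test_that("the ablation protocol runs the four feature combinations on shared folds", {
  ds <- simulate_dataset(tiny_sim_config(seed = 41, histone_enrichment_fold = 1.3))
  fm <- featurize_sim(ds)
  plan <- make_folds(fm$labels, n_folds = 5, seed = 41)
  reports <- ablation_suite(fm, config = fast_model_config(seed = 41), fold_plan = plan)
  expect_named(reports, c("histone_sequence", "histone_sequence_gc",
                          "histone_sequence_methylation",
                          "histone_sequence_methylation_gc"))
  labs <- vapply(reports, function(r) r$combination, character(1))
  expect_true(all(grepl("^Histone \\+ Sequence", labs)))
  # identical folds across combinations
  for (r in reports) expect_identical(r$fold_plan$assignments, plan$assignments)
  # with planted methylation/GC signal, the full set does at least as well
  expect_lte(reports$histone_sequence_methylation_gc$mean_error_rate,
             reports$histone_sequence$mean_error_rate + 1e-9)

  fm_no_meth <- fm
  keep <- fm$families != "methylation"
  fm_no_meth$X <- fm$X[, keep]
  fm_no_meth$families <- fm$families[keep]
  expect_error(ablation_suite(fm_no_meth, fold_plan = plan), "methylation")
})

test_that("per-fold scaling is fitted on training rows only", {
  # a feature whose extremes sit in one fold: if the scaler saw the test
  # fold, its values could not exceed [0,1] pre-clipping; we assert the
  # structural contract instead - scale_features itself leaks nothing.
  X <- matrix(c(0, 1, 2, 3, 100, -50), ncol = 1,
              dimnames = list(NULL, "f"))
  fm <- structure(list(X = X, labels = c(0, 1, 0, 1, 0, 1),
                       families = "histone", scaling = "raw"),
                  class = "feature_matrix")
  sc <- scale_features(fm, fit_rows = 1:4)
  expect_equal(unname(sc$scaler$max), 3)   # max from fit rows, not global
  expect_equal(unname(sc$fm$X[5, 1]), 1)   # held-out clipped
  expect_equal(unname(sc$fm$X[6, 1]), 0)
})
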