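test_that("57 samples split into seven folds of 6 and three of 5", {
  lab <- rep(c("died", "discharged"), c(19, 38))
  folds <- make_folds(lab, 10, seed = 4)
  sizes <- as.vector(table(folds))
  expect_equal(sort(sizes), c(5, 5, 5, 6, 6, 6, 6, 6, 6, 6))
  expect_identical(as.integer(make_folds(lab, 10, seed = 4)),
                   as.integer(folds))
  expect_false(identical(as.integer(make_folds(lab, 10, seed = 5)),
                         as.integer(folds)))
})

test_that("stratified folds hold 1-2 of the 19 positives each, any seed", {
  lab <- rep(c("died", "discharged"), c(19, 38))
  for (seed in 1:100) {
    folds <- make_folds(lab, 10, seed = seed)
    per_fold <- table(factor(folds[lab == "died"], levels = 1:10))
    expect_true(all(per_fold %in% 1:2))
    # overall fold sizes stay within one sample of each other
    expect_lte(diff(range(table(folds))), 1)
  }
})

test_that("a class smaller than the fold count falls back with a warning", {
  lab <- rep(c("SAM", "healthy_control"), c(57, 7))
  expect_warning(folds <- make_folds(lab, 10, seed = 1), "unstratified")
  expect_equal(length(unique(folds)), 10)
  expect_error(make_folds(lab[1:5], 10), "folds for")
})

test_that("a perfectly separable signal gives AUC 1 for every family", {
  set.seed(41)
  n <- 24
  lab <- factor(rep(c("case", "control"), each = n / 2))
  X <- matrix(rnorm(n * 30), nrow = n)
  X[, 7] <- ifelse(lab == "case", 1, 0) * 10 + rnorm(n, sd = 0.01)
  attr(X, "feature_ids") <- seq_len(30)
  for (fam in c("random_forest", "gaussian_process",
                "support_vector_machine", "sparse_logistic_regression")) {
    cv <- run_cv(X, lab, classifier_spec(fam, hyper = list(ntree = 300)),
                 k = 5, n_folds = 6, seed = 42)
    expect_equal(cv_auc(cv), 1.0, info = fam)
  }
})

test_that("every sample is scored exactly once, with full provenance", {
  co <- simulate_cohort(tiny_config(), seed = 51)
  d <- comparison_data(co)
  cv <- run_cv(d$X, d$labels, classifier_spec("sparse_logistic_regression"),
               k = 20, n_folds = 5, seed = 52)
  expect_false(any(is.na(cv$scores$score)))
  expect_identical(sort(cv$scores$sample), sort(rownames(d$X)))
  expect_equal(anyDuplicated(cv$scores$sample), 0L)
  expect_true(all(cv$scores$score >= 0 & cv$scores$score <= 1))
  # one selected-feature list per fold, each of size k
  expect_length(cv$selected, 5)
  expect_true(all(lengths(cv$selected) == 20))
  # rank-sum provenance is tagged with the training fold
  rk <- rank_sum_feature_scores(d$X[1:10, ], d$labels[1:10],
                                provenance = "fold-1-train")
  expect_identical(attr(rk, "provenance"), "fold-1-train")
})

test_that("runs are bit-reproducible under a fixed seed", {
  co <- simulate_cohort(tiny_config(), seed = 53)
  d <- comparison_data(co)
  cv1 <- run_cv(d$X, d$labels, classifier_spec("random_forest",
                                               hyper = list(ntree = 200)),
                k = 15, n_folds = 5, seed = 7)
  cv2 <- run_cv(d$X, d$labels, classifier_spec("random_forest",
                                               hyper = list(ntree = 200)),
                k = 15, n_folds = 5, seed = 7)
  expect_identical(cv1$scores, cv2$scores)
  expect_identical(cv1$selected, cv2$selected)
})

test_that("in-fold selection never sees its test fold", {
  # the selected features of a fold must be computable from the training
  # rows alone: recompute them independently and compare
  co <- simulate_cohort(tiny_config(), seed = 54)
  d <- comparison_data(co)
  folds <- make_folds(d$labels, 5, seed = 9)
  cv <- run_cv(d$X, d$labels, classifier_spec("sparse_logistic_regression"),
               k = 10, folds = folds, seed = 9)
  fid <- attr(d$X, "feature_ids")
  for (f in 1:5) {
    tr <- folds != f
    rk <- rank_sum_feature_scores(d$X[tr, , drop = FALSE], d$labels[tr],
                                  feature_ids = fid)
    expect_identical(cv$selected[[f]], top_k_features(rk, 10))
  }
})

test_that("run_all crosses comparisons, families and ks with one best each", {
  co <- simulate_cohort(tiny_config(n_cv = 24), seed = 55)
  X <- cohort_matrix(co, 1)
  mask <- fit_background_mask(X)
  Xm <- apply_mask(X, mask)
  rownames(Xm) <- rownames(X)
  cmps <- builtin_comparisons()[c("mortality_vs_survival", "oedema")]
  res <- suppressWarnings(
    run_all(Xm, co$metadata, comparisons = cmps,
            families = c("random_forest", "sparse_logistic_regression"),
            ks = c(10, 5), n_folds = 5, seed = 3, n_boot = 100, n_perm = 100,
            hyper = list(random_forest = list(ntree = 150)))
  )
  expect_equal(nrow(res$report), 2 * 2 * 2)
  expect_equal(sum(res$report$best), length(unique(res$report$comparison)))
  for (cid in unique(res$report$comparison)) {
    sub <- res$report[res$report$comparison == cid, ]
    expect_equal(sum(sub$best), 1)
    expect_equal(max(sub$auc), sub$auc[sub$best])
  }
})
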