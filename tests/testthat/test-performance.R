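# Brute-force oracles: AUC by explicit pair counting, Youden point by an
# exhaustive threshold scan.

pair_auc <- function(pos, neg) {
  mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
}

scan_youden <- function(scores, pos) {
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  best <- -Inf; sens <- spec <- NA
  for (t in thr) {
    se <- mean(scores[pos] >= t); sp <- mean(scores[!pos] < t)
    j <- se + sp - 1
    if (j > best + 1e-12 || (abs(j - best) <= 1e-12 && se > sens)) {
      best <- j; sens <- se; spec <- sp
    }
  }
  list(j = best, sensitivity = sens, specificity = spec)
}

test_that("AUC handles the canonical separable, crossed and tied cases", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.4, 0.3),
                       rep(c("pos", "neg"), each = 2), "pos")$auc, 1.0)
  # 2 concordant + 2 discordant of 4 pairs
  expect_equal(roc_auc(c(0.9, 0.3, 0.8, 0.4),
                       rep(c("pos", "neg"), each = 2), "pos")$auc, 0.5)
  expect_equal(roc_auc(rep(0.7, 10), rep(c("pos", "neg"), 5), "pos")$auc, 0.5)
  expect_error(roc_auc(1:4, rep("pos", 4)), "both classes")
})

test_that("ROC curves are monotone staircases from (0,0) to (1,1)", {
  set.seed(61)
  for (i in 1:20) {
    s <- sample(seq(0, 1, 0.05), 30, replace = TRUE)  # heavy ties
    lab <- sample(rep(c("a", "b"), 15))
    cur <- roc_auc(s, lab, "a")$curve
    expect_equal(cur$fpr[1], 0); expect_equal(cur$tpr[1], 0)
    expect_equal(cur$fpr[nrow(cur)], 1); expect_equal(cur$tpr[nrow(cur)], 1)
    expect_true(all(diff(cur$fpr) >= 0) && all(diff(cur$tpr) >= 0))
  }
})

test_that("trapezoidal integral equals Mann-Whitney concordance to 1e-12", {
  set.seed(62)
  for (i in 1:1000) {
    n_pos <- sample(2:15, 1); n_neg <- sample(2:15, 1)
    s <- if (i %% 2) rnorm(n_pos + n_neg) else
      sample(1:6, n_pos + n_neg, replace = TRUE)
    lab <- rep(c("pos", "neg"), c(n_pos, n_neg))
    r <- roc_auc(s, lab, "pos")
    trapz <- sum(diff(r$curve$fpr) *
                   (utils::head(r$curve$tpr, -1) + utils::tail(r$curve$tpr, -1)) / 2)
    expect_equal(trapz, r$auc, tolerance = 1e-12)
    expect_equal(r$auc, pair_auc(s[lab == "pos"], s[lab == "neg"]),
                 tolerance = 1e-12)
  }
})

test_that("AUC flips under negation and survives monotone transforms", {
  set.seed(63)
  s <- rnorm(40); lab <- sample(rep(c("a", "b"), 20))
  a1 <- roc_auc(s, lab, "a")$auc
  expect_equal(roc_auc(-s, lab, "a")$auc, 1 - a1)
  expect_equal(roc_auc(exp(s), lab, "a")$auc, a1)
  expect_equal(roc_auc(rank(s), lab, "a")$auc, a1)
})

test_that("AUC and DeLong CI agree with pROC", {
  skip_if_not_installed("pROC")
  set.seed(64)
  for (i in 1:25) {
    s <- rnorm(30) + rep(c(0.8, 0), c(12, 18))
    lab <- rep(c("case", "ctrl"), c(12, 18))
    ours <- roc_auc(s, lab, "case")
    ref <- pROC::roc(lab, s, levels = c("ctrl", "case"), direction = "<",
                     quiet = TRUE)
    expect_equal(ours$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
    ci_ref <- as.numeric(pROC::ci.auc(ref, method = "delong"))
    ci_ours <- faimsvoc:::delong_ci(s[lab == "case"], s[lab == "ctrl"])
    expect_equal(ci_ours, ci_ref[c(1, 3)], tolerance = 1e-8)
  }
})

test_that("the operating point maximises Youden's J (exhaustive oracle)", {
  set.seed(65)
  for (i in 1:200) {
    n <- sample(6:30, 1)
    s <- sample(seq(0, 1, 0.1), n, replace = TRUE)
    pos <- seq_len(n) %in% sample(n, sample(2:(n - 2), 1))
    lab <- ifelse(pos, "p", "n")
    r <- roc_auc(s, lab, "p")
    op <- operating_point(r$curve)
    oracle <- scan_youden(s, pos)
    expect_equal(op$j, oracle$j, tolerance = 1e-12)
    expect_equal(op$sensitivity, oracle$sensitivity, tolerance = 1e-12)
  }
  # separable scores: perfect operating point
  op <- operating_point(roc_auc(c(1, 1, 0, 0), c("p", "p", "n", "n"), "p")$curve)
  expect_equal(op$sensitivity, 1); expect_equal(op$specificity, 1)
  # all-tied scores: J = 0 at an extreme
  op0 <- operating_point(roc_auc(rep(1, 6), rep(c("p", "n"), 3), "p")$curve)
  expect_equal(op0$j, 0)
})

test_that("predictive values reproduce the published-table rows", {
  pv <- predictive_values(29 / 38, 12 / 19, 38, 19)
  expect_equal(round_half_up(pv$ppv, 2), 0.81)
  expect_equal(round_half_up(pv$npv, 2), 0.57)
  pv2 <- predictive_values(55 / 57, 7 / 7, 57, 7)
  expect_equal(pv2$npv, 7 / 9)
  expect_equal(round_half_up(pv2$npv, 2), 0.78)
  pv3 <- predictive_values(1, 1, 10, 5)
  expect_equal(pv3$ppv, 1); expect_equal(pv3$npv, 1)
  expect_warning(pv4 <- predictive_values(0, 1, 5, 5), "PPV undefined")
  expect_true(is.na(pv4$ppv))
})

test_that("integer confusion matrices are reconstructed from printed rates", {
  r <- reconstruct_confusion(0.76, 0.63, 38, 19)
  expect_true(attr(r, "unique"))
  expect_equal(r$orientation, "a_positive")
  expect_equal(r$tp, 29); expect_equal(r$tn, 12)

  r2 <- reconstruct_confusion(1.00, 1.00, 10, 5)
  expect_true(attr(r2, "unique"))  # both orientations give the same table
  expect_setequal(r2$tp[r2$orientation == "a_positive"], 10)

  r3 <- reconstruct_confusion(0.89, 0.55, 9, 38)
  r3a <- r3[r3$orientation == "a_positive", ]
  expect_equal(r3a$tp, 8); expect_equal(r3a$tn, 21)
  pv <- predictive_values(r3a$tp / 9, r3a$tn / 38, 9, 38)
  expect_equal(round_half_up(pv$ppv, 2), 0.32)
  expect_equal(round_half_up(pv$npv, 2), 0.95)

  expect_error(reconstruct_confusion(0.995, 0.5, 3, 4), "no integer")
})

test_that("a perfect AUC at n = 20/20 is permutation-significant", {
  s <- c(rnorm(20, 5), rnorm(20, 0))
  lab <- rep(c("case", "ctrl"), each = 20)
  inf <- auc_inference(s, lab, "case", n_boot = 100, n_perm = 10000, seed = 2)
  expect_lte(inf$p_value, 0.001)
  expect_equal(inf$auc, 1.0)
})

test_that("degenerate all-tied scores give a CI containing 0.5", {
  s <- rep(0.5, 20); lab <- rep(c("a", "b"), 10)
  inf <- auc_inference(s, lab, "a", n_boot = 200, n_perm = 200, seed = 3)
  expect_true(inf$ci[1] <= 0.5 && inf$ci[2] >= 0.5)
  expect_error(auc_inference(c(1, 2), c("a", "b")), ">= 2 samples")
})

test_that("performance_report rows are internally consistent", {
  co <- simulate_cohort(tiny_config(), seed = 66)
  d <- comparison_data(co)
  cv <- run_cv(d$X, d$labels, classifier_spec("random_forest",
                                              hyper = list(ntree = 200)),
               k = 10, n_folds = 5, seed = 6)
  rep1 <- performance_report(cv, "mortality_vs_survival",
                             n_boot = 200, n_perm = 200, seed = 6)
  expect_true(rep1$ci_low <= rep1$auc && rep1$auc <= rep1$ci_high)
  for (col in c("auc", "sensitivity", "specificity", "ppv", "npv"))
    expect_true(rep1[[col]] >= 0 && rep1[[col]] <= 1)
  # sens/spec correspond to an integer confusion matrix at the class sizes
  expect_equal(rep1$sensitivity * rep1$n_pos,
               round(rep1$sensitivity * rep1$n_pos))
  expect_equal(rep1$specificity * rep1$n_neg,
               round(rep1$specificity * rep1$n_neg))
})
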