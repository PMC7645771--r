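test_that("the same seed reproduces a cohort byte-identically", {
  cfg <- tiny_config()
  co1 <- simulate_cohort(cfg, seed = 81)
  co2 <- simulate_cohort(cfg, seed = 81)
  expect_identical(co1$metadata, co2$metadata)
  expect_identical(co1$runs, co2$runs)
  co3 <- simulate_cohort(cfg, seed = 82)
  expect_false(identical(co1$runs[[1]][[1]]$positive$intensities,
                         co3$runs[[1]][[1]]$positive$intensities))
})

test_that("zero noise and zero effects make replicates identical", {
  cfg <- tiny_config(replicates = 3, effect_d = 0)
  cfg$noise_sd <- 0; cfg$gain_sd <- 0
  co <- simulate_cohort(cfg, seed = 83)
  r <- co$runs[[1]]
  expect_identical(r[[1]]$positive$intensities, r[[2]]$positive$intensities)
  expect_identical(r[[2]]$negative$intensities, r[[3]]$negative$intensities)
  # and with no class effects, all subjects share one expected signal
  expect_identical(co$runs[[1]][[1]]$positive$intensities,
                   co$runs[[5]][[1]]$positive$intensities)
})

test_that("planted peaks land at their configured coordinates", {
  cfg <- sim_config(n_cv = 128, replicates = 1,
                    peaks = data.frame(polarity = "positive", df_center = 40,
                                       cv_center = 3.0, width_df = 5,
                                       width_cv = 0.55, amplitude = 8),
                    class_effects = list(),
                    cohort = list(n_discharged = 2, n_died_early = 2,
                                  n_died_late = 2, n_controls = 2))
  cfg$noise_sd <- 0; cfg$gain_sd <- 0
  cfg$background$amplitude <- 0
  co <- simulate_cohort(cfg, seed = 84)
  m <- co$runs[[1]][[1]]$positive$intensities
  peak_px <- which(m == max(m), arr.ind = TRUE)[1, ]
  df_axis <- co$runs[[1]][[1]]$positive$df_axis
  cv_axis <- co$runs[[1]][[1]]$positive$cv_axis
  # within half a pixel of the configured centre
  expect_lte(abs(df_axis[peak_px["row"]] - 40), diff(df_axis)[1] / 2)
  expect_lte(abs(cv_axis[peak_px["col"]] - 3.0), abs(diff(cv_axis)[1]) / 2)
  # the negative polarity has no peak at all here
  expect_equal(max(abs(co$runs[[1]][[1]]$negative$intensities)), 0)
})

test_that("ground truth marks the pixels that actually differ by class", {
  cfg <- study_config()
  co <- simulate_cohort(cfg, seed = 85)
  truth <- co$truth[[1]]
  expect_equal(truth$variable, "outcome"); expect_equal(truth$arm, "died")
  expect_true(all(truth$planted >= 1 &
                    truth$planted <= 2 * cfg$n_df * cfg$n_cv))
  # around 200 pixels at this geometry, by construction
  expect_gt(length(truth$planted), 100)
  expect_lt(length(truth$planted), 350)
  # the empirical between-arm mean difference reproduces the claimed deltas:
  # n = 19 vs 38 gives a standard error ~0.3 per pixel, small against the
  # planted deltas of 1-2 noise units
  X <- cohort_matrix(co, 1)
  died <- co$metadata$outcome == "died"
  emp <- colMeans(X[died, ]) - colMeans(X[!died & co$metadata$group == "SAM", ])
  expect_gt(cor(emp[truth$planted], truth$delta), 0.7)
  expect_equal(mean(emp[truth$planted]), mean(truth$delta), tolerance = 0.2)
  # unplanted pixels carry no comparable difference (only noise and the
  # finite-sample gain imbalance on bright background pixels)
  set.seed(1)
  unplanted <- sample(setdiff(seq_along(emp), truth$planted), 2000)
  expect_lt(mean(abs(emp[unplanted])), 0.3 * mean(abs(emp[truth$planted])))
})

test_that("metadata marginals track the configured rates", {
  big <- sim_config(n_cv = 8, cohort = list(n_discharged = 380,
                                            n_died_early = 90,
                                            n_died_late = 100,
                                            n_controls = 70))
  meta <- faimsvoc:::with_seed(86, simulate_metadata(big))
  disc <- meta[meta$outcome == "discharged" & meta$group == "SAM", ]
  died <- meta[meta$outcome == "died", ]
  binom_ok <- function(x, n, p) abs(x / n - p) <= 3 * sqrt(p * (1 - p) / n)
  expect_true(binom_ok(sum(disc$oedema), nrow(disc), 17 / 38))
  expect_true(binom_ok(sum(died$oedema), nrow(died), 5 / 19))
  expect_true(binom_ok(sum(disc$sex == "male"), nrow(disc), 23 / 38))
  expect_true(binom_ok(sum(died$diarrhoea), nrow(died), 11 / 19))
  # ages are truncated to the eligibility window, so means sit slightly
  # above nominal; the ordering and rough location must hold
  expect_lt(abs(mean(disc$age_months) - 25.9), 4)
  expect_gt(mean(disc$age_months), mean(died$age_months))
  expect_equal(mean(died$muac_cm), 10.5, tolerance = 0.05)
  expect_true(all(died$day_of_death %in% 1:6))
  expect_equal(sum(died$day_of_death <= 3), 90)
  expect_equal(sum(meta$group == "healthy_control"), 70)
})

test_that("stronger planted effects give higher cross-validated AUC", {
  meds <- vapply(c(0, 1, 2), function(d) {
    aucs <- vapply(1:3, function(i) {
      co <- simulate_cohort(study_config(n_cv = 48, effect_d = d),
                            seed = 900 + 10 * d + i)
      dd <- comparison_data(co)
      cv_auc(run_cv(dd$X, dd$labels,
                    classifier_spec("random_forest", hyper = list(ntree = 300)),
                    k = 30, n_folds = 5, seed = 910 + i))
    }, numeric(1))
    median(aucs)
  }, numeric(1))
  expect_gt(meds[3], meds[1] + 0.2)   # d = 2 clearly beats the null
  expect_true(all(diff(meds) >= -0.1))  # non-decreasing up to noise
})

test_that("invalid generator configurations are rejected", {
  expect_error(sim_config(peaks = within(default_peaks(), width_cv[1] <- -1)),
               "positive")
  expect_error(sim_config(cohort = list(n_discharged = 1, n_died_early = 3,
                                        n_died_late = 3, n_controls = 2)),
               ">= 2")
  bad <- sim_config()
  bad$class_effects[[1]]$peaks <- c(1, 99)
  expect_error(faimsvoc:::validate_sim_config(bad), "non-existent peak")
})

test_that("recovery_fraction measures per-fold planted overlap", {
  co <- simulate_cohort(study_config(n_cv = 64), seed = 87)
  d <- comparison_data(co)
  cv <- run_cv(d$X, d$labels, classifier_spec("sparse_logistic_regression"),
               k = 50, n_folds = 5, seed = 88)
  rec <- recovery_fraction(cv, co$truth[[1]])
  expect_length(rec$per_fold, 5)
  expect_true(rec$median >= 0 && rec$median <= 1)
  expect_gt(rec$median, 0.3)  # d = 2 signal is mostly recovered
})
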