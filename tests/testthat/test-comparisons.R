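test_that("the built-in comparison set has the study's eleven contrasts", {
  cmps <- builtin_comparisons()
  expect_length(cmps, 11)
  expect_equal(anyDuplicated(names(cmps)), 0L)
  expect_true(all(c("sam_vs_healthy", "mortality_vs_survival",
                    "early_mortality_vs_survival", "late_mortality_vs_survival",
                    "early_vs_late_mortality", "waz_le_minus3", "oedema",
                    "diarrhoea", "pneumonia", "hiv", "age_2yr") %in% names(cmps)))
})

test_that("comparisons resolve to the study's arm sizes on a matched cohort", {
  meta <- table1_metadata()
  cmps <- builtin_comparisons()
  arm_sizes <- function(id) {
    a <- resolve(cmps[[id]], meta)
    c(length(a$arm_a), length(a$arm_b), length(a$excluded))
  }
  expect_equal(arm_sizes("sam_vs_healthy"), c(57, 7, 0))
  expect_equal(arm_sizes("mortality_vs_survival"), c(19, 38, 0))
  expect_equal(arm_sizes("early_mortality_vs_survival"), c(9, 38, 10))
  expect_equal(arm_sizes("late_mortality_vs_survival"), c(10, 38, 9))
  expect_equal(arm_sizes("early_vs_late_mortality"), c(9, 10, 38))
  expect_equal(arm_sizes("oedema"), c(22, 35, 0))
  expect_equal(arm_sizes("diarrhoea"), c(23, 34, 0))
  expect_equal(arm_sizes("pneumonia"), c(17, 40, 0))
  expect_equal(arm_sizes("hiv"), c(14, 38, 5))
})

test_that("arms are disjoint and partition the scope on random cohorts", {
  for (seed in 1:5) {
    meta <- faimsvoc:::with_seed(seed, simulate_metadata(sim_config(n_cv = 8)))
    sam_ids <- meta$sample_id[meta$group == "SAM"]
    for (cmp in builtin_comparisons()) {
      arms <- tryCatch(resolve(cmp, meta), error = function(e) NULL)
      if (is.null(arms)) next
      expect_length(intersect(arms$arm_a, arms$arm_b), 0)
      scope_ids <- if (cmp$scope == "SAM") sam_ids else meta$sample_id
      expect_setequal(c(arms$arm_a, arms$arm_b, arms$excluded), scope_ids)
    }
  }
})

test_that("an empty arm is an error naming the arm", {
  meta <- table1_metadata()
  no_deaths <- validate_metadata(meta[meta$outcome == "discharged", ])
  expect_error(resolve(builtin_comparisons()$mortality_vs_survival, no_deaths),
               "'died' is empty")
})

test_that("pooled t-test from printed summaries matches the baseline table", {
  # age, months: 25.9 (16.1) in 38 discharged vs 16.8 (13.3) in 19 died
  age <- t_test_summary(25.9, 16.1, 38, 16.8, 13.3, 19)
  expect_equal(round_half_up(age$p_value, 2), 0.04)
  # MUAC, cm: 11.5 (1.6) vs 10.5 (1.5)
  muac <- t_test_summary(11.5, 1.6, 38, 10.5, 1.5, 19)
  expect_equal(round_half_up(muac$p_value, 2), 0.03)
  expect_equal(age$df, 55)
})

test_that("summary t-test equals the raw-data t-test realising the summaries", {
  set.seed(71)
  for (i in 1:10) {
    n1 <- sample(5:40, 1); n2 <- sample(5:40, 1)
    m1 <- rnorm(1); s1 <- runif(1, 0.5, 3); m2 <- rnorm(1); s2 <- runif(1, 0.5, 3)
    realise <- function(n, m, s) {  # sample with exactly these mean/sd
      x <- rnorm(n); m + s * (x - mean(x)) / sd(x)
    }
    x1 <- realise(n1, m1, s1); x2 <- realise(n2, m2, s2)
    ours <- t_test_summary(m1, s1, n1, m2, s2, n2, pooled = TRUE)
    ref <- t.test(x1, x2, var.equal = TRUE)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-9)
    ours_w <- t_test_summary(m1, s1, n1, m2, s2, n2, pooled = FALSE)
    ref_w <- t.test(x1, x2)
    expect_equal(ours_w$p_value, ref_w$p.value, tolerance = 1e-9)
  }
})

test_that("baseline_table summarises arms and yields p = 1 on identical arms", {
  meta <- table1_metadata()
  tab <- baseline_table(meta, "outcome")
  expect_true(all(tab$p_value >= 0 & tab$p_value <= 1, na.rm = TRUE))
  expect_true(all(c("age_months", "muac_cm", "oedema", "male") %in% tab$variable))
  oed <- tab[tab$variable == "oedema", ]
  expect_equal(oed$stat_a + oed$stat_b, 22)  # discharged 17 + died 5

  # duplicate the discharged arm into a fake second arm: every p = 1
  disc <- meta[meta$outcome == "discharged" & meta$group == "SAM", ]
  twin <- disc
  twin$sample_id <- paste0(twin$sample_id, "x")
  twin$outcome <- "died"; twin$day_of_death <- 3L
  same <- validate_metadata(rbind(disc, twin))
  tab2 <- baseline_table(same, "outcome")
  num <- tab2[tab2$type != "categorical", ]
  expect_true(all(num$p_value == 1))
})

test_that("the baseline arms are ordered and sized as labelled", {
  meta <- table1_metadata()
  tab <- baseline_table(meta, "outcome")
  expect_equal(attr(tab, "arms"), c("died", "discharged"))
  age <- tab[tab$variable == "age_months", ]
  expect_equal(age$n_a, 19); expect_equal(age$n_b, 38)
})
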