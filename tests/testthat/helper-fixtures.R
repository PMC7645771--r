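# Fixtures built in code: small random scans/runs and a deterministic
# metadata table matching the study cohort's exact counts.

rand_scan <- function(n_df = 8, n_cv = 12, polarity = "positive", seed = 1) {
  m <- faimsvoc:::with_seed(seed, matrix(rnorm(n_df * n_cv), n_df, n_cv))
  dispersion_scan(m, polarity,
                  df_axis = default_df_axis(n_df),
                  cv_axis = default_cv_axis(n_cv))
}

mk_run <- function(sample_id = "S1", rep = 1, n_df = 8, n_cv = 12, seed = 1) {
  instrument_run(sample_id, rep,
                 rand_scan(n_df, n_cv, "positive", seed),
                 rand_scan(n_df, n_cv, "negative", seed + 1000))
}

# One metadata row; defaults are overridden per arm.
meta_row <- function(id, outcome = "discharged", group = "SAM",
                     day = NA_integer_, oedema = FALSE, hiv = "negative",
                     diarrhoea = FALSE, pneumonia = FALSE, waz = -4,
                     age = 30, site = "CPGH", sex = "male") {
  data.frame(sample_id = id, site = site, age_months = age, sex = sex,
             muac_cm = 11, waz = waz, whz = -3, haz = -3, oedema = oedema,
             diarrhoea = diarrhoea, vomiting = FALSE, fever = FALSE,
             pneumonia = pneumonia, hiv = hiv, danger_signs = FALSE,
             group = group, outcome = outcome, day_of_death = day,
             stringsAsFactors = FALSE)
}

# Deterministic cohort with the study's exact counts: 38 discharged + 19 died
# (9 on day 1-3, 10 on day 4-6) + 7 healthy controls; oedema 17/5, diarrhoea
# 12/11, pneumonia 10/7, HIV 28-7-3 / 10-7-2 by outcome.
table1_metadata <- function() {
  flag <- function(n, k) c(rep(TRUE, k), rep(FALSE, n - k))
  disc <- do.call(rbind, lapply(1:38, function(i) meta_row(
    sprintf("D%02d", i),
    oedema = flag(38, 17)[i], diarrhoea = flag(38, 12)[i],
    pneumonia = flag(38, 10)[i],
    hiv = rep(c("negative", "positive", "unknown"), c(28, 7, 3))[i],
    waz = if (i <= 20) -4 else -2, age = if (i <= 15) 36 else 12)))
  died <- do.call(rbind, lapply(1:19, function(i) meta_row(
    sprintf("M%02d", i), outcome = "died",
    day = c(rep(1:3, 3), rep(4:6, length.out = 10))[i],
    oedema = flag(19, 5)[i], diarrhoea = flag(19, 11)[i],
    pneumonia = flag(19, 7)[i],
    hiv = rep(c("negative", "positive", "unknown"), c(10, 7, 2))[i],
    waz = if (i <= 12) -4 else -2, age = if (i <= 5) 36 else 12)))
  ctrl <- do.call(rbind, lapply(1:7, function(i) meta_row(
    sprintf("H%02d", i), group = "healthy_control", waz = -0.5, age = 50)))
  validate_metadata(rbind(disc, died, ctrl))
}

# Small, fast generator configuration for pipeline tests.
tiny_config <- function(n_cv = 32, replicates = 1, effect_d = 2, ...) {
  sim_config(n_cv = n_cv, replicates = replicates, effect_d = effect_d,
             cohort = list(n_discharged = 8, n_died_early = 3,
                           n_died_late = 3, n_controls = 2), ...)
}

# Reduced-geometry study-size configuration (full arm sizes, narrower cv axis)
study_config <- function(n_cv = 128, replicates = 1, ...) {
  sim_config(n_cv = n_cv, replicates = replicates, ...)
}

# Extract one comparison's masked matrix + labels from a cohort.
comparison_data <- function(cohort, comparison = "mortality_vs_survival",
                            replicate = 1, mask = TRUE) {
  X <- cohort_matrix(cohort, replicate)
  ids_all <- attr(X, "feature_ids")
  if (mask) {
    m <- fit_background_mask(X)
    X <- apply_mask(X, m)
  }
  arms <- resolve(builtin_comparisons()[[comparison]], cohort$metadata)
  ids <- c(arms$arm_a, arms$arm_b)
  lab <- factor(rep(c(arms$arm_a_name, arms$arm_b_name),
                    c(length(arms$arm_a), length(arms$arm_b))),
                levels = c(arms$arm_a_name, arms$arm_b_name))
  fid <- attr(X, "feature_ids")
  X <- X[ids, , drop = FALSE]
  attr(X, "feature_ids") <- fid
  list(X = X, labels = lab)
}
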