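# Synthetic FAIMS cohorts: dispersion matrices with a smooth background ridge,
# sparse 2D Gaussian analyte peaks whose intensity/position can differ by
# class with a stated effect size, replicate and sample noise, and a cohort
# metadata table with study-like group sizes (38 discharged, 19 died --- 9
# within 3 days, 10 on day 4-6 --- and 7 healthy controls).
#
# The generator emulates the geometry and the statistical structure of real
# dispersion plots (a background ridge whose compensation-voltage position
# drifts with dispersion field, as real ion chemistry does), not the ion
# chemistry itself. Ground truth (which pixels carry class signal) is emitted
# alongside the data so recovery metrics are first-class outputs.

#' Configuration for the synthetic cohort generator
#'
#' Defaults reproduce the study conditions: 51 x 512 geometry, three
#' replicates per sample, arm sizes 38 discharged / 9 early deaths / 10 late
#' deaths / 7 healthy controls, clinical marginals matching the study's
#' baseline table, and one planted class effect of size `effect_d` (in
#' per-pixel noise-SD units) on three analyte peaks for the mortality
#' contrast.
#'
#' @param n_df,n_cv dispersion-plot geometry (default 51 x 512)
#' @param background list: `amplitude` (ion-current units), `cv_center` (V, at
#'   df = 0), `cv_drift` (V per df percent; the ridge migrates with field),
#'   `cv_width` (V)
#' @param peaks data.frame with columns `polarity`, `df_center` (%),
#'   `cv_center` (V), `width_df` (%), `width_cv` (V), `amplitude`
#' @param class_effects list of effects; each is a list with `variable`
#'   (metadata column), `arm` (value of that column receiving the effect),
#'   `peaks` (row indices into `peaks`), `d` (additive amplitude effect in
#'   noise-SD units at the peak maximum) and `cv_shift` (V)
#' @param noise_sd per-pixel Gaussian noise SD (default 1)
#' @param gain_sd SD of the per-run log-normal multiplicative gain jitter
#'   (default 0.05), modelling instrument run-to-run variability
#' @param replicates instrument runs per sample (default 3)
#' @param cohort list of arm sizes: `n_discharged`, `n_died_early`,
#'   `n_died_late`, `n_controls`
#' @param effect_d effect size used by the default `class_effects` (default 2)
#' @param seed default seed used by [simulate_cohort()]
#' @return a `sim_config` list
#' @export
sim_config <- function(n_df = 51, n_cv = 512,
                       background = list(amplitude = 30, cv_center = 1.5,
                                         cv_drift = -0.03, cv_width = 1.2),
                       peaks = default_peaks(),
                       class_effects = NULL,
                       noise_sd = 1, gain_sd = 0.05, replicates = 3,
                       cohort = list(n_discharged = 38, n_died_early = 9,
                                     n_died_late = 10, n_controls = 7),
                       effect_d = 2, seed = 1L) {
  class_effects <- class_effects %||% list(
    list(variable = "outcome", arm = "died", peaks = 1:3, d = effect_d,
         cv_shift = 0)
  )
  cfg <- structure(list(n_df = n_df, n_cv = n_cv, background = background,
                        peaks = peaks, class_effects = class_effects,
                        noise_sd = noise_sd, gain_sd = gain_sd,
                        replicates = replicates, cohort = cohort,
                        seed = as.integer(seed)),
                   class = "sim_config")
  validate_sim_config(cfg)
}

#' Default analyte peak table (three class-informative, two common)
#'
#' Peaks 1-3 (the default class-effect carriers) sit well away from the
#' background ridge, as genuinely discriminatory analyte peaks do --- pixels
#' on the ridge are dominated by run-to-run gain jitter, which is exactly why
#' the background is thresholded away. Peaks 4-5 are class-uninformative
#' analyte peaks common to all samples.
#'
#' @return data.frame of peak definitions (see [sim_config()])
#' @export
default_peaks <- function() {
  data.frame(
    polarity = c("positive", "positive", "negative", "positive", "negative"),
    df_center = c(40, 60, 50, 30, 70),
    cv_center = c(3.0, -3.5, 3.0, -2.0, -4.0),
    width_df = c(5, 5, 5, 6, 6),
    width_cv = c(0.55, 0.55, 0.55, 0.7, 0.7),
    amplitude = c(8, 8, 8, 10, 10),
    stringsAsFactors = FALSE
  )
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    stopifnot(n_df >= 2, n_cv >= 2, replicates >= 1,
              noise_sd >= 0, gain_sd >= 0)
    if (any(peaks$width_df <= 0) || any(peaks$width_cv <= 0) ||
        any(peaks$amplitude <= 0))
      stop_fv("sim_config: peak widths and amplitudes must be positive")
    if (background$amplitude < 0 || background$cv_width <= 0)
      stop_fv("sim_config: invalid background ridge")
    sizes <- unlist(cohort)
    if (any(sizes < 2))
      stop_fv("sim_config: every arm needs >= 2 subjects (got %s)",
              paste(sizes, collapse = ", "))
    for (eff in class_effects) {
      if (any(eff$peaks < 1 | eff$peaks > nrow(peaks)))
        stop_fv("sim_config: class effect references non-existent peak")
      if (is.null(eff$variable) || is.null(eff$arm))
        stop_fv("sim_config: class effect needs 'variable' and 'arm'")
    }
  })
  cfg
}

# truncated normal via inverse CDF (exact, vectorised)
rtnorm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

# Draw one arm's worth of metadata rows from study-like marginals.
.meta_arm <- function(n, outcome, day_range, group, site_p, male_p,
                      age_m, age_s, age_rng, muac_m, muac_s,
                      waz_m, waz_s, whz_m, whz_s, haz_m, haz_s,
                      oedema_p, vomit_p, diarr_p, fever_p, pneu_p, danger_p,
                      hiv_p, miss_whz = 0.07, miss_haz = 0.035) {
  day <- if (is.null(day_range)) rep(NA_integer_, n) else
    sample(day_range, n, replace = TRUE)
  whz <- stats::rnorm(n, whz_m, whz_s)
  whz[stats::runif(n) < miss_whz] <- NA
  haz <- stats::rnorm(n, haz_m, haz_s)
  haz[stats::runif(n) < miss_haz] <- NA
  data.frame(
    site = sample(.meta_sites, n, replace = TRUE, prob = site_p),
    age_months = rtnorm(n, age_m, age_s, age_rng[1], age_rng[2]),
    sex = ifelse(stats::runif(n) < male_p, "male", "female"),
    muac_cm = rtnorm(n, muac_m, muac_s, 5, Inf),
    waz = stats::rnorm(n, waz_m, waz_s),
    whz = whz, haz = haz,
    oedema = stats::runif(n) < oedema_p,
    diarrhoea = stats::runif(n) < diarr_p,
    vomiting = stats::runif(n) < vomit_p,
    fever = stats::runif(n) < fever_p,
    pneumonia = stats::runif(n) < pneu_p,
    hiv = sample(c("negative", "positive", "unknown"), n, replace = TRUE,
                 prob = hiv_p),
    danger_signs = stats::runif(n) < danger_p,
    group = group, outcome = outcome, day_of_death = day,
    stringsAsFactors = FALSE
  )
}

#' Simulate a cohort metadata table with study-like marginals
#'
#' Marginal rates per arm follow the study's baseline table (e.g. mean age
#' 25.9 vs 16.8 months, MUAC 11.5 vs 10.5 cm, oedema 44.7% vs 26.3% in
#' discharged vs died; controls older with higher MUAC). Consistency rules
#' are enforced (day of death 1-3 for early deaths, 4-6 for late; controls
#' never die and carry no SAM morbidity flags).
#'
#' @param config a [sim_config()]
#' @return a validated `cohort_metadata`
#' @export
simulate_metadata <- function(config) {
  ch <- config$cohort
  disc <- .meta_arm(ch$n_discharged, "discharged", NULL, "SAM",
                    site_p = c(15, 4, 19) / 38, male_p = 23 / 38,
                    age_m = 25.9, age_s = 16.1, age_rng = c(6, 60),
                    muac_m = 11.5, muac_s = 1.6,
                    waz_m = -3.8, waz_s = 1.3, whz_m = -3.1, whz_s = 1.4,
                    haz_m = -3.2, haz_s = 1.5,
                    oedema_p = 17 / 38, vomit_p = 7 / 38, diarr_p = 12 / 38,
                    fever_p = 9 / 38, pneu_p = 10 / 38, danger_p = 2 / 38,
                    hiv_p = c(28, 7, 3) / 38)
  died_args <- list(site_p = c(10, 1, 8) / 19, male_p = 12 / 19,
                    age_m = 16.8, age_s = 13.3, age_rng = c(6, 60),
                    muac_m = 10.5, muac_s = 1.5,
                    waz_m = -4.3, waz_s = 1.6, whz_m = -3.7, whz_s = 1.4,
                    haz_m = -3.1, haz_s = 2.3,
                    oedema_p = 5 / 19, vomit_p = 7 / 19, diarr_p = 11 / 19,
                    fever_p = 10 / 19, pneu_p = 7 / 19, danger_p = 6 / 19,
                    hiv_p = c(10, 7, 2) / 19)
  early <- do.call(.meta_arm, c(list(ch$n_died_early, "died", 1:3, "SAM"),
                                died_args))
  late <- do.call(.meta_arm, c(list(ch$n_died_late, "died", 4:6, "SAM"),
                               died_args))
  ctrl <- .meta_arm(ch$n_controls, "discharged", NULL, "healthy_control",
                    site_p = c(0, 0, 1), male_p = 4 / 7,
                    age_m = 52.9, age_s = 22.1, age_rng = c(6, 72),
                    muac_m = 15.1, muac_s = 2.0,
                    waz_m = -0.5, waz_s = 0.9, whz_m = -0.5, whz_s = 0.8,
                    haz_m = -1.0, haz_s = 1.0,
                    oedema_p = 0, vomit_p = 0, diarr_p = 0, fever_p = 0,
                    pneu_p = 0, danger_p = 0, hiv_p = c(1, 0, 0),
                    miss_whz = 0, miss_haz = 0)
  ctrl$muac_cm <- pmax(ctrl$muac_cm, 12.6)  # control eligibility: MUAC > 12.5
  ctrl$whz <- pmax(ctrl$whz, -1.9)          # control eligibility: WHZ > -2
  meta <- rbind(disc, early, late, ctrl)
  meta <- cbind(sample_id = sprintf("S%03d", seq_len(nrow(meta))), meta,
                stringsAsFactors = FALSE)
  validate_metadata(meta)
}

# Noise-free expected signal (background + peaks) for one polarity, given the
# per-peak amplitude adjustments and cv shifts of one subject.
.expected_signal <- function(config, polarity, amp_add = NULL, cv_add = NULL) {
  n_df <- config$n_df; n_cv <- config$n_cv
  df <- default_df_axis(n_df); cv <- default_cv_axis(n_cv)
  bg <- config$background
  ridge_center <- bg$cv_center + bg$cv_drift * df
  gain_df <- 0.5 + 0.5 * df / 100  # ridge strengthens with dispersion field
  M <- (bg$amplitude * gain_df) *
    exp(-(outer(ridge_center, cv, "-"))^2 / (2 * bg$cv_width^2))
  pk <- config$peaks
  amp_add <- amp_add %||% numeric(nrow(pk))
  cv_add <- cv_add %||% numeric(nrow(pk))
  for (i in which(pk$polarity == polarity)) {
    amp <- pk$amplitude[i] + amp_add[i]
    ctr <- pk$cv_center[i] + cv_add[i]
    M <- M + amp * outer(exp(-(df - pk$df_center[i])^2 / (2 * pk$width_df[i]^2)),
                         exp(-(cv - ctr)^2 / (2 * pk$width_cv[i]^2)))
  }
  M
}

# Per-subject peak adjustments implied by the class effects.
.subject_adjust <- function(config, meta_row) {
  npk <- nrow(config$peaks)
  amp_add <- numeric(npk); cv_add <- numeric(npk)
  for (eff in config$class_effects) {
    val <- meta_row[[eff$variable]]
    if (!is.na(val) && as.character(val) == as.character(eff$arm)) {
      amp_add[eff$peaks] <- amp_add[eff$peaks] + (eff$d %||% 0) * config$noise_sd
      cv_add[eff$peaks] <- cv_add[eff$peaks] + (eff$cv_shift %||% 0)
    }
  }
  list(amp_add = amp_add, cv_add = cv_add)
}

# Ground truth: for each class effect, the flat pixel indices whose expected
# between-arm difference is at least half the maximum planted effect.
.ground_truth <- function(config) {
  lapply(config$class_effects, function(eff) {
    npk <- nrow(config$peaks)
    amp_add <- numeric(npk); cv_add <- numeric(npk)
    amp_add[eff$peaks] <- (eff$d %||% 0) * config$noise_sd
    cv_add[eff$peaks] <- eff$cv_shift %||% 0
    delta <- c(
      t(.expected_signal(config, "positive", amp_add, cv_add) -
          .expected_signal(config, "positive")),
      t(.expected_signal(config, "negative", amp_add, cv_add) -
          .expected_signal(config, "negative"))
    )
    thr <- 0.5 * max(abs(delta))
    planted <- which(abs(delta) >= thr)
    list(variable = eff$variable, arm = eff$arm, d = eff$d %||% 0,
         cv_shift = eff$cv_shift %||% 0,
         planted = planted, delta = delta[planted])
  })
}

#' Simulate a full FAIMS cohort with planted class structure
#'
#' Generates the metadata table, then, for every subject, `replicates`
#' instrument runs: expected signal (background ridge + analyte peaks, with
#' the subject's class-effect adjustments) times a per-run log-normal gain,
#' plus iid Gaussian pixel noise. The same seed reproduces the cohort
#' byte-identically.
#'
#' @param config a [sim_config()]
#' @param seed integer seed (default: the config's seed)
#' @return a `faims_cohort`: list with `runs` (per subject, a list of
#'   `instrument_run`s), `metadata`, `truth` (per class effect: planted flat
#'   pixel indices and their expected differences), `config`
#' @export
simulate_cohort <- function(config = sim_config(), seed = config$seed) {
  validate_sim_config(config)
  truth <- .ground_truth(config)
  with_seed(seed, {
    meta <- simulate_metadata(config)
    n_px <- config$n_df * config$n_cv
    runs <- lapply(seq_len(nrow(meta)), function(i) {
      adj <- .subject_adjust(config, meta[i, ])
      sig_p <- .expected_signal(config, "positive", adj$amp_add, adj$cv_add)
      sig_n <- .expected_signal(config, "negative", adj$amp_add, adj$cv_add)
      lapply(seq_len(config$replicates), function(r) {
        gain <- exp(stats::rnorm(1, 0, config$gain_sd))
        mk <- function(sig, pol) dispersion_scan(
          gain * sig + matrix(stats::rnorm(n_px, 0, config$noise_sd),
                              config$n_df, config$n_cv),
          polarity = pol,
          df_axis = default_df_axis(config$n_df),
          cv_axis = default_cv_axis(config$n_cv))
        instrument_run(meta$sample_id[i], r, mk(sig_p, "positive"),
                       mk(sig_n, "negative"))
      })
    })
    names(runs) <- meta$sample_id
    structure(list(runs = runs, metadata = meta, truth = truth,
                   config = config, seed = seed),
              class = "faims_cohort")
  })
}

#' Simulate a null cohort (labels carry no information about the matrices)
#'
#' Identical to [simulate_cohort()] with every class effect removed; the
#' leakage-guard fixture.
#'
#' @inheritParams simulate_cohort
#' @return a `faims_cohort` with empty ground truth
#' @export
simulate_null_cohort <- function(config = sim_config(), seed = config$seed) {
  config$class_effects <- list()
  simulate_cohort(config, seed)
}

#' @export
print.faims_cohort <- function(x, ...) {
  cat(sprintf("<faims_cohort> %d subjects x %d replicates, %d x %d x 2 = %d features, %d planted effect(s)\n",
              length(x$runs), x$config$replicates, x$config$n_df, x$config$n_cv,
              2 * x$config$n_df * x$config$n_cv, length(x$truth)))
  invisible(x)
}

#' Selected-replicate samples of a simulated (or loaded) cohort
#' @param cohort a `faims_cohort`
#' @param replicate replicate carried to analysis (default 2)
#' @return list of `faims_sample`
#' @export
cohort_samples <- function(cohort, replicate = 2) {
  lapply(cohort$runs, function(rr)
    faims_sample(rr[[1]]$sample_id, select_replicate(rr, replicate),
                 replicate = replicate))
}

#' Fraction of selected features that fall inside the planted ground truth
#'
#' Recovery metric for simulated cohorts: for each cross-validation fold, the
#' fraction of that fold's selected features lying in the planted pixel set;
#' summarised by the median over folds.
#'
#' @param cv a `cv_result`
#' @param truth one element of a cohort's `truth` list (or an integer vector
#'   of planted flat indices)
#' @return list with `per_fold` fractions and `median`
#' @export
recovery_fraction <- function(cv, truth) {
  planted <- if (is.list(truth)) truth$planted else as.integer(truth)
  per_fold <- vapply(cv$selected, function(sel)
    if (is.null(sel)) NA_real_ else mean(sel %in% planted), numeric(1))
  list(per_fold = per_fold, median = stats::median(per_fold, na.rm = TRUE))
}

#' Combined feature matrix of a cohort (one row per subject)
#' @param cohort a `faims_cohort`
#' @param replicate replicate carried to analysis (default 2)
#' @return samples x features matrix (rownames = sample ids)
#' @export
cohort_matrix <- function(cohort, replicate = 2) {
  if (cohort$config$replicates < replicate) {
    # fall back to the only/first replicate when fewer were simulated
    replicate <- min(replicate, cohort$config$replicates)
  }
  feature_matrix(cohort_samples(cohort, replicate))
}
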