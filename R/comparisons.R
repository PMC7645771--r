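# The study's grouped comparisons over cohort metadata, and the
# baseline-characteristics table.
#
# Primary comparisons: SAM vs healthy controls (instrument validation);
# mortality within 6 days vs discharge; early mortality (death on day 1-3) vs
# discharge; late mortality (death on day 4-6) vs discharge; early vs late
# mortality. Secondary comparisons (known mortality risk factors): WAZ <= -3
# vs > -3, oedema, diarrhoea, pneumonia, HIV serostatus (unknown excluded),
# and age dichotomised at 2 years. All except the control comparison are
# restricted to the SAM cohort; healthy controls enter only the validation
# comparison. Subjects matching neither arm (e.g. missing the defining
# variable) are excluded and counted.

#' Define one two-arm comparison over cohort metadata
#'
#' @param id short identifier
#' @param arm_a_name,arm_b_name arm labels; arm A is the positive class in
#'   reports
#' @param arm_a,arm_b predicate functions taking the metadata data.frame and
#'   returning a logical vector (NA = not a member)
#' @param scope `"SAM"` (restrict to the SAM group, default) or `"all"`
#' @param note free-text orientation note
#' @return a `comparison_spec`
#' @export
comparison_spec <- function(id, arm_a_name, arm_a, arm_b_name, arm_b,
                            scope = c("SAM", "all"), note = "") {
  scope <- match.arg(scope)
  structure(list(id = id, arm_a_name = arm_a_name, arm_b_name = arm_b_name,
                 arm_a = arm_a, arm_b = arm_b, scope = scope, note = note),
            class = "comparison_spec")
}

#' The study's eleven built-in comparisons
#'
#' Five mortality/validation comparisons and six morbidity comparisons, as in
#' the study's reported classification table. Early mortality = death within
#' 3 days of admission; late mortality = death on day 4, 5 or 6.
#'
#' @return named list of 11 `comparison_spec` objects
#' @export
builtin_comparisons <- function() {
  died_early <- function(m) m$outcome == "died" & m$day_of_death <= 3
  died_late <- function(m) m$outcome == "died" & m$day_of_death >= 4
  specs <- list(
    comparison_spec("sam_vs_healthy",
                    "SAM", function(m) m$group == "SAM",
                    "healthy_control", function(m) m$group == "healthy_control",
                    scope = "all", note = "validation comparison"),
    comparison_spec("mortality_vs_survival",
                    "died", function(m) m$outcome == "died",
                    "discharged", function(m) m$outcome == "discharged"),
    comparison_spec("early_mortality_vs_survival",
                    "died_early", died_early,
                    "discharged", function(m) m$outcome == "discharged"),
    comparison_spec("late_mortality_vs_survival",
                    "died_late", died_late,
                    "discharged", function(m) m$outcome == "discharged"),
    comparison_spec("early_vs_late_mortality",
                    "died_early", died_early, "died_late", died_late),
    comparison_spec("waz_le_minus3",
                    "waz_le_-3", function(m) m$waz <= -3,
                    "waz_gt_-3", function(m) m$waz > -3),
    comparison_spec("oedema",
                    "oedema", function(m) m$oedema,
                    "no_oedema", function(m) !m$oedema),
    comparison_spec("diarrhoea",
                    "diarrhoea", function(m) m$diarrhoea,
                    "no_diarrhoea", function(m) !m$diarrhoea),
    comparison_spec("pneumonia",
                    "pneumonia", function(m) m$pneumonia,
                    "no_pneumonia", function(m) !m$pneumonia),
    comparison_spec("hiv",
                    "hiv_positive", function(m) m$hiv == "positive",
                    "hiv_negative", function(m) m$hiv == "negative",
                    note = "hiv = unknown excluded"),
    comparison_spec("age_2yr",
                    "age_gt_2yr", function(m) m$age_months > 24,
                    "age_le_2yr", function(m) m$age_months <= 24)
  )
  names(specs) <- vapply(specs, `[[`, character(1), "id")
  specs
}

#' Resolve a comparison against a cohort
#'
#' Applies the arm predicates (within the spec's scope), checks disjointness
#' and returns the member sample ids per arm plus the excluded ids.
#'
#' @param spec a `comparison_spec`
#' @param metadata a `cohort_metadata`
#' @return list with `arm_a`, `arm_b` (character sample ids), `excluded`,
#'   `arm_a_name`, `arm_b_name`
#' @export
resolve <- function(spec, metadata) {
  stopifnot(inherits(spec, "comparison_spec"))
  m <- as.data.frame(metadata)
  if (spec$scope == "SAM") m <- m[m$group == "SAM", , drop = FALSE]
  in_a <- spec$arm_a(m); in_b <- spec$arm_b(m)
  in_a[is.na(in_a)] <- FALSE; in_b[is.na(in_b)] <- FALSE
  if (any(in_a & in_b))
    stop_fv("resolve: comparison '%s' arms overlap (sample %s)",
            spec$id, m$sample_id[in_a & in_b][1])
  if (!any(in_a)) stop_fv("resolve: comparison '%s': arm '%s' is empty",
                          spec$id, spec$arm_a_name)
  if (!any(in_b)) stop_fv("resolve: comparison '%s': arm '%s' is empty",
                          spec$id, spec$arm_b_name)
  list(arm_a = m$sample_id[in_a], arm_b = m$sample_id[in_b],
       excluded = m$sample_id[!in_a & !in_b],
       arm_a_name = spec$arm_a_name, arm_b_name = spec$arm_b_name)
}

#' Two-sample pooled-variance t-test from summary statistics
#'
#' Student's t-test computed from per-arm mean, SD and n --- exactly the test
#' that reproduces a baseline table's printed p-values from its printed
#' summaries. `pooled = FALSE` gives Welch's unequal-variance version.
#'
#' @param mean1,sd1,n1,mean2,sd2,n2 per-arm summaries
#' @param pooled use the pooled-variance (Student) form (default TRUE)
#' @return list with `t`, `df`, `p_value`
#' @export
t_test_summary <- function(mean1, sd1, n1, mean2, sd2, n2, pooled = TRUE) {
  stopifnot(n1 >= 2, n2 >= 2)
  if (pooled) {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se <- sqrt(sd1^2 / n1 + sd2^2 / n2)
    df <- se^4 / ((sd1^2 / n1)^2 / (n1 - 1) + (sd2^2 / n2)^2 / (n2 - 1))
  }
  t <- (mean1 - mean2) / se
  list(t = t, df = df, p_value = 2 * stats::pt(-abs(t), df))
}

.baseline_continuous <- c(age_months = "age_months", muac_cm = "muac_cm",
                          waz = "waz", whz = "whz", haz = "haz")
.baseline_binary <- c(male = "sex", oedema = "oedema", diarrhoea = "diarrhoea",
                      vomiting = "vomiting", fever = "fever",
                      pneumonia = "pneumonia", danger_signs = "danger_signs")

#' Baseline-characteristics table with per-variable tests
#'
#' Summarises each clinical variable per arm and tests the arms against each
#' other: mean (SD) with a two-sample pooled-variance t-test for continuous
#' variables; n (%) with a two-proportion z-test (no continuity correction)
#' for binary ones; a chi-squared test for multi-level categoricals (site,
#' HIV). Subjects missing a variable drop out of that variable's row only
#' (per-variable denominators are reported).
#'
#' @param metadata a `cohort_metadata`
#' @param grouping metadata column defining the two arms (default
#'   `"outcome"`, i.e. discharged vs died within the SAM group)
#' @param scope `"SAM"` or `"all"` rows (default SAM unless grouping is
#'   `"group"`)
#' @param pooled pooled-variance t-test (default TRUE; FALSE = Welch)
#' @return data.frame with one row per variable: `variable`, `type`,
#'   `n_a`, `stat_a`, `sd_or_pct_a`, `n_b`, `stat_b`, `sd_or_pct_b`, `p_value`
#' @export
baseline_table <- function(metadata, grouping = "outcome", scope = NULL,
                           pooled = TRUE) {
  m <- as.data.frame(metadata)
  scope <- scope %||% if (grouping == "group") "all" else "SAM"
  if (scope == "SAM") m <- m[m$group == "SAM", , drop = FALSE]
  g <- as.factor(m[[grouping]])
  g <- droplevels(g)
  if (nlevels(g) != 2)
    stop_fv("baseline_table: grouping '%s' has %d levels, need 2", grouping, nlevels(g))
  a <- g == levels(g)[1]
  rows <- list()
  add <- function(...) rows[[length(rows) + 1L]] <<- data.frame(..., stringsAsFactors = FALSE)
  for (nm in names(.baseline_continuous)) {
    col <- .baseline_continuous[[nm]]
    if (!col %in% names(m)) { message(sprintf("baseline_table: '%s' absent; omitted", col)); next }
    va <- m[[col]][a]; vb <- m[[col]][!a]
    va <- va[!is.na(va)]; vb <- vb[!is.na(vb)]
    if (length(va) < 2 || length(vb) < 2) next
    tt <- t_test_summary(mean(va), stats::sd(va), length(va),
                         mean(vb), stats::sd(vb), length(vb), pooled = pooled)
    p <- if (stats::sd(va) == 0 && stats::sd(vb) == 0 && mean(va) == mean(vb)) 1 else tt$p_value
    add(variable = nm, type = "continuous",
        n_a = length(va), stat_a = mean(va), sd_or_pct_a = stats::sd(va),
        n_b = length(vb), stat_b = mean(vb), sd_or_pct_b = stats::sd(vb),
        p_value = p)
  }
  for (nm in names(.baseline_binary)) {
    col <- .baseline_binary[[nm]]
    if (!col %in% names(m)) { message(sprintf("baseline_table: '%s' absent; omitted", col)); next }
    v <- if (col == "sex") m[[col]] == "male" else as.logical(m[[col]])
    va <- v[a]; vb <- v[!a]
    va <- va[!is.na(va)]; vb <- vb[!is.na(vb)]
    if (!length(va) || !length(vb)) next
    x <- c(sum(va), sum(vb)); n <- c(length(va), length(vb))
    p <- if (x[1] / n[1] == x[2] / n[2]) 1 else
      suppressWarnings(stats::prop.test(x, n, correct = FALSE)$p.value)
    add(variable = nm, type = "binary",
        n_a = n[1], stat_a = x[1], sd_or_pct_a = 100 * x[1] / n[1],
        n_b = n[2], stat_b = x[2], sd_or_pct_b = 100 * x[2] / n[2],
        p_value = p)
  }
  for (col in intersect(c("site", "hiv"), names(m))) {
    tab <- table(m[[col]], g)
    if (nrow(tab) < 2) next
    p <- tryCatch(suppressWarnings(stats::chisq.test(tab)$p.value),
                  error = function(e) NA_real_)
    add(variable = col, type = "categorical",
        n_a = sum(a), stat_a = NA_real_, sd_or_pct_a = NA_real_,
        n_b = sum(!a), stat_b = NA_real_, sd_or_pct_b = NA_real_,
        p_value = p)
  }
  out <- do.call(rbind, rows)
  attr(out, "arms") <- levels(g)
  out
}
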