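# Data model and file I/O for FAIMS dispersion scans, instrument runs and
# cohort metadata.
#
# A FAIMS (field asymmetric ion mobility spectrometry) instrument reports, for
# each ion polarity, a matrix of ion current over a grid of dispersion-field
# strength (percent of maximum, scanned ascending) by compensation voltage
# (volts, scanned from +6 V down to -6 V). The default geometry is 51
# dispersion-field steps by 512 compensation-voltage steps, so one sample
# (both polarities) carries 2 * 51 * 512 = 52,224 data points. Each sample is
# measured in replicate (three instrument runs by default) and one replicate
# (the second by default) is carried forward to analysis.

#' Default dispersion-field axis (percent of maximum field)
#' @param n_df number of dispersion-field steps
#' @return ascending numeric vector of length `n_df`, from 0 to 100
#' @export
default_df_axis <- function(n_df = 51) seq(0, 100, length.out = n_df)

#' Default compensation-voltage axis (volts)
#' @param n_cv number of compensation-voltage steps
#' @return descending numeric vector of length `n_cv`, from +6 to -6
#' @export
default_cv_axis <- function(n_cv = 512) seq(6, -6, length.out = n_cv)

#' Construct a single-polarity dispersion scan
#'
#' @param intensities numeric matrix of ion current (arbitrary units; may be
#'   negative after instrument baseline subtraction), dimensions
#'   `n_df x n_cv` (dispersion field in rows, compensation voltage in columns)
#' @param polarity `"positive"` or `"negative"`
#' @param df_axis dispersion-field percentages (ascending); default spans
#'   0-100% over `nrow(intensities)` steps
#' @param cv_axis compensation voltages (descending); default spans +6 to -6 V
#'   over `ncol(intensities)` steps
#' @return an object of class `dispersion_scan`
#' @export
dispersion_scan <- function(intensities, polarity = c("positive", "negative"),
                            df_axis = NULL, cv_axis = NULL) {
  polarity <- match.arg(polarity)
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  df_axis <- df_axis %||% default_df_axis(nrow(intensities))
  cv_axis <- cv_axis %||% default_cv_axis(ncol(intensities))
  scan <- structure(
    list(polarity = polarity, intensities = intensities,
         df_axis = as.numeric(df_axis), cv_axis = as.numeric(cv_axis)),
    class = "dispersion_scan"
  )
  validate_scan(scan)
}

validate_scan <- function(scan) {
  with(scan, {
    if (nrow(intensities) != length(df_axis))
      stop_fv("scan has %d rows but df_axis has length %d",
              nrow(intensities), length(df_axis))
    if (ncol(intensities) != length(cv_axis))
      stop_fv("scan has %d columns but cv_axis has length %d",
              ncol(intensities), length(cv_axis))
    if (any(!is.finite(intensities)))
      stop_fv("scan intensities contain non-finite values")
    if (length(df_axis) > 1 && any(diff(df_axis) <= 0))
      stop_fv("df_axis must be strictly ascending")
    if (length(cv_axis) > 1 && any(diff(cv_axis) >= 0))
      stop_fv("cv_axis must be strictly descending")
  })
  scan
}

#' @export
print.dispersion_scan <- function(x, ...) {
  cat(sprintf("<dispersion_scan> %s polarity, %d df x %d cv, intensity range [%.3g, %.3g]\n",
              x$polarity, nrow(x$intensities), ncol(x$intensities),
              min(x$intensities), max(x$intensities)))
  invisible(x)
}

#' Construct one instrument run (both polarities of one replicate)
#'
#' @param sample_id opaque sample identifier
#' @param replicate_index replicate number (1-3 on the standard protocol)
#' @param positive,negative `dispersion_scan` objects of matching geometry
#' @return an object of class `instrument_run`
#' @export
instrument_run <- function(sample_id, replicate_index, positive, negative) {
  stopifnot(inherits(positive, "dispersion_scan"),
            inherits(negative, "dispersion_scan"))
  if (positive$polarity != "positive" || negative$polarity != "negative")
    stop_fv("instrument_run: scans supplied with swapped or duplicated polarities")
  if (!identical(dim(positive$intensities), dim(negative$intensities)))
    stop_fv("instrument_run: polarity geometries differ (%s vs %s)",
            paste(dim(positive$intensities), collapse = "x"),
            paste(dim(negative$intensities), collapse = "x"))
  structure(list(sample_id = as.character(sample_id),
                 replicate_index = as.integer(replicate_index),
                 positive = positive, negative = negative),
            class = "instrument_run")
}

#' Select the analysis replicate from a set of instrument runs
#'
#' The standard protocol measures each sample three times and carries the
#' second run forward, as it has been found to give the most useful
#' discriminatory information; the choice is configurable.
#'
#' @param runs list of `instrument_run` objects for one sample
#' @param which replicate index to select (default 2)
#' @return the selected `instrument_run`
#' @export
select_replicate <- function(runs, which = 2) {
  if (length(runs) == 0) stop_fv("select_replicate: empty run list")
  idx <- vapply(runs, function(r) r$replicate_index, integer(1))
  if (anyDuplicated(idx))
    stop_fv("select_replicate: duplicated replicate indices (%s)",
            paste(idx, collapse = ", "))
  hit <- which(idx == which)
  if (length(hit) != 1)
    stop_fv("select_replicate: replicate %d not present; available: %s",
            which, paste(sort(idx), collapse = ", "))
  runs[[hit]]
}

#' Bundle a subject's selected run with its metadata link
#'
#' @param sample_id subject identifier present in the cohort metadata
#' @param selected_run the `instrument_run` carried into analysis
#' @param replicate configured replicate choice the run must match
#' @return an object of class `faims_sample`
#' @export
faims_sample <- function(sample_id, selected_run, replicate = 2) {
  stopifnot(inherits(selected_run, "instrument_run"))
  if (selected_run$replicate_index != replicate)
    stop_fv("faims_sample: selected run is replicate %d, configured replicate is %d",
            selected_run$replicate_index, replicate)
  structure(list(sample_id = as.character(sample_id),
                 selected_run = selected_run),
            class = "faims_sample")
}

# ---------------------------------------------------------------------------
# Matrix-CSV dialect: one file per (sample, replicate, polarity).
# First row: corner label then the cv axis; first column: the df axis;
# remaining cells: intensities. Self-describing and diffable. Axes are stored
# df-ascending / cv-descending; this is a package convention (instrument
# export ordering is vendor-specific).

#' Write a dispersion scan to matrix CSV
#'
#' Values are written with 17 significant digits so that a read/write
#' round-trip reproduces doubles bit-identically.
#'
#' @param scan a `dispersion_scan`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_scan <- function(scan, path) {
  stopifnot(inherits(scan, "dispersion_scan"))
  fmt <- function(x) sprintf("%.17g", x)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c(paste0("df_pct_vs_cv_v:", scan$polarity),
                     fmt(scan$cv_axis)), collapse = ","), con)
  body <- cbind(fmt(scan$df_axis),
                matrix(fmt(scan$intensities), nrow = nrow(scan$intensities)))
  writeLines(apply(body, 1L, paste, collapse = ","), con)
  invisible(path)
}

#' Read a dispersion scan from matrix CSV
#'
#' @param path file in the dialect written by [write_scan()]
#' @param polarity polarity to assign/validate
#' @param geometry optional `c(n_df, n_cv)`; if supplied, a file of any other
#'   shape is rejected with a geometry-mismatch error
#' @return a validated `dispersion_scan`
#' @export
read_scan <- function(path, polarity = c("positive", "negative"),
                      geometry = NULL) {
  polarity <- match.arg(polarity)
  if (!file.exists(path)) stop_fv("read_scan: file not found: %s", path)
  lines <- readLines(path)
  if (length(lines) < 2) stop_fv("read_scan: %s: too few rows for a scan", path)
  cells <- strsplit(lines, ",", fixed = TRUE)
  ncols <- lengths(cells)
  if (any(ncols != ncols[1]))
    stop_fv("read_scan: %s: ragged rows (row %d has %d cells, expected %d)",
            path, which(ncols != ncols[1])[1], ncols[ncols != ncols[1]][1], ncols[1])
  tab <- do.call(rbind, cells)
  parse_num <- function(x, what, rows, cols) {
    out <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(out) & !(trimws(x) %in% c("NA")))
    if (length(bad)) {
      stop_fv("read_scan: %s: non-numeric %s at row %d, column %d ('%s')",
              path, what, rows[bad[1]], cols[bad[1]], x[bad[1]])
    }
    out
  }
  nr <- nrow(tab); nc <- ncol(tab)
  cv_axis <- parse_num(tab[1, -1], "cv-axis value", rep(1L, nc - 1L), 2:nc)
  df_axis <- parse_num(tab[-1, 1], "df-axis value", 2:nr, rep(1L, nr - 1L))
  body <- tab[-1, -1, drop = FALSE]
  idx <- expand.grid(row = 2:nr, col = 2:nc)
  vals <- parse_num(as.vector(body), "intensity", idx$row, idx$col)
  intens <- matrix(vals, nrow = nr - 1L, ncol = nc - 1L)
  if (!is.null(geometry) &&
      !(nrow(intens) == geometry[1] && ncol(intens) == geometry[2]))
    stop_fv("read_scan: %s: geometry mismatch: file is %d x %d, expected %d x %d",
            path, nrow(intens), ncol(intens), geometry[1], geometry[2])
  dispersion_scan(intens, polarity, df_axis = df_axis, cv_axis = cv_axis)
}

# ---------------------------------------------------------------------------
# Cohort metadata

.meta_required <- c("sample_id", "site", "age_months", "sex", "muac_cm",
                    "waz", "whz", "haz", "oedema", "diarrhoea", "vomiting",
                    "fever", "pneumonia", "hiv", "danger_signs", "group",
                    "outcome", "day_of_death")
.meta_sites <- c("CPGH", "KCH", "QECH")
.meta_logical <- c("oedema", "diarrhoea", "vomiting", "fever", "pneumonia",
                   "danger_signs")

#' Validate a cohort metadata table
#'
#' Enforces the clinical-schema invariants: known factor levels; a day of
#' death (1-6) present if and only if the outcome is died; healthy controls
#' never die; HIV status `"unknown"` is a real level (refusal or death before
#' testing), distinct from a missing cell. Missing values in clinical fields
#' are allowed and exclude the subject only from comparisons needing that
#' field.
#'
#' @param meta data.frame with the columns of [read_metadata()]
#' @return the validated data.frame (types coerced), invisibly classed
#'   `cohort_metadata`
#' @export
validate_metadata <- function(meta) {
  if (!is.data.frame(meta) || nrow(meta) == 0)
    stop_fv("metadata: empty table is not a cohort")
  missing_cols <- setdiff(.meta_required, names(meta))
  if (length(missing_cols))
    stop_fv("metadata: missing mandatory column(s): %s",
            paste(missing_cols, collapse = ", "))
  meta$sample_id <- as.character(meta$sample_id)
  if (anyDuplicated(meta$sample_id))
    stop_fv("metadata: duplicated sample_id(s)")
  chk_levels <- function(col, levels, allow_na = FALSE) {
    v <- as.character(meta[[col]])
    bad <- !(v %in% levels) & !(allow_na & is.na(v))
    if (any(bad))
      stop_fv("metadata: column '%s' has invalid value '%s' (row %d)",
              col, v[bad][1], which(bad)[1])
    v
  }
  meta$site <- chk_levels("site", .meta_sites, allow_na = TRUE)
  meta$sex <- chk_levels("sex", c("male", "female"))
  meta$hiv <- chk_levels("hiv", c("negative", "positive", "unknown"))
  meta$group <- chk_levels("group", c("SAM", "healthy_control"))
  meta$outcome <- chk_levels("outcome", c("discharged", "died"))
  for (col in c("age_months", "muac_cm", "waz", "whz", "haz"))
    meta[[col]] <- as.numeric(meta[[col]])
  for (col in .meta_logical) meta[[col]] <- as.logical(meta[[col]])
  meta$day_of_death <- suppressWarnings(as.integer(meta$day_of_death))
  died <- meta$outcome == "died"
  if (any(died & is.na(meta$day_of_death)))
    stop_fv("metadata: outcome 'died' without day_of_death (sample %s)",
            meta$sample_id[died & is.na(meta$day_of_death)][1])
  if (any(!died & !is.na(meta$day_of_death)))
    stop_fv("metadata: day_of_death present for non-died subject (sample %s)",
            meta$sample_id[!died & !is.na(meta$day_of_death)][1])
  bad_day <- died & (meta$day_of_death < 1 | meta$day_of_death > 6)
  if (any(bad_day))
    stop_fv("metadata: day_of_death %d outside the 1-6 day window (sample %s)",
            meta$day_of_death[bad_day][1], meta$sample_id[bad_day][1])
  if (any(meta$group == "healthy_control" & died))
    stop_fv("metadata: healthy_control subject recorded as died (sample %s)",
            meta$sample_id[meta$group == "healthy_control" & died][1])
  class(meta) <- c("cohort_metadata", "data.frame")
  meta
}

#' Read a cohort metadata CSV
#'
#' One row per subject. Required columns: `sample_id`, `site` (CPGH/KCH/QECH),
#' `age_months`, `sex` (male/female), `muac_cm`, `waz`, `whz`, `haz`,
#' `oedema`, `diarrhoea`, `vomiting`, `fever`, `pneumonia` (logical), `hiv`
#' (negative/positive/unknown), `danger_signs` (logical), `group`
#' (SAM/healthy_control), `outcome` (discharged/died), `day_of_death`
#' (integer 1-6, empty unless died).
#'
#' @param path CSV file path
#' @return a validated `cohort_metadata` data.frame
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop_fv("read_metadata: file not found: %s", path)
  if (file.size(path) == 0) stop_fv("read_metadata: %s is empty", path)
  meta <- utils::read.csv(path, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  validate_metadata(meta)
}

#' Write cohort metadata CSV
#' @param meta a `cohort_metadata` (or conforming data.frame)
#' @param path output path
#' @return `path`, invisibly
#' @export
write_metadata <- function(meta, path) {
  utils::write.csv(as.data.frame(meta), path, row.names = FALSE, na = "")
  invisible(path)
}
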