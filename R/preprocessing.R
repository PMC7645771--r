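# Combine the two polarities into one per-sample feature vector and remove
# uninformative background pixels.
#
# Flat layout convention (1-based): the positive-polarity block comes first,
# the negative block second; within a block the matrix is unrolled row-major
# with dispersion field as the outer index and compensation voltage as the
# inner index. So for geometry n_df x n_cv,
#   flat = (polarity_block) * n_df * n_cv + (df_index - 1) * n_cv + cv_index
# with polarity_block 0 for positive, 1 for negative. Index 1 is the positive
# pixel at (df_axis[1], cv_axis[1]); index 2 * n_df * n_cv is the negative
# pixel at (df_axis[n_df], cv_axis[n_cv]). At the default 51 x 512 geometry
# the vector has 52,224 entries.

#' Flatten one instrument run into a single feature vector
#'
#' Positive and negative ion matrices are concatenated into one vector under
#' the package's documented flat layout (positive block first, row-major with
#' compensation voltage innermost).
#'
#' @param run an `instrument_run`
#' @return numeric vector of length `2 * n_df * n_cv` (52,224 at default
#'   geometry), with attributes `sample_id`, `n_df`, `n_cv`
#' @export
combine_polarities <- function(run) {
  stopifnot(inherits(run, "instrument_run"))
  p <- run$positive$intensities
  n <- run$negative$intensities
  if (!identical(dim(p), dim(n)))
    stop_fv("combine_polarities: polarity geometries differ")
  # t() gives row-major order (cv innermost) when flattened
  v <- c(as.vector(t(p)), as.vector(t(n)))
  structure(v, sample_id = run$sample_id, n_df = nrow(p), n_cv = ncol(p))
}

#' Map flat feature indices to instrument coordinates
#'
#' Inverse of the flat layout used by [combine_polarities()]: returns, for
#' each 1-based flat index, the polarity, the dispersion-field percentage and
#' the compensation voltage of that pixel.
#'
#' @param indices integer vector of 1-based flat indices
#' @param n_df,n_cv geometry (defaults 51 x 512)
#' @param df_axis,cv_axis axis values; defaults are the standard instrument
#'   axes for the given geometry
#' @return data.frame with columns `index`, `polarity`, `df_index`,
#'   `cv_index`, `df_percent`, `cv_volts`
#' @export
feature_map_coordinates <- function(indices, n_df = 51, n_cv = 512,
                                    df_axis = NULL, cv_axis = NULL) {
  indices <- as.integer(indices)
  block <- n_df * n_cv
  if (any(indices < 1 | indices > 2 * block))
    stop_fv("feature_map_coordinates: index out of range 1..%d", 2 * block)
  df_axis <- df_axis %||% default_df_axis(n_df)
  cv_axis <- cv_axis %||% default_cv_axis(n_cv)
  pol <- ifelse(indices > block, "negative", "positive")
  within_block <- (indices - 1L) %% block
  df_i <- within_block %/% n_cv + 1L
  cv_i <- within_block %% n_cv + 1L
  data.frame(index = indices, polarity = pol,
             df_index = df_i, cv_index = cv_i,
             df_percent = df_axis[df_i], cv_volts = cv_axis[cv_i],
             stringsAsFactors = FALSE)
}

#' Map instrument coordinates to flat feature indices
#'
#' @param polarity `"positive"` or `"negative"` (vectorised)
#' @param df_index,cv_index 1-based matrix indices (vectorised)
#' @param n_df,n_cv geometry
#' @return integer vector of 1-based flat indices
#' @export
flat_index <- function(polarity, df_index, cv_index, n_df = 51, n_cv = 512) {
  block <- ifelse(polarity == "negative", 1L, 0L) * n_df * n_cv
  as.integer(block + (df_index - 1L) * n_cv + cv_index)
}

#' Stack a cohort's combined feature vectors into a samples x features matrix
#'
#' @param samples list of `faims_sample` (or `instrument_run`) objects
#' @return numeric matrix, one row per sample (rownames = sample ids)
#' @export
feature_matrix <- function(samples) {
  vecs <- lapply(samples, function(s) {
    run <- if (inherits(s, "faims_sample")) s$selected_run else s
    combine_polarities(run)
  })
  len <- unique(lengths(vecs))
  if (length(len) != 1)
    stop_fv("feature_matrix: samples have differing geometries")
  X <- do.call(rbind, lapply(vecs, as.numeric))
  rownames(X) <- vapply(vecs, attr, character(1), "sample_id")
  X
}

# ---------------------------------------------------------------------------
# Background mask

#' Fit a label-blind background mask on training vectors
#'
#' Most of a dispersion plot is background carrying no analyte information.
#' A pixel is retained when its chosen statistic across training samples
#' exceeds the given quantile of that statistic over all pixels. The default
#' statistic is the across-sample standard deviation (a pixel that never
#' varies cannot discriminate anything) at the 50th percentile, halving the
#' feature count. The rule uses no class labels, so a mask fitted on the full
#' cohort leaks no label information into cross-validation; a per-fold refit
#' is available for strictness.
#'
#' @param X samples x features numeric matrix (>= 2 rows)
#' @param statistic `"sd"` (across-sample standard deviation, default) or
#'   `"mean_abs"` (mean absolute intensity)
#' @param quantile retain pixels whose statistic strictly exceeds this
#'   quantile of the statistic's distribution (default 0.5)
#' @param feature_ids optional original flat indices of the columns of `X`
#'   (default `1:ncol(X)`)
#' @param provenance free-text tag recording which samples the mask saw
#'   (e.g. `"all"` or `"fold-3-train"`)
#' @return an object of class `feature_mask`: list with `retained` (sorted
#'   flat indices), `rule` (statistic, quantile, threshold), `n_features`,
#'   `provenance`
#' @export
fit_background_mask <- function(X, statistic = c("sd", "mean_abs"),
                                quantile = 0.5, feature_ids = NULL,
                                provenance = "all") {
  statistic <- match.arg(statistic)
  if (nrow(X) < 2) stop_fv("fit_background_mask: need >= 2 training vectors")
  feature_ids <- feature_ids %||% seq_len(ncol(X))
  stat <- switch(statistic, sd = col_sds(X), mean_abs = colMeans(abs(X)))
  thr <- stats::quantile(stat, quantile, names = FALSE)
  keep <- which(stat > thr)
  if (length(keep) == 0)
    warn_fv("fit_background_mask: degenerate input (no pixel exceeds the threshold); empty mask")
  structure(list(retained = feature_ids[keep],
                 rule = list(statistic = statistic, quantile = quantile,
                             threshold = thr),
                 n_features = ncol(X),
                 provenance = provenance),
            class = "feature_mask")
}

#' @export
print.feature_mask <- function(x, ...) {
  cat(sprintf("<feature_mask> %d / %d pixels retained (%s > %.4g, q = %g; fitted on: %s)\n",
              length(x$retained), x$n_features, x$rule$statistic,
              x$rule$threshold, x$rule$quantile, x$provenance))
  invisible(x)
}

#' Apply a background mask to a feature vector or matrix
#'
#' Retained values are kept in index order and never altered; the retained
#' flat indices travel with the result for back-mapping to instrument
#' coordinates.
#'
#' @param x numeric vector, or samples x features matrix
#' @param mask a `feature_mask`, or an integer vector of flat indices
#' @return masked vector/matrix with attribute `feature_ids` (the retained
#'   flat indices)
#' @export
apply_mask <- function(x, mask) {
  ids <- if (inherits(mask, "feature_mask")) mask$retained else as.integer(mask)
  p <- if (is.matrix(x)) ncol(x) else length(x)
  if (length(ids) && (min(ids) < 1 || max(ids) > p))
    stop_fv("apply_mask: mask index out of range 1..%d", p)
  out <- if (is.matrix(x)) x[, ids, drop = FALSE] else x[ids]
  attr(out, "feature_ids") <- ids
  out
}
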