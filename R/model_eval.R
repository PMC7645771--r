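# Tenfold cross-validation engine with feature selection nested inside each
# training fold.
#
# The data are split into ten folds; for each fold the remaining 90% is the
# training set on which the rank-sum ranking (and, optionally, the background
# mask) is fitted, the top-k features are selected, a classifier is trained,
# and the held-out 10% is scored. Because selection happens within the fold,
# the pooled out-of-fold scores are free of selection leakage. A deliberately
# leaky variant (selection on all samples before splitting) is provided to
# demonstrate the optimistic bias that the nested design avoids.

#' Assign samples to cross-validation folds
#'
#' Deterministic given `seed`. With stratification (default), each class is
#' shuffled and the concatenated classes are dealt cyclically across folds, so
#' fold sizes differ by at most one and each fold's class count is within one
#' sample of the global ratio. A class smaller than the number of folds
#' triggers a fallback to unstratified folds with a warning.
#'
#' @param labels class labels (any type; used only for stratification)
#' @param n_folds number of folds (default 10)
#' @param seed integer seed
#' @param stratified stratify folds by class (default TRUE)
#' @return integer vector of fold ids (1..n_folds), one per sample, with
#'   attributes `n_folds`, `seed`, `stratified`
#' @export
make_folds <- function(labels, n_folds = 10, seed = 1L, stratified = TRUE) {
  labels <- droplevels(as.factor(labels))
  n <- length(labels)
  if (n_folds > n) stop_fv("make_folds: %d folds for %d samples", n_folds, n)
  tab <- table(labels)
  if (any(tab < 1)) stop_fv("make_folds: empty class")
  if (stratified && any(tab < n_folds)) {
    warn_fv("make_folds: class '%s' has %d < %d samples; falling back to unstratified folds",
            names(tab)[tab < n_folds][1], min(tab), n_folds)
    stratified <- FALSE
  }
  fold <- integer(n)
  with_seed(seed, {
    if (stratified) {
      order_all <- unlist(lapply(levels(as.factor(labels)), function(cl) {
        idx <- which(labels == cl)
        if (length(idx) > 1) sample(idx) else idx
      }))
    } else {
      order_all <- sample(n)
    }
    fold[order_all] <- rep_len(seq_len(n_folds), n)
  })
  structure(fold, n_folds = n_folds, seed = seed, stratified = stratified)
}

#' Run cross-validated classification with in-fold feature selection
#'
#' @param X samples x features numeric matrix (typically background-masked;
#'   column identities in `attr(X, "feature_ids")` or `feature_ids`)
#' @param labels factor of two levels; `positive` defaults to the first level
#' @param spec a [classifier_spec()] (or family name)
#' @param k number of features selected per training fold (default 100)
#' @param folds fold assignment from [make_folds()]; built from `n_folds` and
#'   `seed` when NULL
#' @param n_folds,seed,stratified used when `folds` is NULL; `seed` also
#'   seeds per-fold classifier fits
#' @param selection `"in_fold"` (default: rank features on each training fold
#'   only) or `"pooled"` (rank once on all samples before splitting --- the
#'   leaky variant, for bias demonstrations only)
#' @param refit_mask refit the background mask on each training fold
#'   (default FALSE: the label-blind mask is fitted once upstream)
#' @param mask_rule list(statistic, quantile) used when `refit_mask = TRUE`
#' @param positive positive class label
#' @param feature_ids flat indices of the columns of `X`
#' @return a `cv_result`: list with `scores` (data.frame sample, score, label,
#'   fold), `selected` (per-fold list of selected flat indices), `family`,
#'   `k`, `positive`, `classes`, `selection`, `incomplete`, `failed_folds`
#' @export
run_cv <- function(X, labels, spec = classifier_spec("random_forest"),
                   k = 100, folds = NULL, n_folds = 10, seed = 1L,
                   stratified = TRUE, selection = c("in_fold", "pooled"),
                   refit_mask = FALSE,
                   mask_rule = list(statistic = "sd", quantile = 0.5),
                   positive = NULL, feature_ids = NULL) {
  selection <- match.arg(selection)
  if (is.character(spec)) spec <- classifier_spec(spec, seed = seed)
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) != 2) stop_fv("run_cv: need exactly 2 classes")
  positive <- positive %||% levels(labels)[1]
  feature_ids <- feature_ids %||% attr(X, "feature_ids") %||% seq_len(ncol(X))
  if (is.null(folds)) folds <- make_folds(labels, n_folds, seed, stratified)
  nf <- attr(folds, "n_folds") %||% max(folds)

  col_of <- match(feature_ids, feature_ids)  # identity; selected ids -> columns
  pooled_sel <- NULL
  if (selection == "pooled") {
    rk <- rank_sum_feature_scores(X, labels, feature_ids = feature_ids,
                                  provenance = "pooled (leaky)")
    pooled_sel <- top_k_features(rk, k)
  }

  scores <- rep(NA_real_, nrow(X))
  selected <- vector("list", nf)
  failed <- integer(0)
  for (f in seq_len(nf)) {
    te <- which(folds == f)
    tr <- which(folds != f)
    if (length(te) == 0) next
    Xtr <- X[tr, , drop = FALSE]
    Xte <- X[te, , drop = FALSE]
    ids_f <- feature_ids
    if (refit_mask) {
      m <- fit_background_mask(Xtr, statistic = mask_rule$statistic,
                               quantile = mask_rule$quantile,
                               feature_ids = feature_ids,
                               provenance = sprintf("fold-%d-train", f))
      keep_cols <- match(m$retained, feature_ids)
      Xtr <- Xtr[, keep_cols, drop = FALSE]
      Xte <- Xte[, keep_cols, drop = FALSE]
      ids_f <- m$retained
    }
    sel <- if (selection == "in_fold") {
      rk <- rank_sum_feature_scores(Xtr, labels[tr], feature_ids = ids_f,
                                    provenance = sprintf("fold-%d-train", f))
      top_k_features(rk, k)
    } else pooled_sel
    sel_cols <- match(sel, ids_f)
    fs <- tryCatch(
      fit_predict(spec, Xtr[, sel_cols, drop = FALSE], labels[tr],
                  Xte[, sel_cols, drop = FALSE], positive = positive,
                  seed = child_seed(seed, f)),
      error = function(e) {
        warn_fv("run_cv: classifier failed in fold %d (%s); fold skipped",
                f, conditionMessage(e))
        NULL
      })
    if (is.null(fs)) { failed <- c(failed, f); next }
    scores[te] <- fs
    selected[[f]] <- sel
  }

  ids <- rownames(X) %||% as.character(seq_len(nrow(X)))
  structure(list(
    scores = data.frame(sample = ids, score = scores,
                        label = as.character(labels), fold = as.integer(folds),
                        stringsAsFactors = FALSE),
    selected = selected, family = spec$family, k = k,
    positive = positive, classes = levels(labels),
    selection = selection, seed = seed,
    incomplete = length(failed) > 0, failed_folds = failed
  ), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  ok <- !is.na(x$scores$score)
  cat(sprintf("<cv_result> %s, k = %d, %d samples scored%s (positive class: %s, selection: %s)\n",
              x$family, x$k, sum(ok),
              if (x$incomplete) sprintf(", folds failed: %s", paste(x$failed_folds, collapse = ",")) else "",
              x$positive, x$selection))
  invisible(x)
}

#' Pooled out-of-fold AUC of a cross-validation result
#' @param cv a `cv_result`
#' @return scalar AUC of the pooled out-of-fold scores
#' @export
cv_auc <- function(cv) {
  ok <- !is.na(cv$scores$score)
  roc_auc(cv$scores$score[ok], cv$scores$label[ok], positive = cv$positive)$auc
}

#' Run every comparison x classifier family x feature count
#'
#' The full study grid: for each resolvable comparison, tenfold
#' cross-validation is run for each classifier family and each k, and the
#' best-performing (highest pooled AUC) cell per comparison is flagged.
#'
#' @param X samples x features matrix with rownames = sample ids (already
#'   background-masked; flat indices in `attr(X, "feature_ids")`)
#' @param metadata a `cohort_metadata` covering the rows of `X`
#' @param comparisons list of comparison specs (default [builtin_comparisons()])
#' @param families classifier family names (default all four)
#' @param ks feature counts (default `c(100, 50, 20)`)
#' @param n_folds,seed cross-validation settings
#' @param n_boot,n_perm inference settings passed to [performance_report()]
#' @param hyper named list of per-family hyperparameter overrides
#' @return a `run_all_result`: list with `report` (one data.frame row per
#'   (comparison, family, k) incl. `best` flag) and `results` (the
#'   `cv_result` objects, named `comparison:family:k`)
#' @export
run_all <- function(X, metadata, comparisons = builtin_comparisons(),
                    families = .classifier_families, ks = c(100, 50, 20),
                    n_folds = 10, seed = 1L, n_boot = 2000, n_perm = 10000,
                    hyper = list()) {
  results <- list()
  rows <- list()
  for (ci in seq_along(comparisons)) {
    cmp <- comparisons[[ci]]
    arms <- tryCatch(resolve(cmp, metadata), error = function(e) {
      message(sprintf("run_all: comparison '%s' skipped: %s", cmp$id,
                      conditionMessage(e)))
      NULL
    })
    if (is.null(arms)) next
    ids <- c(arms$arm_a, arms$arm_b)
    keep <- match(ids, rownames(X))
    if (anyNA(keep)) stop_fv("run_all: metadata sample(s) missing from X: %s",
                             paste(ids[is.na(keep)][1], collapse = ", "))
    lab <- factor(rep(c(cmp$arm_a_name, cmp$arm_b_name),
                      c(length(arms$arm_a), length(arms$arm_b))),
                  levels = c(cmp$arm_a_name, cmp$arm_b_name))
    Xc <- X[keep, , drop = FALSE]
    attr(Xc, "feature_ids") <- attr(X, "feature_ids")
    folds <- make_folds(lab, n_folds, seed = child_seed(seed, ci))
    for (fam in families) for (k in ks) {
      spec <- classifier_spec(fam, hyper = hyper[[fam]] %||% list(),
                              seed = child_seed(seed, ci))
      cv <- run_cv(Xc, lab, spec, k = k, folds = folds,
                   seed = child_seed(seed, ci))
      rep1 <- performance_report(cv, comparison = cmp$id, n_boot = n_boot,
                                 n_perm = n_perm,
                                 seed = child_seed(seed, ci))
      results[[paste(cmp$id, fam, k, sep = ":")]] <- cv
      rows[[length(rows) + 1L]] <- rep1
    }
  }
  report <- do.call(rbind, rows)
  report$best <- FALSE
  for (cid in unique(report$comparison)) {
    sub <- which(report$comparison == cid)
    report$best[sub[which.max(report$auc[sub])]] <- TRUE
  }
  structure(list(report = report, results = results),
            class = "run_all_result")
}
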