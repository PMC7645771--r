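# Performance reporting: ROC/AUC with confidence intervals and permutation
# p-values, Youden operating points, predictive values, and reconstruction of
# integer confusion matrices from published 2-decimal summaries.

#' ROC curve and AUC from pooled scores
#'
#' The AUC equals the Mann-Whitney concordance probability (ties counted 1/2),
#' and the returned curve's trapezoidal integral equals it exactly. The curve
#' starts at (0,0), ends at (1,1) and is non-decreasing in both coordinates.
#'
#' @param scores numeric scores, higher = more like the positive class
#' @param labels two-class labels
#' @param positive label counting as positive (default: first factor level)
#' @return list with `curve` (data.frame `threshold`, `fpr`, `tpr`; the
#'   threshold is the smallest score still called positive) and `auc`
#' @export
roc_auc <- function(scores, labels, positive = NULL) {
  labels <- droplevels(as.factor(labels))
  positive <- positive %||% levels(labels)[1]
  pos <- labels == positive
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0)
    stop_fv("roc_auc: both classes must be present (got %d positive, %d negative)",
            n_pos, n_neg)
  if (anyNA(scores)) stop_fv("roc_auc: scores contain NA")
  # Mann-Whitney concordance via ranks (ties averaged = half credit)
  r <- rank(scores)
  auc <- (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  # staircase: descending unique thresholds, cumulative TP/FP
  thr <- sort(unique(scores), decreasing = TRUE)
  tp <- vapply(thr, function(t) sum(scores[pos] >= t), numeric(1))
  fp <- vapply(thr, function(t) sum(scores[!pos] >= t), numeric(1))
  curve <- data.frame(threshold = c(Inf, thr),
                      fpr = c(0, fp / n_neg), tpr = c(0, tp / n_pos))
  list(curve = curve, auc = auc,
       n_pos = n_pos, n_neg = n_neg, positive = positive)
}

#' Confidence interval and p-value for an AUC
#'
#' The 95% CI is a stratified nonparametric bootstrap (resampling scores
#' within each class, percentile interval; default 2000 resamples) or the
#' DeLong asymptotic interval. The p-value is the one-sided probability,
#' under random relabelling of samples (default 10,000 permutations), of an
#' AUC at least as large as observed --- i.e. a permutation test against
#' AUC = 0.5.
#'
#' @param scores,labels,positive as in [roc_auc()]
#' @param ci_method `"bootstrap"` (default) or `"delong"`
#' @param n_boot bootstrap resamples
#' @param n_perm label permutations
#' @param seed RNG seed
#' @return list with `auc`, `ci` (length-2), `p_value`, `ci_method`, `n_boot`,
#'   `n_perm`
#' @export
auc_inference <- function(scores, labels, positive = NULL,
                          ci_method = c("bootstrap", "delong"),
                          n_boot = 2000, n_perm = 10000, seed = 1L) {
  ci_method <- match.arg(ci_method)
  labels <- droplevels(as.factor(labels))
  positive <- positive %||% levels(labels)[1]
  pos_scores <- scores[labels == positive]
  neg_scores <- scores[labels != positive]
  n_pos <- length(pos_scores); n_neg <- length(neg_scores)
  if (n_pos < 2 || n_neg < 2)
    stop_fv("auc_inference: need >= 2 samples per class (got %d/%d)", n_pos, n_neg)
  obs <- roc_auc(scores, labels, positive)$auc

  auc_of <- function(ps, ns) {
    r <- rank(c(ps, ns))
    (sum(r[seq_along(ps)]) - length(ps) * (length(ps) + 1) / 2) /
      (length(ps) * length(ns))
  }

  ci <- with_seed(child_seed(seed, 1), {
    if (ci_method == "bootstrap") {
      boots <- vapply(seq_len(n_boot), function(b) {
        auc_of(sample(pos_scores, n_pos, replace = TRUE),
               sample(neg_scores, n_neg, replace = TRUE))
      }, numeric(1))
      stats::quantile(boots, c(0.025, 0.975), names = FALSE)
    } else {
      delong_ci(pos_scores, neg_scores)
    }
  })

  p <- with_seed(child_seed(seed, 2), {
    r_all <- rank(scores)
    n <- length(scores)
    perm <- vapply(seq_len(n_perm), function(b) {
      idx <- sample.int(n, n_pos)
      (sum(r_all[idx]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
    }, numeric(1))
    (1 + sum(perm >= obs)) / (n_perm + 1)
  })

  list(auc = obs, ci = as.numeric(ci), p_value = p,
       ci_method = ci_method, n_boot = n_boot, n_perm = n_perm)
}

# DeLong (1988) variance of the AUC via placement values.
delong_ci <- function(pos_scores, neg_scores, level = 0.95) {
  m <- length(pos_scores); n <- length(neg_scores)
  psi <- outer(pos_scores, neg_scores,
               function(a, b) (a > b) + 0.5 * (a == b))
  auc <- mean(psi)
  v10 <- rowMeans(psi); v01 <- colMeans(psi)
  s2 <- stats::var(v10) / m + stats::var(v01) / n
  z <- stats::qnorm(1 - (1 - level) / 2)
  c(max(0, auc - z * sqrt(s2)), min(1, auc + z * sqrt(s2)))
}

#' Youden-optimal operating point of a ROC curve
#'
#' Maximises J = sensitivity + specificity - 1 over the curve's thresholds;
#' ties are broken in favour of higher sensitivity.
#'
#' @param curve the `curve` data.frame from [roc_auc()] (or the whole list)
#' @return list with `threshold`, `sensitivity`, `specificity`, `j`
#' @export
operating_point <- function(curve) {
  if (is.list(curve) && !is.data.frame(curve)) curve <- curve$curve
  j <- curve$tpr - curve$fpr
  # tie window absorbs float noise in tpr - fpr for equal rational J values
  best <- which(j >= max(j) - 1e-12)
  pick <- best[which.max(curve$tpr[best])]
  list(threshold = curve$threshold[pick],
       sensitivity = curve$tpr[pick],
       specificity = 1 - curve$fpr[pick],
       j = j[pick])
}

#' Positive and negative predictive values at the cohort prevalence
#'
#' `ppv = sens * n_pos / (sens * n_pos + (1 - spec) * n_neg)`;
#' `npv = spec * n_neg / (spec * n_neg + (1 - sens) * n_pos)`.
#'
#' @param sensitivity,specificity rates in [0,1]
#' @param n_pos,n_neg class sizes (>= 1)
#' @return list with `ppv`, `npv` (NA with a warning on a zero denominator)
#' @export
predictive_values <- function(sensitivity, specificity, n_pos, n_neg) {
  stopifnot(sensitivity >= 0, sensitivity <= 1,
            specificity >= 0, specificity <= 1, n_pos >= 1, n_neg >= 1)
  dp <- sensitivity * n_pos + (1 - specificity) * n_neg
  dn <- specificity * n_neg + (1 - sensitivity) * n_pos
  ppv <- if (dp > 0) sensitivity * n_pos / dp else { warn_fv("predictive_values: no positive calls; PPV undefined"); NA_real_ }
  npv <- if (dn > 0) specificity * n_neg / dn else { warn_fv("predictive_values: no negative calls; NPV undefined"); NA_real_ }
  list(ppv = ppv, npv = npv)
}

#' Reconstruct the integer confusion matrix behind printed rates
#'
#' Published tables print sensitivity/specificity to two decimals without
#' stating which arm was the positive class. Given the two printed rates and
#' the two arm sizes, this searches both orientations for integer TP/TN counts
#' whose rates round (half up) to the printed values.
#'
#' @param printed_sens,printed_spec rates as printed (2 decimals)
#' @param n_a,n_b the two arm sizes as printed
#' @return data.frame of candidate solutions with columns `orientation`
#'   (`"a_positive"`/`"b_positive"`), `n_pos`, `n_neg`, `tp`, `fn`, `tn`,
#'   `fp`, `sensitivity`, `specificity`; attribute `unique` is TRUE when a
#'   single solution (up to symmetric equivalence) exists. Errors if no
#'   integer solution matches.
#' @export
reconstruct_confusion <- function(printed_sens, printed_spec, n_a, n_b) {
  search_one <- function(orientation, n_pos, n_neg) {
    tp <- which(round_half_up(0:n_pos / n_pos, 2) == printed_sens) - 1L
    tn <- which(round_half_up(0:n_neg / n_neg, 2) == printed_spec) - 1L
    if (!length(tp) || !length(tn)) return(NULL)
    g <- expand.grid(tp = tp, tn = tn)
    data.frame(orientation = orientation, n_pos = n_pos, n_neg = n_neg,
               tp = g$tp, fn = n_pos - g$tp, tn = g$tn, fp = n_neg - g$tn,
               sensitivity = g$tp / n_pos, specificity = g$tn / n_neg,
               stringsAsFactors = FALSE)
  }
  out <- rbind(search_one("a_positive", n_a, n_b),
               search_one("b_positive", n_b, n_a))
  if (is.null(out) || nrow(out) == 0)
    stop_fv("reconstruct_confusion: no integer confusion matrix rounds to sens %.2f / spec %.2f at sizes %d/%d",
            printed_sens, printed_spec, n_a, n_b)
  # two orientations describing the same physical table count as one solution:
  # canonical key = (correct calls in arm A, correct calls in arm B)
  key <- ifelse(out$orientation == "a_positive",
                paste(out$tp, out$tn), paste(out$tn, out$tp))
  attr(out, "unique") <- length(unique(key)) == 1
  out
}

#' Full performance report for one cross-validation result
#'
#' One published-table row: pooled out-of-fold AUC with 95% CI and permutation
#' p-value, the Youden operating point's sensitivity/specificity, and
#' PPV/NPV at the comparison's prevalence.
#'
#' @param cv a `cv_result`
#' @param comparison comparison identifier for the report row
#' @param n_boot,n_perm,ci_method,seed inference settings ([auc_inference()])
#' @return one-row data.frame: `comparison`, `family`, `k`, `n_pos`, `n_neg`,
#'   `positive`, `auc`, `ci_low`, `ci_high`, `p_value`, `threshold`,
#'   `sensitivity`, `specificity`, `ppv`, `npv`, `incomplete`
#' @export
performance_report <- function(cv, comparison = "comparison",
                               n_boot = 2000, n_perm = 10000,
                               ci_method = "bootstrap", seed = 1L) {
  stopifnot(inherits(cv, "cv_result"))
  ok <- !is.na(cv$scores$score)
  scores <- cv$scores$score[ok]
  labels <- cv$scores$label[ok]
  roc <- roc_auc(scores, labels, positive = cv$positive)
  inf <- auc_inference(scores, labels, positive = cv$positive,
                       ci_method = ci_method, n_boot = n_boot,
                       n_perm = n_perm, seed = seed)
  op <- operating_point(roc$curve)
  pv <- predictive_values(op$sensitivity, op$specificity, roc$n_pos, roc$n_neg)
  data.frame(comparison = comparison, family = cv$family, k = cv$k,
             n_pos = roc$n_pos, n_neg = roc$n_neg, positive = cv$positive,
             auc = roc$auc, ci_low = inf$ci[1], ci_high = inf$ci[2],
             p_value = inf$p_value, threshold = op$threshold,
             sensitivity = op$sensitivity, specificity = op$specificity,
             ppv = pv$ppv, npv = pv$npv, incomplete = cv$incomplete,
             stringsAsFactors = FALSE)
}
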