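# Rank-sum (Wilcoxon / Mann-Whitney) feature ranking and top-k selection.
#
# Every retained pixel is scored by a two-sample rank-sum test between the two
# class arms of the training data; the k smallest two-sided p-values are kept
# (k = 100 by default; 50 and 20 are also standard). Selection runs inside
# each cross-validation training fold, never on test samples.

#' Score every feature by a two-sample rank-sum test
#'
#' For each column of `X`, computes the Mann-Whitney U statistic of the first
#' class (U = rank sum of class-A values minus nA(nA+1)/2) and a two-sided
#' p-value. P-values are exact (closed-form null distribution) when both
#' classes have at most `exact_max` samples and the feature has no ties;
#' with ties in a small sample the label assignments are enumerated
#' exhaustively when feasible; otherwise a tie-corrected,
#' continuity-corrected normal approximation is used (the same approximation
#' as [stats::wilcox.test()]). A feature constant across all samples gets
#' p = 1 by convention.
#'
#' @param X samples x features numeric matrix
#' @param labels factor (or coercible) with exactly two levels; the first
#'   level is class A
#' @param feature_ids original flat indices of the columns (default
#'   `attr(X, "feature_ids")`, else `1:ncol(X)`)
#' @param exact_max use an exact p-value when both class sizes are at most
#'   this (default 10)
#' @param enum_cap with ties, enumerate label assignments exhaustively only
#'   when `choose(n, nA)` is at most this (default 20000)
#' @param provenance tag recording which samples were scored
#' @return a `feature_ranking`: data.frame with columns `feature_id`,
#'   `statistic` (U for class A), `p_value`, `rank` (1 = most discriminatory;
#'   ties in p broken by ascending feature id)
#' @export
rank_sum_feature_scores <- function(X, labels, feature_ids = NULL,
                                    exact_max = 10, enum_cap = 20000,
                                    provenance = "all") {
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) != 2)
    stop_fv("rank_sum_feature_scores: need exactly 2 classes, got %d", nlevels(labels))
  if (!is.matrix(X)) X <- matrix(X, ncol = 1L)
  if (nrow(X) != length(labels))
    stop_fv("rank_sum_feature_scores: %d rows but %d labels", nrow(X), length(labels))
  feature_ids <- feature_ids %||% attr(X, "feature_ids") %||% seq_len(ncol(X))
  a <- labels == levels(labels)[1]
  nA <- sum(a); nB <- sum(!a); n <- nA + nB
  if (nA == 0 || nB == 0) stop_fv("rank_sum_feature_scores: a class is empty")

  R <- col_ranks(X)
  if (!is.matrix(R)) R <- matrix(R, ncol = ncol(X))
  U <- colSums(R[a, , drop = FALSE]) - nA * (nA + 1) / 2

  # tie structure per feature; sum(t^3 - t) over tie groups drives both the
  # tie detection and the variance correction (0 = no ties)
  tie_term <- vapply(seq_len(ncol(X)), function(j) {
    v <- X[, j]
    if (anyDuplicated(v) == 0L) return(0)
    t <- tabulate(match(v, v))
    t <- t[t > 1L]
    sum(t^3 - t)
  }, numeric(1))
  has_tie <- tie_term > 0
  constant <- tie_term >= n^3 - n  # single tie group of size n

  p <- numeric(ncol(X))
  small <- nA <= exact_max && nB <= exact_max

  exact_ok <- small & !has_tie
  if (any(exact_ok)) {
    u <- U[exact_ok]
    lo <- stats::pwilcox(u, nA, nB)
    hi <- 1 - stats::pwilcox(u - 1, nA, nB)
    p[exact_ok] <- pmin(1, 2 * pmin(lo, hi))
  }

  enum_ok <- small & has_tie & !constant & choose(n, nA) <= enum_cap
  if (any(enum_ok)) {
    combs <- utils::combn(n, nA)
    for (j in which(enum_ok)) {
      r <- R[, j]
      u_all <- colSums(matrix(r[combs], nrow = nA)) - nA * (nA + 1) / 2
      # two-sided exact permutation p: distance from the null mean
      dev <- abs(u_all - nA * nB / 2)
      p[j] <- mean(dev >= abs(U[j] - nA * nB / 2) - 1e-9)
    }
  }

  approx_idx <- which(!(exact_ok | enum_ok) & !constant)
  if (length(approx_idx)) {
    mu <- nA * nB / 2
    sigma2 <- (nA * nB / 12) *
      ((n + 1) - tie_term[approx_idx] / (n * (n - 1)))
    sigma2[sigma2 < 0] <- 0
    z <- U[approx_idx] - mu
    cc <- sign(z) * 0.5  # continuity correction toward the mean
    pj <- 2 * stats::pnorm(-abs(z - cc) / sqrt(sigma2))
    pj[sigma2 == 0] <- 1
    p[approx_idx] <- pmin(1, pj)
  }

  p[constant] <- 1
  U[constant] <- nA * nB / 2

  ord <- order(p, feature_ids)
  rk <- integer(length(p)); rk[ord] <- seq_along(p)
  out <- data.frame(feature_id = feature_ids, statistic = as.numeric(U),
                    p_value = p, rank = rk)
  structure(out, class = c("feature_ranking", "data.frame"),
            classes = levels(labels), n_per_class = c(nA, nB),
            provenance = provenance)
}

#' Keep the top k features of a ranking
#'
#' Selects the k smallest two-sided p-values, ties broken by ascending flat
#' index, so a re-run on the same data always selects the same set.
#'
#' @param ranking a `feature_ranking`
#' @param k number of features to keep (default 100); if k exceeds the
#'   number of ranked features, all are returned with a warning
#' @return integer vector of selected flat feature indices, in rank order
#' @export
top_k_features <- function(ranking, k = 100) {
  stopifnot(inherits(ranking, "feature_ranking"), k >= 1)
  if (k > nrow(ranking)) {
    warn_fv("top_k_features: k = %d exceeds the %d ranked features; returning all",
            k, nrow(ranking))
    k <- nrow(ranking)
  }
  ord <- order(ranking$rank)
  ranking$feature_id[ord][seq_len(k)]
}
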