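# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a fixed RNG seed, restoring the caller's RNG state
#' @noRd
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Derive a child seed from a base seed, kept inside 32-bit integer range
#' @noRd
child_seed <- function(seed, index) {
  (as.numeric(seed) * 1009 + index * 101) %% 2147483647
}

#' Round half away from zero, as report tables print (2.5 -> 3, not 2)
#'
#' Base [round()] rounds half to even; published clinical tables round half up.
#'
#' @param x numeric vector
#' @param digits number of decimal places
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 2) {
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

#' Column standard deviations without an n x p apply loop
#' @noRd
col_sds <- function(X) {
  n <- nrow(X)
  if (n < 2) stop("need at least 2 rows to compute a standard deviation")
  mu <- colMeans(X)
  ss <- colSums(X^2) - n * mu^2
  ss[ss < 0] <- 0  # guard tiny negative from float cancellation
  sqrt(ss / (n - 1))
}

#' Column ranks (ties averaged)
#' @noRd
col_ranks <- function(X) {
  apply(X, 2L, rank, ties.method = "average")
}

stop_fv <- function(...) stop(sprintf(...), call. = FALSE)
warn_fv <- function(...) warning(sprintf(...), call. = FALSE)
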