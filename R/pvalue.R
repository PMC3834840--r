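#' Exact permutation p-value for the outlier count
#'
#' Probability, under uniformly random reassignment of the `n1` control and
#' `n2` case labels to the `n1 + n2` samples (expression values held fixed and
#' assumed distinct), that at least `k` case-labelled samples lie beyond the
#' extremum of the control-labelled samples. This happens exactly when the `k`
#' most extreme of the pooled values all carry case labels, giving the closed
#' form
#'
#' \deqn{P(K \ge k) = \prod_{i=0}^{k-1} \frac{n_2 - i}{n_1 + n_2 - i},
#'       \qquad P(K \ge 0) = 1.}
#'
#' The p-value depends only on the outlier count, not on the magnitude of the
#' excess expression, and is therefore conservative. When a case value ties
#' the control extremum it is not counted in `k` (the permutation model
#' assumes distinct values), which is again conservative.
#'
#' @param k Observed number of outlier case samples, `0 <= k <= n2`.
#'   Vectorised; recycled against `n1`, `n2`.
#' @param n1 Number of control samples (>= 1).
#' @param n2 Number of case samples (>= 1).
#'
#' @return Numeric vector of probabilities in `(0, 1]`.
#' @examples
#' dids_pvalue(2, 2, 2)     # 1/6
#' dids_pvalue(0:3, 5, 3)
#' @export
dids_pvalue <- function(k, n1, n2) {
  if (length(k) == 0L) return(numeric(0))
  args <- vctrs_recycle(k, n1, n2)
  k <- args[[1]]; n1 <- args[[2]]; n2 <- args[[3]]
  if (anyNA(k) || anyNA(n1) || anyNA(n2)) {
    abort("`k`, `n1` and `n2` must not contain missing values")
  }
  if (any(n1 < 1) || any(n2 < 1)) {
    abort("group sizes `n1` and `n2` must both be >= 1")
  }
  if (any(k < 0) || any(k > n2)) {
    abort("`k` must satisfy 0 <= k <= n2")
  }
  if (any(k != trunc(k)) || any(n1 != trunc(n1)) || any(n2 != trunc(n2))) {
    abort("`k`, `n1` and `n2` must be integers")
  }
  mapply(function(k, n1, n2) {
    if (k == 0) return(1)
    i <- 0:(k - 1)
    prod((n2 - i) / (n1 + n2 - i))
  }, k, n1, n2)
}

# tail table P(K >= k) for k = 0..n2 (index k+1); used by the vectorised
# matrix engine where n1, n2 are constant across genes
pvalue_table <- function(n1, n2) {
  i <- 0:(n2 - 1)
  c(1, cumprod((n2 - i) / (n1 + n2 - i)))
}

# minimal common-length recycling (scalar against vector)
vctrs_recycle <- function(...) {
  xs <- list(...)
  n <- max(lengths(xs))
  lapply(xs, function(x) {
    if (length(x) == n) x
    else if (length(x) == 1L) rep(x, n)
    else abort("arguments must have length 1 or a common length")
  })
}
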