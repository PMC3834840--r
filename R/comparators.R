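# Comparator outlier statistics; formulas follow the original publications:
#   COPA: Tomlins et al. 2005 / MacDonald & Ghosh 2006 (percentile contrast
#         of cases against the overall median, MAD-scaled)
#   OS:   Tibshirani & Hastie 2007 (sum of standardised case values beyond
#         q75(all) + IQR(all))
#   ORT:  Wu 2007 (sum of control-median-centred case values beyond
#         q75(controls) + IQR(controls), robustly scaled)
#   MOST: Lian 2008 (maximum over k of standardised ordered-subset sums)
# The MAD-style robust scales all use the 1.4826 normal-consistency factor so
# the statistics are comparable across methods; scaling does not affect
# within-method rankings. A degenerate (zero) robust scale yields NA — a
# flagged sentinel ranked last, never an infinity.

#' COPA statistic
#'
#' Cancer Outlier Profile Analysis: the `r`-th percentile of the case values,
#' centred by the overall median and scaled by the overall MAD (1.4826
#' scaling). Large positive values indicate case over-expression in a
#' subgroup.
#'
#' @param controls,cases Numeric expression vectors for the two groups.
#' @param r Percentile in (0.5, 1); default 0.90.
#' @return A single statistic; `NA` when the overall MAD is zero.
#' @export
copa_stat <- function(controls, cases, r = 0.90) {
  if (r <= 0.5 || r >= 1) abort("`r` must lie in (0.5, 1)")
  all <- c(controls, cases)
  scale <- stats::mad(all)  # 1.4826 * median(|x - median|)
  if (scale == 0) return(NA_real_)
  (stats::quantile(cases, r, names = FALSE) - stats::median(all)) / scale
}

#' Outlier-sums (OS) statistic
#'
#' Standardises all values by the overall median and MAD, then sums the
#' standardised case values exceeding `q75(all) + IQR(all)`. Zero when no
#' case exceeds the cutoff.
#'
#' @inheritParams copa_stat
#' @return A single statistic; `NA` when the overall MAD is zero.
#' @export
os_stat <- function(controls, cases) {
  all <- c(controls, cases)
  if (length(all) < 4L) abort("OS needs n1 + n2 >= 4")
  med <- stats::median(all)
  scale <- stats::mad(all)
  if (scale == 0) return(NA_real_)
  q <- stats::quantile(all, c(0.25, 0.75), names = FALSE)
  cutoff <- q[2] + (q[2] - q[1])
  sum((cases[cases > cutoff] - med) / scale)
}

#' Outlier-robust t-statistic (ORT)
#'
#' Outliers are case values above `q75(controls) + IQR(controls)`. The
#' statistic sums their deviations from the control median, divided by the
#' median absolute deviation of group-median-centred values pooled over both
#' groups (1.4826 scaling). Zero when no case exceeds the control fence.
#'
#' @inheritParams copa_stat
#' @return A single statistic; `NA` when the pooled robust scale is zero.
#' @export
ort_stat <- function(controls, cases) {
  if (length(controls) < 4L) abort("ORT needs n1 >= 4 for control quartiles")
  q <- stats::quantile(controls, c(0.25, 0.75), names = FALSE)
  cutoff <- q[2] + (q[2] - q[1])
  medc <- stats::median(controls)
  devs <- c(abs(controls - medc), abs(cases - stats::median(cases)))
  scale <- 1.4826 * stats::median(devs)
  if (scale == 0) return(NA_real_)
  sum(cases[cases > cutoff] - medc) / scale
}

# ---- MOST ------------------------------------------------------------------

# Monte-Carlo normalisation constants: mu_k, sigma_k of the cumulative sums
# of the top-k order statistics of n2 iid N(0,1) draws. Cached per n2 under a
# fixed internal seed so every session reproduces the same constants.
.most_cache <- new.env(parent = emptyenv())

most_constants <- function(n2, n_rep = 1e5) {
  key <- paste0("n", n2, "_r", n_rep)
  if (!is.null(.most_cache[[key]])) return(.most_cache[[key]])
  cons <- with_seed_(190741L, {
    x <- matrix(rnorm(n_rep * n2), nrow = n_rep)
    sorted <- matrix(x[order(row(x), -x)], nrow = n_rep, byrow = TRUE)
    cums <- t(apply(sorted, 1L, cumsum))
    if (n2 == 1L) cums <- matrix(sorted, ncol = 1L)
    list(mu = colMeans(cums), sigma = apply(cums, 2L, stats::sd))
  })
  .most_cache[[key]] <- cons
  cons
}

most_core <- function(cases_sorted_desc, medc, scale, cons) {
  n2 <- length(cases_sorted_desc)
  m <- (cumsum(cases_sorted_desc) - seq_len(n2) * medc) / scale
  z <- (m - cons$mu) / cons$sigma
  k <- which.max(z)
  c(statistic = z[k], k = k)
}

#' Maximum-ordered-subset t-statistic (MOST)
#'
#' Sorts the case values in decreasing order; for each subset size `k`,
#' the sum of the top-`k` deviations from the control median (robustly
#' scaled as in [ort_stat()]) is standardised by the Monte-Carlo mean and
#' standard deviation of the matching sum of standard-normal order
#' statistics; the statistic is the maximum over `k`. The maximising `k`
#' (an estimate of the aberrant-subgroup size) is attached as attribute
#' `"k"`.
#'
#' @inheritParams copa_stat
#' @param n_rep Monte-Carlo replicates for the normalisation constants
#'   (cached per case-group size).
#' @return A single statistic with attribute `k`; `NA` when the pooled
#'   robust scale is zero.
#' @export
most_stat <- function(controls, cases, n_rep = 1e5) {
  if (length(cases) < 2L) abort("MOST needs n2 >= 2")
  medc <- stats::median(controls)
  devs <- c(abs(controls - medc), abs(cases - stats::median(cases)))
  scale <- 1.4826 * stats::median(devs)
  if (scale == 0) return(NA_real_)
  cons <- most_constants(length(cases), n_rep)
  out <- most_core(sort(cases, decreasing = TRUE), medc, scale, cons)
  structure(out[["statistic"]], k = as.integer(out[["k"]]))
}

# ---- classical two-sample tests -------------------------------------------

t_core <- function(m1, m2, v1, v2, n1, n2, equal_var) {
  if (equal_var) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se2 <- sp2 * (1 / n1 + 1 / n2)
    df <- rep(n1 + n2 - 2, length.out = length(se2))
  } else {
    a <- v1 / n1; b <- v2 / n2
    se2 <- a + b
    df <- se2^2 / (a^2 / (n1 - 1) + b^2 / (n2 - 1))
  }
  t <- (m2 - m1) / sqrt(se2)
  t[se2 == 0] <- NA_real_
  list(statistic = t, df = df, p_value = 2 * stats::pt(-abs(t), df))
}

mw_core <- function(controls, cases) {
  n1 <- length(controls); n2 <- length(cases); n <- n1 + n2
  r <- rank(c(controls, cases))
  u <- sum(r[(n1 + 1):n]) - n2 * (n2 + 1) / 2  # case-over-control wins
  ties <- table(r)
  sigma <- sqrt((n1 * n2 / 12) *
                  ((n + 1) - sum(ties^3 - ties) / (n * (n - 1))))
  z0 <- u - n1 * n2 / 2
  z <- if (sigma == 0) NA_real_ else (z0 - sign(z0) * 0.5) / sigma
  list(statistic = u, z = z,
       p_value = if (is.na(z)) NA_real_ else min(1, 2 * stats::pnorm(-abs(z))))
}

ks_core <- function(controls, cases) {
  n1 <- length(controls); n2 <- length(cases)
  w <- c(controls, cases)
  ord <- order(w)
  steps <- cumsum(ifelse(ord <= n1, 1 / n1, -1 / n2))
  ties <- duplicated(w[ord], fromLast = TRUE)  # evaluate at last tied index
  d <- max(abs(steps[!ties]))
  list(statistic = d, p_value = ks_pvalue_asymptotic(d, n1, n2))
}

# asymptotic two-sided Kolmogorov distribution tail; the two standard
# series branches with the conventional tol-driven truncation (tol 1e-6),
# so values agree with common reference implementations to well below the
# truncation error
ks_pvalue_asymptotic <- function(d, n1, n2, tol = 1e-6) {
  lambda <- sqrt(n1 * n2 / (n1 + n2)) * d
  if (lambda == 0) return(1)
  if (lambda < 1) {
    k_max <- floor(sqrt(2 - log(tol)))
    k <- seq(1, k_max, by = 2)
    k <- k[k < k_max]
    cdf <- sqrt(2 * pi) / lambda *
      sum(exp(-k^2 * pi^2 / (8 * lambda^2)))
    max(0, min(1, 1 - cdf))
  } else {
    z <- -2 * lambda^2
    s <- 1; k <- 1; old <- 0; new <- 1
    while (abs(old - new) > tol) {
      old <- new
      new <- new - 2 * s * exp(z * k^2)
      s <- -s
      k <- k + 1
    }
    max(0, min(1, 1 - new))
  }
}

#' Classical two-sample statistics
#'
#' The conventional group-versus-group tests used as benchmarks: Student
#' (equal-variance) and Welch (unequal-variance) t-tests, the Mann-Whitney
#' U with normal approximation and continuity correction (U counts
#' case-over-control wins), and the two-sample Kolmogorov-Smirnov D with
#' asymptotic p-value. All are two-sided; positive t means case
#' over-expression.
#'
#' @inheritParams copa_stat
#' @param which One of `"ttest_ev"`, `"ttest_uv"`, `"mw"`, `"ks"`.
#' @return A one-row tibble with `method`, `statistic` and `p_value`
#'   (statistic is t, U or D; `NA` statistic flags a degenerate variance).
#' @export
classical_stat <- function(controls, cases,
                           which = c("ttest_ev", "ttest_uv", "mw", "ks")) {
  which <- match.arg(which)
  n1 <- length(controls); n2 <- length(cases)
  res <- switch(which,
    ttest_ev = ,
    ttest_uv = {
      if (n1 < 2 || n2 < 2) abort("t-tests need >= 2 samples per group")
      t_core(mean(controls), mean(cases),
             stats::var(controls), stats::var(cases),
             n1, n2, equal_var = which == "ttest_ev")
    },
    mw = mw_core(controls, cases),
    ks = ks_core(controls, cases)
  )
  tibble(method = which, statistic = unname(res$statistic),
         p_value = unname(res$p_value))
}

# ---- vectorised matrix engines (used by the simulation harness) -----------

copa_scores <- function(ctrl, case, r = 0.90) {
  all <- cbind(ctrl, case)
  med <- row_median(all)
  scale <- 1.4826 * row_median(abs(all - med))
  s <- (row_quantile(case, r) - med) / scale
  s[scale == 0] <- NA_real_
  s
}

os_scores <- function(ctrl, case) {
  all <- cbind(ctrl, case)
  med <- row_median(all)
  scale <- 1.4826 * row_median(abs(all - med))
  q <- apply(all, 1L, stats::quantile, probs = c(0.25, 0.75), names = FALSE)
  cutoff <- q[2, ] + (q[2, ] - q[1, ])
  keep <- case > cutoff
  s <- rowSums(((case - med) / scale) * keep)
  s[scale == 0] <- NA_real_
  s
}

pooled_robust_scale <- function(ctrl, case) {
  medc <- row_median(ctrl)
  medk <- row_median(case)
  devs <- cbind(abs(ctrl - medc), abs(case - medk))
  list(medc = medc, scale = 1.4826 * row_median(devs))
}

ort_scores <- function(ctrl, case) {
  q <- apply(ctrl, 1L, stats::quantile, probs = c(0.25, 0.75), names = FALSE)
  cutoff <- q[2, ] + (q[2, ] - q[1, ])
  rs <- pooled_robust_scale(ctrl, case)
  keep <- case > cutoff
  s <- rowSums((case - rs$medc) * keep) / rs$scale
  s[rs$scale == 0] <- NA_real_
  s
}

most_scores <- function(ctrl, case, n_rep = 1e5, with_k = FALSE) {
  n2 <- ncol(case)
  cons <- most_constants(n2, n_rep)
  rs <- pooled_robust_scale(ctrl, case)
  out <- vapply(seq_len(nrow(case)), function(i) {
    if (rs$scale[i] == 0) return(c(NA_real_, NA_real_))
    most_core(sort.int(case[i, ], decreasing = TRUE),
              rs$medc[i], rs$scale[i], cons)
  }, numeric(2))
  if (with_k) list(score = out[1, ], k_hat = as.integer(out[2, ]))
  else out[1, ]
}

t_scores <- function(ctrl, case, equal_var) {
  n1 <- ncol(ctrl); n2 <- ncol(case)
  m1 <- rowMeans(ctrl); m2 <- rowMeans(case)
  v1 <- (rowSums(ctrl^2) - n1 * m1^2) / (n1 - 1)
  v2 <- (rowSums(case^2) - n2 * m2^2) / (n2 - 1)
  t_core(m1, m2, pmax(v1, 0), pmax(v2, 0), n1, n2, equal_var)
}

mw_scores <- function(ctrl, case) {
  all <- cbind(ctrl, case)
  n1 <- ncol(ctrl); n2 <- ncol(case); n <- n1 + n2
  out <- vapply(seq_len(nrow(all)), function(i) {
    res <- mw_core(all[i, seq_len(n1)], all[i, (n1 + 1):n])
    c(res$statistic, if (is.na(res$z)) NA_real_ else abs(res$z), res$p_value)
  }, numeric(3))
  list(statistic = out[1, ], score = out[2, ], p_value = out[3, ])
}

ks_scores <- function(ctrl, case) {
  n1 <- ncol(ctrl)
  all <- cbind(ctrl, case)
  out <- vapply(seq_len(nrow(all)), function(i) {
    res <- ks_core(all[i, seq_len(n1)], all[i, -seq_len(n1)])
    c(res$statistic, res$p_value)
  }, numeric(2))
  list(statistic = out[1, ], score = out[1, ], p_value = out[2, ])
}
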