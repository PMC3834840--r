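# method registry: every benchmarkable method as a score over genes x
# samples matrices. One-sided outlier scores (dids_*, copa, os, ort, most)
# increase with case over-expression; two-sided tests enter through |t|,
# |z| or D so that one empirical upper-tail threshold fits all methods.

dids_methods <- function() {
  c("dids_tanh", "dids_quad", "dids_sqrt",
    "copa", "os", "ort", "most", "ttest_ev", "ttest_uv", "mw", "ks")
}

normalise_method <- function(method) {
  m <- gsub("-", "_", tolower(method))
  m[m == "ttest.ev"] <- "ttest_ev"
  m[m == "ttest.uv"] <- "ttest_uv"
  bad <- setdiff(m, dids_methods())
  if (length(bad)) {
    abort(paste0("unknown method(s): ", paste(bad, collapse = ", "),
                 "; available: ", paste(dids_methods(), collapse = ", ")))
  }
  m
}

method_score_matrix <- function(method, ctrl, case, copa_r = 0.90) {
  switch(method,
    dids_tanh = dids_engine(ctrl, case, scoring_function("tanh"), "up")$score,
    dids_quad = dids_engine(ctrl, case, scoring_function("quad"), "up")$score,
    dids_sqrt = dids_engine(ctrl, case, scoring_function("sqrt"), "up")$score,
    copa = copa_scores(ctrl, case, copa_r),
    os = os_scores(ctrl, case),
    ort = ort_scores(ctrl, case),
    most = most_scores(ctrl, case),
    ttest_ev = abs(t_scores(ctrl, case, TRUE)$statistic),
    ttest_uv = abs(t_scores(ctrl, case, FALSE)$statistic),
    mw = mw_scores(ctrl, case)$score,
    ks = ks_scores(ctrl, case)$score
  )
}

#' Per-gene comparator score table
#'
#' Scores every gene of an expression table with one registered method and
#' ranks genes by score (descending; degenerate-scale sentinels last). For
#' the score-only outlier statistics (COPA, OS, ORT, MOST and the raw DIDS
#' scores) the `p_value` column is `NA`; the classical tests report their
#' two-sided p-value.
#'
#' @inheritParams dids
#' @param method One of `dids_tanh`, `dids_quad`, `dids_sqrt`, `copa`,
#'   `os`, `ort`, `most`, `ttest_ev`, `ttest_uv`, `mw`, `ks` (hyphenated
#'   spellings accepted).
#' @param copa_r COPA percentile (default 0.90).
#' @return A tibble `gene_id`, `method`, `statistic`, `score`, `p_value`,
#'   `rank` (plus `k_hat` for MOST), ordered by rank.
#' @export
comparator_scores <- function(data, labels = NULL, method = "copa",
                              copa_r = 0.90, gene_col = 1) {
  method <- normalise_method(method)[1]
  if (inherits(data, "dids_sim")) {
    labels <- labels %||% data$labels
    data <- data$expression
  }
  em <- as_expression_input(data, gene_col)
  groups <- as_group_labels(labels, em$sample_ids)
  gm <- split_groups(em$values, groups)

  res <- tibble(gene_id = em$gene_ids, method = method)
  if (method == "most") {
    out <- most_scores(gm$ctrl, gm$case, with_k = TRUE)
    res$statistic <- out$score
    res$score <- out$score
    res$p_value <- NA_real_
    res$k_hat <- out$k_hat
  } else if (method %in% c("ttest_ev", "ttest_uv")) {
    out <- t_scores(gm$ctrl, gm$case, method == "ttest_ev")
    res$statistic <- out$statistic
    res$score <- abs(out$statistic)
    res$p_value <- out$p_value
  } else if (method == "mw") {
    out <- mw_scores(gm$ctrl, gm$case)
    res$statistic <- out$statistic
    res$score <- out$score
    res$p_value <- out$p_value
  } else if (method == "ks") {
    out <- ks_scores(gm$ctrl, gm$case)
    res$statistic <- out$statistic
    res$score <- out$score
    res$p_value <- out$p_value
  } else {
    s <- method_score_matrix(method, gm$ctrl, gm$case, copa_r)
    res$statistic <- s
    res$score <- s
    res$p_value <- NA_real_
  }
  res <- arrange(res, is.na(.data$score), desc(.data$score), .data$gene_id)
  res$rank <- seq_len(nrow(res))
  res
}

#' Empirical null score threshold for a method
#'
#' Simulates `n_null` genes with no group difference (all values
#' `N(0, 1)`), scores them with the method, and returns the `(1 - alpha)`
#' empirical quantile (inverse-ECDF). Detection at this threshold uses
#' `score >= threshold`, so `alpha = 1` calls everything.
#'
#' @param method Registered method name (see [comparator_scores()]).
#' @param n1,n2 Group sizes.
#' @param alpha Target false-positive rate; must satisfy
#'   `alpha * n_null >= 1`.
#' @param n_null Number of null genes (default 1e5; at least `100 / alpha`
#'   is recommended for a stable tail quantile).
#' @param seed Optional seed.
#' @param copa_r COPA percentile.
#' @return A single numeric threshold.
#' @export
empirical_null_threshold <- function(method, n1, n2, alpha, n_null = 1e5,
                                     seed = NULL, copa_r = 0.90) {
  method <- normalise_method(method)[1]
  assert_scalar_prob(alpha, "alpha")
  n_null <- assert_count(n_null, "n_null")
  if (alpha * n_null < 1) {
    abort(sprintf(paste0(
      "alpha = %g is not resolvable with n_null = %d null genes; ",
      "increase n_null to at least %d (>= 100/alpha recommended)"),
      alpha, n_null, ceiling(1 / alpha)))
  }
  null_mat <- with_seed_(seed, simulate_null_matrix(n_null, n1 + n2))
  scores <- method_score_matrix(method, null_mat[, seq_len(n1), drop = FALSE],
                                null_mat[, -seq_len(n1), drop = FALSE],
                                copa_r)
  null_quantile(scores, alpha)
}

null_quantile <- function(scores, alpha) {
  stats::quantile(scores, 1 - alpha, type = 1, names = FALSE, na.rm = TRUE)
}

#' Power surface over effect size and aberrant fraction
#'
#' Reproduces the reporter-gene power protocol: for each method a single set
#' of `n_null` null genes fixes the empirical score thresholds at every
#' `alpha`; for each `(delta, p_a)` cell, `n_reporters` reporter genes are
#' simulated (reporters only) and the power is the fraction whose score
#' reaches the threshold. All methods are scored on the same simulated
#' genes.
#'
#' @param methods Character vector of registered method names.
#' @param delta Numeric grid of mean shifts.
#' @param p_a Numeric grid of aberrant-case fractions.
#' @param alpha Numeric grid of false-positive rates.
#' @param n1,n2 Group sizes.
#' @param n_reporters Reporter genes per cell (default 500).
#' @param n_null Null genes for the thresholds (default 1e5).
#' @param seed Optional master seed.
#' @param copa_r COPA percentile.
#' @return A `dids_surface` tibble: `method`, `delta`, `p_a`, `alpha`,
#'   `power`, `n_reporters`, `n_null`.
#' @export
power_surface <- function(methods = "dids_tanh", delta = 1:4,
                          p_a = seq(0.01, 0.39, by = 0.02),
                          alpha = c(1e-4, 3e-4, 1e-3, 3e-3, 0.01, 0.03, 0.1),
                          n1 = 50, n2 = 50, n_reporters = 500, n_null = 1e5,
                          seed = NULL, copa_r = 0.90) {
  methods <- normalise_method(methods)
  for (a in alpha) assert_scalar_prob(a, "alpha")
  if (any(alpha * n_null < 1)) {
    abort("smallest alpha not resolvable with n_null; increase n_null")
  }
  null_mat <- with_seed_(derive_seed(seed, 1L),
                         simulate_null_matrix(n_null, n1 + n2))
  ctrl <- null_mat[, seq_len(n1), drop = FALSE]
  case <- null_mat[, -seq_len(n1), drop = FALSE]
  # alpha = 1 imposes no constraint (everything is called); below that the
  # threshold is the inverse-ECDF upper-tail quantile of the null scores
  thresholds <- lapply(setNames(methods, methods), function(m) {
    s <- method_score_matrix(m, ctrl, case, copa_r)
    vapply(alpha, function(a) {
      if (a >= 1) -Inf else null_quantile(s, a)
    }, numeric(1))
  })
  rm(null_mat, ctrl, case)

  grid <- tidyr::expand_grid(delta = delta, p_a = p_a)
  out <- purrr::pmap(grid, function(delta, p_a) {
    n_ab <- round_half_up(p_a * n2)
    cell_seed <- derive_seed(seed, 100L + round(1e4 * delta + 100 * p_a))
    rep_mat <- with_seed_(cell_seed,
      simulate_reporter_matrix(n_reporters, n1, n2, delta, n_ab))
    rctrl <- rep_mat[, seq_len(n1), drop = FALSE]
    rcase <- rep_mat[, -seq_len(n1), drop = FALSE]
    bind_rows(lapply(methods, function(m) {
      s <- method_score_matrix(m, rctrl, rcase, copa_r)
      tibble(method = m, delta = delta, p_a = p_a, alpha = alpha,
             power = vapply(seq_along(alpha), function(i) {
               mean(!is.na(s) & s >= thresholds[[m]][i])
             }, numeric(1)))
    }))
  })
  out <- bind_rows(out)
  out$n_reporters <- n_reporters
  out$n_null <- n_null
  new_surface(out, type = "power")
}

new_surface <- function(x, type) {
  structure(x, class = c("dids_surface", class(x)), surface_type = type)
}

#' Pairwise method differences on a power or PPV surface
#'
#' For every ordered pair of methods on the surface, the difference
#' `value(method_a) - value(method_b)` at each grid point (the pairwise
#' difference tables behind the benchmark heat maps).
#'
#' @param surface A [power_surface()] or [ppv_surface()] result.
#' @return A tibble with `method_a`, `method_b`, the grid columns and
#'   `diff`.
#' @export
surface_differences <- function(surface) {
  stopifnot(inherits(surface, "dids_surface"))
  type <- attr(surface, "surface_type")
  value_col <- if (type == "power") "power" else "ppv"
  grid_cols <- intersect(c("delta", "p_a", "alpha", "top_n"),
                         names(surface))
  methods <- unique(surface$method)
  pairs <- tidyr::expand_grid(method_a = methods, method_b = methods)
  pairs <- pairs[pairs$method_a != pairs$method_b, ]
  purrr::pmap(pairs, function(method_a, method_b) {
    a <- surface[surface$method == method_a,
                 c(grid_cols, value_col)]
    b <- surface[surface$method == method_b,
                 c(grid_cols, value_col)]
    m <- left_join(a, b, by = grid_cols, suffix = c("_a", "_b"))
    tibble(method_a = method_a, method_b = method_b,
           m[grid_cols],
           diff = m[[paste0(value_col, "_a")]] -
             m[[paste0(value_col, "_b")]])
  }) |> bind_rows()
}

# ordering of all genes for top-N selection; DIDS methods follow the core
# protocol (alpha filter first, then score), everything else is pure score
method_gene_order <- function(method, ctrl, case, alpha, copa_r) {
  if (startsWith(method, "dids_")) {
    f <- scoring_function(sub("dids_", "", method))
    eng <- dids_engine(ctrl, case, f, "up")
    p <- pvalue_table(ncol(ctrl), ncol(case))[eng$k + 1L]
    order(p > alpha, -eng$score, p)
  } else {
    s <- method_score_matrix(method, ctrl, case, copa_r)
    order(is.na(s), -s)
  }
}

#' PPV surface over effect size and aberrant fraction
#'
#' For each replicate a full spike-in dataset (reporters plus non-reporter
#' background) is simulated; each method ranks all genes and the positive
#' predictive value is the fraction of reporters among its top `N`
#' candidates, averaged over replicates. DIDS variants rank filter-passing
#' genes first (by score), as in [dids()]; the false discovery rate is
#' reported as `fdr = 1 - ppv`.
#'
#' @inheritParams power_surface
#' @param top_n Integer grid of candidate-list sizes.
#' @param n_genes,reporter_fraction Dataset composition per replicate.
#' @param replicates Number of replicate datasets per cell.
#' @param alpha DIDS filter level used in ranking (default 0.05).
#' @return A `dids_surface` tibble: `method`, `delta`, `p_a`, `top_n`,
#'   `ppv`, `fdr`, `replicates`.
#' @export
ppv_surface <- function(methods = "dids_tanh", delta = 1:4,
                        p_a = seq(0.01, 0.39, by = 0.02),
                        top_n = c(10, 20, 50, 100, 250),
                        n1 = 50, n2 = 50, n_genes = 25000,
                        reporter_fraction = 0.01, replicates = 10,
                        alpha = 0.05, seed = NULL, copa_r = 0.90) {
  methods <- normalise_method(methods)
  if (any(top_n > n_genes)) abort("`top_n` cannot exceed `n_genes`")
  grid <- tidyr::expand_grid(delta = delta, p_a = p_a)
  out <- purrr::pmap(grid, function(delta, p_a) {
    acc <- array(0, dim = c(length(methods), length(top_n)))
    if (round_half_up(p_a * n2) == 0) {
      warn(sprintf(
        "p_a = %g with n2 = %d gives 0 aberrant cases; PPV will be at chance",
        p_a, n2))
    }
    for (r in seq_len(replicates)) {
      cfg <- sim_config(n1 = n1, n2 = n2, n_genes = n_genes,
                        reporter_fraction = reporter_fraction,
                        p_a = p_a, delta = delta,
                        seed = derive_seed(seed,
                          1000L * r + round(1e4 * delta + 100 * p_a)))
      sim <- suppressWarnings(simulate_dataset(cfg))  # warned once above
      em <- as_expression_input(sim$expression)
      gm <- split_groups(em$values, as_group_labels(sim$labels,
                                                    em$sample_ids))
      is_rep <- em$gene_ids %in% sim$reporters
      for (mi in seq_along(methods)) {
        ord <- method_gene_order(methods[mi], gm$ctrl, gm$case, alpha,
                                 copa_r)
        hits <- cumsum(is_rep[ord])
        acc[mi, ] <- acc[mi, ] + hits[top_n] / top_n
      }
    }
    tidyr::expand_grid(method = methods, top_n = top_n) |>
      mutate(delta = delta, p_a = p_a,
             ppv = as.vector(t(acc / replicates))) |>
      select("method", "delta", "p_a", "top_n", "ppv")
  })
  out <- bind_rows(out)
  out$fdr <- 1 - out$ppv
  out$replicates <- replicates
  new_surface(out, type = "ppv")
}

#' Heat-map plot of a power or PPV surface
#'
#' @param object A [power_surface()] or [ppv_surface()] result.
#' @param ... Unused.
#' @return A ggplot object: tiles over `p_a` and `alpha` (power) or `p_a`
#'   and `top_n` (PPV), facetted by method and delta.
#' @export
autoplot.dids_surface <- function(object, ...) {
  type <- attr(object, "surface_type")
  yvar <- if (type == "power") "alpha" else "top_n"
  fill <- if (type == "power") "power" else "ppv"
  ggplot2::ggplot(object,
    ggplot2::aes(x = factor(.data$p_a), y = factor(.data[[yvar]]),
                 fill = .data[[fill]])) +
    ggplot2::geom_tile() +
    ggplot2::facet_grid(method ~ delta,
                        labeller = ggplot2::label_both) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "aberrant case fraction p_a", y = yvar)
}
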