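#' Control-group threshold for outlier detection
#'
#' The outlier threshold is the extremum of the control group: the maximum
#' for the up direction, the minimum for the down direction. Case samples
#' strictly beyond this threshold are the outlier samples.
#'
#' @param controls Numeric vector of control-group expression values.
#' @param direction `"up"` or `"down"`.
#' @return A single numeric threshold.
#' @examples
#' control_threshold(c(1, 3, 2), "up")   # 3
#' control_threshold(c(1, 3, 2), "down") # 1
#' @export
control_threshold <- function(controls, direction = c("up", "down")) {
  direction <- match.arg(direction)
  if (length(controls) < 1L) {
    abort("control group is empty; the design is unusable")
  }
  if (!all(is.finite(controls))) {
    abort("control values must be finite")
  }
  if (direction == "up") max(controls) else min(controls)
}

#' Excess expression of outlier case samples
#'
#' For the up direction, returns `b_j - threshold` for every case value
#' strictly above the threshold; for the down direction, `threshold - b_j`
#' for every case value strictly below it. A case value exactly equal to the
#' threshold is not an outlier. Order follows the case-sample order; the
#' length of the result is the outlier count `k`.
#'
#' @param cases Numeric vector of case-group expression values.
#' @param threshold Threshold from [control_threshold()] for the same
#'   direction.
#' @inheritParams control_threshold
#' @return Numeric vector of strictly positive excesses (possibly empty).
#' @examples
#' excess_expression(c(0.5, 3.5, 7), 3, "up") # 0.5 4.0
#' @export
excess_expression <- function(cases, threshold, direction = c("up", "down")) {
  direction <- match.arg(direction)
  if (!all(is.finite(cases))) abort("case values must be finite")
  e <- if (direction == "up") cases - threshold else threshold - cases
  e[e > 0]
}

#' DIDS score from excess expression
#'
#' Sums the scoring-function contributions of all outlier samples:
#' `score = sum_j f(e_j)`. An empty excess vector gives 0.
#'
#' @param excess Non-negative excess-expression values (from
#'   [excess_expression()]).
#' @param scoring Scoring-function name or a [scoring_function()] object.
#' @return A single non-negative score.
#' @examples
#' dids_score(c(1, 4), "quad") # 17
#' @export
dids_score <- function(excess, scoring = "tanh") {
  f <- scoring_function(scoring)
  if (length(excess) == 0L) return(0)
  if (any(!is.finite(excess)) || any(excess < 0)) {
    abort("excess values must be finite and non-negative")
  }
  sum(f(excess))
}

#' Analyse a single gene
#'
#' Composes [control_threshold()], [excess_expression()], [dids_score()] and
#' [dids_pvalue()] for one gene in one direction. The rank is left unassigned;
#' it is assigned cohort-wide by [rank_candidates()].
#'
#' @param controls,cases Numeric expression vectors for the two groups.
#' @inheritParams dids_score
#' @param alpha Nominal significance level in `(0, 1]` used for the
#'   `passed_filter` flag (inclusive: `p_value <= alpha`).
#' @inheritParams control_threshold
#' @param gene_id Optional gene identifier carried into the result.
#' @return A one-row tibble with columns `gene_id`, `direction`, `n1`, `n2`,
#'   `k`, `threshold`, `score`, `p_value`, `passed_filter`, `rank`.
#' @examples
#' dids_gene(c(0, 0.5, 1), c(0.9, 2, 3), scoring = "quad", direction = "up")
#' @export
dids_gene <- function(controls, cases, scoring = "tanh", alpha = 0.05,
                      direction = c("up", "down"), gene_id = NA_character_) {
  direction <- match.arg(direction)
  assert_scalar_prob(alpha, "alpha")
  if (length(cases) < 1L) abort("case group is empty; the design is unusable")
  f <- scoring_function(scoring)
  thr <- control_threshold(controls, direction)
  e <- excess_expression(cases, thr, direction)
  k <- length(e)
  p <- dids_pvalue(k, length(controls), length(cases))
  tibble(
    gene_id = as.character(gene_id),
    direction = direction,
    n1 = length(controls),
    n2 = length(cases),
    k = k,
    threshold = thr,
    score = dids_score(e, f),
    p_value = p,
    passed_filter = p <= alpha,
    rank = NA_integer_
  )
}

#' Rank filtered candidate genes
#'
#' Genes that pass the alpha filter are sorted by score (descending) and
#' assigned ranks `1..m`; ties are broken by smaller p-value, then by gene id.
#' Filtered-out genes carry no rank and follow the ranked genes, ordered by
#' score. All rows must share one direction.
#'
#' @param results Tibble of per-gene results (as from [dids_gene()] or one
#'   direction of [dids()]), containing at least `gene_id`, `direction`,
#'   `score`, `p_value`, `passed_filter`.
#' @return The same tibble with the `rank` column filled and rows reordered
#'   (ranked genes first).
#' @export
rank_candidates <- function(results) {
  stopifnot(is.data.frame(results))
  if (nrow(results) == 0L) {
    results$rank <- integer(0)
    return(as_tibble(results))
  }
  if (length(unique(results$direction)) > 1L) {
    abort("`results` mixes directions; rank each direction separately")
  }
  out <- arrange(as_tibble(results),
                 !.data$passed_filter, desc(.data$score),
                 .data$p_value, .data$gene_id)
  m <- sum(out$passed_filter)
  out$rank <- c(seq_len(m), rep(NA_integer_, nrow(out) - m))
  out
}

# vectorised engine: one direction over complete genes x samples matrices.
# Down-regulation is the up analysis of the negated data; the reported
# threshold is mapped back to the original scale (control minimum).
dids_engine <- function(ctrl, case, f, direction) {
  sgn <- if (direction == "up") 1 else -1
  thr <- row_max(sgn * ctrl)
  e <- sgn * case - thr
  k <- rowSums(e > 0)
  score <- rowSums(f(pmax(e, 0)))
  list(k = as.integer(k), threshold = sgn * thr, score = score)
}

#' Detect imbalanced differential signal across a cohort
#'
#' Runs the full DIDS analysis on a genes-by-samples expression table: per
#' gene and per direction, the control extremum threshold, the outlier count
#' `k`, the scoring-function score, the exact permutation p-value, the alpha
#' filter and the cohort-wide score ranking. The method is deterministic.
#'
#' Expression values are assumed already normalised and on a continuous
#' (typically log) scale. A gene may appear in both the up and the down
#' table; the two directions are analysed and ranked independently.
#'
#' @param data Expression data: a data frame whose first column (or
#'   `gene_col`) holds gene ids and whose remaining columns are samples, a
#'   numeric matrix with gene rownames, or a [simulate_dataset()] result.
#' @param labels Sample labels: a two-column data frame (`sample_id`,
#'   `group`), a named vector, or a vector aligned with the sample columns,
#'   with groups `"control"` and `"case"`. May be omitted when `data` is a
#'   [simulate_dataset()] result.
#' @inheritParams dids_gene
#' @param direction `"both"` (default), `"up"` or `"down"`.
#' @param gene_col Gene-id column of `data` (position or name).
#' @param na_action `"error"` (default) rejects genes with non-finite values;
#'   `"drop"` removes the offending samples gene-wise, so `n1`/`n2` can vary
#'   per gene (the exact p-value handles this naturally).
#' @return An object of class `dids_fit`. Use [tidy()] for the per-gene
#'   result tibble, [glance()] for a one-row summary, [autoplot()] for a
#'   score/p-value overview, and [write_dids_results()] to export TSV tables.
#' @examples
#' expr <- tibble::tibble(
#'   gene_id = c("gA", "gB"),
#'   c1 = c(0.1, 0.2), c2 = c(-0.5, 0.0), k1 = c(2.4, 0.1), k2 = c(3.0, -0.2)
#' )
#' labels <- tibble::tibble(
#'   sample_id = c("c1", "c2", "k1", "k2"),
#'   group = c("control", "control", "case", "case")
#' )
#' fit <- dids(expr, labels, scoring = "tanh", alpha = 1)
#' tidy(fit)
#' @export
dids <- function(data, labels = NULL, scoring = "tanh", alpha = 0.05,
                 direction = c("both", "up", "down"), gene_col = 1,
                 na_action = c("error", "drop")) {
  direction <- match.arg(direction)
  na_action <- match.arg(na_action)
  assert_scalar_prob(alpha, "alpha")
  if (inherits(data, "dids_sim")) {
    labels <- labels %||% data$labels
    data <- data$expression
  }
  em <- as_expression_input(data, gene_col)
  groups <- as_group_labels(labels, em$sample_ids)
  f <- scoring_function(scoring)

  bad_gene <- !apply(is.finite(em$values), 1L, all)
  if (any(bad_gene) && na_action == "error") {
    abort(paste0("non-finite values in gene(s): ",
                 paste(head(em$gene_ids[bad_gene], 5), collapse = ", "),
                 "; use na_action = \"drop\" to drop samples gene-wise"))
  }

  gm <- split_groups(em$values, groups)
  n1 <- ncol(gm$ctrl); n2 <- ncol(gm$case)
  dirs <- if (direction == "both") c("up", "down") else direction

  one_direction <- function(d) {
    ok <- !bad_gene
    res <- tibble(gene_id = em$gene_ids[ok], direction = d,
                  n1 = n1, n2 = n2)
    eng <- dids_engine(gm$ctrl[ok, , drop = FALSE],
                       gm$case[ok, , drop = FALSE], f, d)
    res$k <- eng$k
    res$threshold <- eng$threshold
    res$score <- eng$score
    res$p_value <- pvalue_table(n1, n2)[eng$k + 1L]
    if (any(bad_gene)) {
      dropped <- map(which(bad_gene), function(i) {
        ctrl <- gm$ctrl[i, ]; case <- gm$case[i, ]
        dids_gene(ctrl[is.finite(ctrl)], case[is.finite(case)],
                  scoring = f, alpha = alpha, direction = d,
                  gene_id = em$gene_ids[i])[, names(res)[1:8]]
      })
      res <- bind_rows(res, bind_rows(dropped))
    }
    res$p_bonferroni <- pmin(1, res$p_value * nrow(res))
    res$passed_filter <- res$p_value <= alpha
    res$rank <- NA_integer_
    rank_candidates(res)
  }

  results <- bind_rows(map(dirs, one_direction))
  structure(
    list(results = results, scoring = scoring_name(f), alpha = alpha,
         n1 = n1, n2 = n2, n_genes = length(em$gene_ids),
         directions = dirs, na_action = na_action),
    class = "dids_fit"
  )
}
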