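#' @export
print.dids_fit <- function(x, ...) {
  cat("DIDS analysis\n")
  cat(sprintf("  %d genes, %d controls vs %d cases\n",
              x$n_genes, x$n1, x$n2))
  cat(sprintf("  scoring = %s, alpha = %g, directions = %s\n",
              x$scoring, x$alpha, paste(x$directions, collapse = "/")))
  for (d in x$directions) {
    res <- x$results[x$results$direction == d, ]
    cat(sprintf("  %s: %d gene(s) pass the filter\n",
                d, sum(res$passed_filter)))
  }
  top <- x$results[!is.na(x$results$rank) & x$results$rank <= 5, ]
  if (nrow(top)) {
    cat("  top candidates:\n")
    print(as.data.frame(top[order(top$direction, top$rank),
                            c("gene_id", "direction", "k", "score",
                              "p_value", "rank")]),
          row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' Tidy a DIDS fit into its per-gene result table
#'
#' @param x A [dids()] result.
#' @param direction Optionally restrict to `"up"` or `"down"`.
#' @param ... Unused.
#' @return A tibble with one row per gene and direction: `gene_id`,
#'   `direction`, `n1`, `n2`, `k`, `threshold`, `score`, `p_value`,
#'   `p_bonferroni` (informational, never used for ranking),
#'   `passed_filter`, `rank`.
#' @export
tidy.dids_fit <- function(x, direction = NULL, ...) {
  res <- x$results
  if (!is.null(direction)) {
    direction <- match.arg(direction, c("up", "down"))
    res <- res[res$direction == direction, ]
  }
  as_tibble(res)
}

#' One-row summary of a DIDS fit
#'
#' @param x A [dids()] result.
#' @param ... Unused.
#' @return A one-row tibble: gene and sample counts, scoring function,
#'   alpha, and the number of filter-passing genes per direction.
#' @export
glance.dids_fit <- function(x, ...) {
  tibble(
    n_genes = x$n_genes, n1 = x$n1, n2 = x$n2,
    scoring = x$scoring, alpha = x$alpha,
    n_pass_up = sum(x$results$passed_filter &
                      x$results$direction == "up"),
    n_pass_down = sum(x$results$passed_filter &
                        x$results$direction == "down")
  )
}

#' Score / p-value overview plot of a DIDS fit
#'
#' Plots each gene's DIDS score against its outlier count `k` (which fully
#' determines the exact p-value), coloured by filter status and facetted by
#' direction. Genes stacking at high `k` with high scores are the imbalanced
#' candidates.
#'
#' @param object A [dids()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dids_fit <- function(object, ...) {
  res <- tidy(object)
  ggplot2::ggplot(res, ggplot2::aes(x = .data$k, y = .data$score,
                                    colour = .data$passed_filter)) +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.6, size = 1) +
    ggplot2::facet_wrap(~direction) +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "#D55E00", `FALSE` = "grey60"),
      name = sprintf("p <= %g", object$alpha)) +
    ggplot2::labs(x = "outlier case samples (k)", y = "DIDS score")
}

#' Expression dot plot for a single gene
#'
#' Shows the control and case values of one gene with the control-group
#' extremum drawn as the outlier threshold, the pattern the DIDS statistic
#' is built on.
#'
#' @inheritParams dids
#' @param gene_id Gene to plot.
#' @param direction Threshold to draw: `"up"` (control maximum) or `"down"`
#'   (control minimum).
#' @return A ggplot object.
#' @export
plot_gene <- function(data, labels = NULL, gene_id,
                      direction = c("up", "down"), gene_col = 1) {
  direction <- match.arg(direction)
  if (inherits(data, "dids_sim")) {
    labels <- labels %||% data$labels
    data <- data$expression
  }
  em <- as_expression_input(data, gene_col)
  groups <- as_group_labels(labels, em$sample_ids)
  i <- match(gene_id, em$gene_ids)
  if (is.na(i)) abort(paste0("gene '", gene_id, "' not found"))
  df <- tibble(group = groups, value = em$values[i, ])
  thr <- control_threshold(df$value[df$group == "control"], direction)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$value,
                                   colour = .data$group)) +
    ggplot2::geom_jitter(width = 0.12, height = 0, size = 2, alpha = 0.8) +
    ggplot2::geom_hline(yintercept = thr, linetype = "dashed") +
    ggplot2::guides(colour = "none") +
    ggplot2::labs(title = gene_id, y = "expression", x = NULL)
}
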