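#' Read an expression matrix from TSV/CSV
#'
#' Expects gene ids in the first column (header row of sample ids). The
#' delimiter is sniffed from the header line (tab beats comma) unless
#' forced. Duplicate gene ids, ragged rows and non-numeric cells are
#' rejected with informative errors.
#'
#' @param path Text file path.
#' @param delim `NULL` (sniff), `"\t"` or `","`.
#' @return A tibble: `gene_id` plus one numeric column per sample.
#' @export
read_expression_matrix <- function(path, delim = NULL) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  if (is.null(delim)) {
    header <- readLines(path, n = 1L)
    delim <- if (lengths(regmatches(header, gregexpr("\t", header))) >=
                 lengths(regmatches(header, gregexpr(",", header)))) {
      "\t"
    } else {
      ","
    }
  }
  # readr's parsing warning is promoted to an error below
  df <- suppressWarnings(
    readr::read_delim(path, delim = delim, show_col_types = FALSE,
                      progress = FALSE))
  probs <- readr::problems(df)
  if (nrow(probs)) {
    abort(paste0("malformed rows in ", path, " (line ",
                 paste(unique(probs$row), collapse = ", "), ")"))
  }
  names(df)[1] <- "gene_id"
  df$gene_id <- as.character(df$gene_id)
  bad <- names(df)[-1][!vapply(df[-1], is.numeric, logical(1))]
  if (length(bad)) {
    abort(paste0("non-numeric cells in column(s): ",
                 paste(bad, collapse = ", ")))
  }
  dup <- unique(df$gene_id[duplicated(df$gene_id)])
  if (length(dup)) {
    abort(paste0("duplicated gene id(s): ", paste(dup, collapse = ", ")))
  }
  df
}

#' Write an expression matrix to TSV
#'
#' Full-precision round-trip companion of [read_expression_matrix()].
#'
#' @param data Tibble as returned by [read_expression_matrix()] (or any
#'   gene-id + samples data frame).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(data, path) {
  readr::write_tsv(data, path)
  invisible(path)
}

#' Read a sample-label table
#'
#' Two-column text file (`sample_id`, `group`); group tokens are mapped to
#' control/case via `control_label` / `case_label`.
#'
#' @param path Text file path.
#' @param control_label,case_label Group tokens in the file (defaults
#'   `"control"` / `"case"`).
#' @param delim `NULL` (sniff), `"\t"` or `","`.
#' @return A tibble `sample_id`, `group` with groups `control` / `case`.
#' @export
read_group_labels <- function(path, control_label = "control",
                              case_label = "case", delim = NULL) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  if (is.null(delim)) {
    header <- readLines(path, n = 1L)
    delim <- if (grepl("\t", header)) "\t" else ","
  }
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE)
  if (ncol(df) < 2L) abort("label file must have two columns")
  out <- tibble(sample_id = as.character(df[[1]]),
                group = as.character(df[[2]]))
  bad <- setdiff(unique(out$group), c(control_label, case_label))
  if (length(bad)) {
    abort(paste0("unrecognised group token(s): ",
                 paste(bad, collapse = ", ")))
  }
  out$group <- ifelse(out$group == control_label, "control", "case")
  out
}

#' Write ranked DIDS result tables
#'
#' Writes one TSV per direction (`dids_up.tsv`, `dids_down.tsv`) with the
#' columns `gene_id`, `direction`, `n1`, `n2`, `k`, `threshold`, `score`,
#' `p_value`, `p_bonferroni`, `passed_filter`, `rank`, rows ordered by rank
#' then unranked genes by score. Human tables carry 6 significant digits; a
#' full-precision machine-readable sidecar (`*_full.tsv`) accompanies each.
#' A `manifest.tsv` records the package version and run parameters; outputs
#' are deterministic, so identical inputs give byte-identical files.
#'
#' @param fit A [dids()] result.
#' @param out_dir Output directory (created if needed).
#' @param input_paths Optional named character vector of input files whose
#'   MD5 checksums are recorded in the manifest.
#' @return Invisibly, the paths written.
#' @export
write_dids_results <- function(fit, out_dir, input_paths = NULL) {
  stopifnot(inherits(fit, "dids_fit"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cols <- c("gene_id", "direction", "n1", "n2", "k", "threshold", "score",
            "p_value", "p_bonferroni", "passed_filter", "rank")
  paths <- character(0)
  for (d in fit$directions) {
    res <- fit$results[fit$results$direction == d, cols]
    full <- file.path(out_dir, paste0("dids_", d, "_full.tsv"))
    readr::write_tsv(res, full)
    human <- res
    num <- vapply(human, is.double, logical(1))
    human[num] <- lapply(human[num], signif, digits = 6)
    main <- file.path(out_dir, paste0("dids_", d, ".tsv"))
    readr::write_tsv(human, main)
    paths <- c(paths, main, full)
  }
  manifest <- c(
    paste0("dids_version\t", as.character(utils::packageVersion("dids"))),
    paste0("scoring\t", fit$scoring),
    paste0("alpha\t", fit$alpha),
    paste0("directions\t", paste(fit$directions, collapse = ",")),
    paste0("n1\t", fit$n1),
    paste0("n2\t", fit$n2),
    paste0("n_genes\t", fit$n_genes),
    paste0("na_action\t", fit$na_action)
  )
  if (!is.null(input_paths)) {
    nm <- names(input_paths)
    if (is.null(nm)) nm <- basename(input_paths)
    sums <- tools::md5sum(unname(unlist(input_paths)))
    manifest <- c(manifest, paste0("md5_", nm, "\t", unname(sums)))
  }
  mpath <- file.path(out_dir, "manifest.tsv")
  writeLines(manifest, mpath)
  invisible(c(paths, mpath))
}
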