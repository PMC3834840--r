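# coercion of user inputs (tibbles, matrices, label tables) to the internal
# representation: a numeric genes x samples matrix plus a control/case factor

as_expression_input <- function(data, gene_col = 1) {
  if (is.matrix(data)) {
    if (!is.numeric(data)) abort("expression matrix must be numeric")
    gene_ids <- rownames(data) %||% sprintf("g%05d", seq_len(nrow(data)))
    sample_ids <- colnames(data) %||% sprintf("s%03d", seq_len(ncol(data)))
    values <- unname(data)
  } else if (is.data.frame(data)) {
    if (ncol(data) < 2L) {
      abort("expression data must have a gene-id column and >= 1 sample column")
    }
    gene_ids <- as.character(data[[gene_col]])
    value_df <- data[setdiff(seq_along(data), if (is.numeric(gene_col))
      gene_col else match(gene_col, names(data)))]
    not_num <- names(value_df)[!vapply(value_df, is.numeric, logical(1))]
    if (length(not_num)) {
      abort(paste0("non-numeric sample column(s): ",
                   paste(not_num, collapse = ", ")))
    }
    sample_ids <- names(value_df)
    values <- unname(as.matrix(value_df))
  } else {
    abort("`data` must be a data frame or a numeric matrix")
  }
  if (nrow(values) == 0L) abort("expression data contains zero genes")
  dup <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup)) {
    abort(paste0("duplicated gene id(s): ",
                 paste(head(dup, 5), collapse = ", ")))
  }
  dimnames(values) <- list(gene_ids, sample_ids)
  list(gene_ids = gene_ids, sample_ids = sample_ids, values = values)
}

# labels: two-column data frame (sample_id, group), a named vector, or a
# plain vector aligned with the matrix columns; returns a factor with levels
# control, case aligned to `sample_ids`
as_group_labels <- function(labels, sample_ids,
                            control_label = "control",
                            case_label = "case") {
  if (is.null(labels)) abort("group labels are required")
  if (is.data.frame(labels)) {
    if (ncol(labels) < 2L) abort("label table must have two columns")
    ids <- as.character(labels[[1]])
    grp <- as.character(labels[[2]])
    if (anyDuplicated(ids)) {
      abort(paste0("sample(s) labelled more than once: ",
                   paste(unique(ids[duplicated(ids)]), collapse = ", ")))
    }
    unknown <- setdiff(ids, sample_ids)
    if (length(unknown)) {
      abort(paste0("label(s) for sample(s) absent from the matrix: ",
                   paste(head(unknown, 5), collapse = ", ")))
    }
    missing <- setdiff(sample_ids, ids)
    if (length(missing)) {
      abort(paste0("no label for sample(s): ",
                   paste(head(missing, 5), collapse = ", ")))
    }
    grp <- grp[match(sample_ids, ids)]
  } else if (!is.null(names(labels))) {
    grp <- as.character(labels[match(sample_ids, names(labels))])
    if (anyNA(grp)) abort("named labels must cover every sample")
  } else {
    if (length(labels) != length(sample_ids)) {
      abort("unnamed labels must have one entry per sample column")
    }
    grp <- as.character(labels)
  }
  bad <- setdiff(unique(grp), c(control_label, case_label))
  if (length(bad)) {
    abort(paste0("unrecognised group token(s): ",
                 paste(bad, collapse = ", "),
                 " (expected '", control_label, "' or '", case_label, "')"))
  }
  out <- factor(ifelse(grp == control_label, "control", "case"),
                levels = c("control", "case"))
  if (!all(c("control", "case") %in% out)) {
    abort("both groups must be non-empty")
  }
  out
}

split_groups <- function(values, groups) {
  list(ctrl = values[, groups == "control", drop = FALSE],
       case = values[, groups == "case", drop = FALSE])
}
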