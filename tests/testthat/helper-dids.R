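# shared fixtures and independent oracles; everything generated in code

# Brute-force oracle for the exact permutation p-value, written against the
# definition (never the closed form): place n1+n2 distinct values, try every
# assignment of case labels, count how often >= k case values exceed the
# maximum control value.
oracle_pvalue <- function(k, n1, n2) {
  n <- n1 + n2
  values <- seq_len(n)  # any distinct values give the same answer
  case_sets <- utils::combn(n, n2)
  hits <- apply(case_sets, 2L, function(cs) {
    ctrl_max <- max(values[-cs])
    sum(values[cs] > ctrl_max) >= k
  })
  mean(hits)
}

# a random two-group gene on a log-like scale
random_gene <- function(n1 = 8, n2 = 10, shift = 0) {
  list(controls = rnorm(n1, mean = 5),
       cases = rnorm(n2, mean = 5 + shift))
}

# tiny labelled expression tibble for end-to-end tests
toy_dataset <- function(n_genes = 6, n1 = 4, n2 = 5, seed = 42) {
  withr::with_seed(seed, {
    values <- matrix(rnorm(n_genes * (n1 + n2)), nrow = n_genes)
    values[1, (n1 + 1):(n1 + 2)] <- values[1, (n1 + 1):(n1 + 2)] + 5
    expr <- tibble::tibble(gene_id = sprintf("gene%02d", seq_len(n_genes)))
    samples <- c(sprintf("c%02d", seq_len(n1)), sprintf("t%02d", seq_len(n2)))
    for (j in seq_along(samples)) expr[[samples[j]]] <- values[, j]
    labels <- tibble::tibble(
      sample_id = samples,
      group = rep(c("control", "case"), c(n1, n2)))
    list(expr = expr, labels = labels)
  })
}
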