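#' Configuration for the synthetic spike-in dataset
#'
#' Describes an artificial expression dataset mimicking a cohort where only a
#' subgroup of the cases is aberrant: non-reporter genes are standard normal
#' `N(0, 1)` in every sample; reporter genes are `N(0, 1)` in all controls
#' and in the non-aberrant cases, while a fraction `p_a` of the case samples
#' (rounded half-up to a count) is shifted to `N(delta, 1)`. Because the
#' variance is 1, `delta` is the signal-to-noise ratio of the aberration.
#'
#' @param n1,n2 Control and case group sizes (defaults 50/50, a balanced
#'   cohort of realistic size; see [run_benchmark()] for other scenarios).
#' @param n_genes Total number of genes (default 25000).
#' @param reporter_fraction Fraction of genes that are reporters (default
#'   0.01, i.e. 250 reporters at the default `n_genes`).
#' @param p_a Fraction of case samples aberrant per reporter gene (default
#'   0.1; benchmark grids span 0.01-0.39).
#' @param delta Mean shift of the aberrant values (default 2; benchmark
#'   grids span 1-4).
#' @param seed Optional integer master seed for full reproducibility.
#' @return A `dids_sim_config` list with the validated fields plus the
#'   derived `n_reporters` and `n_aberrant` counts.
#' @export
sim_config <- function(n1 = 50, n2 = 50, n_genes = 25000,
                       reporter_fraction = 0.01, p_a = 0.1, delta = 2,
                       seed = NULL) {
  n1 <- assert_count(n1, "n1"); n2 <- assert_count(n2, "n2")
  n_genes <- assert_count(n_genes, "n_genes")
  if (!is.numeric(reporter_fraction) || reporter_fraction < 0 ||
      reporter_fraction > 1) {
    abort("`reporter_fraction` must lie in [0, 1]")
  }
  assert_scalar_prob(p_a, "p_a", allow_one = FALSE)
  if (!is.numeric(delta) || length(delta) != 1L || delta < 0) {
    abort("`delta` must be a single non-negative shift")
  }
  structure(
    list(n1 = n1, n2 = n2, n_genes = n_genes,
         reporter_fraction = reporter_fraction, p_a = p_a, delta = delta,
         seed = if (is.null(seed)) NULL else assert_count(seed, "seed"),
         n_reporters = as.integer(round_half_up(n_genes * reporter_fraction)),
         n_aberrant = as.integer(round_half_up(p_a * n2))),
    class = "dids_sim_config"
  )
}

#' @export
print.dids_sim_config <- function(x, ...) {
  cat(sprintf(paste0(
    "synthetic dataset config: %d genes (%d reporters), %d controls vs ",
    "%d cases\n  p_a = %g (%d aberrant case(s)/reporter), delta = %g, ",
    "seed = %s\n"),
    x$n_genes, x$n_reporters, x$n1, x$n2, x$p_a, x$n_aberrant, x$delta,
    if (is.null(x$seed)) "<none>" else x$seed))
  invisible(x)
}

# raw engines: plain matrices, no tibble overhead -------------------------

simulate_null_matrix <- function(n_genes, n_samples) {
  matrix(rnorm(n_genes * n_samples), nrow = n_genes)
}

# aberrant values occupy the first n_aberrant case columns; every statistic
# in the package is invariant to sample order within a group
simulate_reporter_matrix <- function(n_genes, n1, n2, delta, n_aberrant) {
  m <- matrix(rnorm(n_genes * (n1 + n2)), nrow = n_genes)
  if (n_aberrant > 0) {
    m[, n1 + seq_len(n_aberrant)] <- m[, n1 + seq_len(n_aberrant)] + delta
  }
  m
}

#' Simulate a spike-in expression dataset
#'
#' Generates the full artificial dataset described by a [sim_config()]:
#' values for the reporter and non-reporter genes, sample labels, and the
#' reporter gene ids as ground truth. Reporter genes are placed at random
#' positions in the gene index. The reporter block and the non-reporter
#' block are generated from independent child seeds of the master seed, so
#' enlarging the non-reporter background (holding the reporter count fixed)
#' does not reshuffle the reporter values.
#'
#' @param config A [sim_config()] object (or arguments passed to it via
#'   `...` when `config` is missing).
#' @param ... Passed to [sim_config()] when `config` is not supplied.
#' @return A `dids_sim` list: `expression` (tibble, `gene_id` + one column
#'   per sample), `labels` (tibble `sample_id`, `group`), `reporters`
#'   (character vector of true-positive gene ids) and `config`.
#' @examples
#' sim <- simulate_dataset(sim_config(n_genes = 100, n1 = 5, n2 = 5,
#'                                    p_a = 0.4, delta = 3, seed = 1))
#' fit <- dids(sim, alpha = 0.05)
#' @export
simulate_dataset <- function(config = NULL, ...) {
  config <- config %||% sim_config(...)
  stopifnot(inherits(config, "dids_sim_config"))
  if (config$n_reporters > 0 && config$n_aberrant == 0) {
    warn(paste0("round(p_a * n2) = 0 aberrant cases per reporter; ",
                "reporters carry no signal and power will be nil"))
  }
  n <- config$n1 + config$n2
  parts <- with_seed_(config$seed, {
    # block seeds first: they must not depend on n_genes, so that growing
    # the background leaves the reporter block untouched
    seeds <- sample.int(2147483647L, 2L)
    reporter_pos <- sort(sample.int(config$n_genes, config$n_reporters))
    list(reporter_pos = reporter_pos, seeds = seeds)
  })
  rep_mat <- with_seed_(
    if (is.null(config$seed)) NULL else parts$seeds[1],
    simulate_reporter_matrix(config$n_reporters, config$n1, config$n2,
                             config$delta, config$n_aberrant))
  null_mat <- with_seed_(
    if (is.null(config$seed)) NULL else parts$seeds[2],
    simulate_null_matrix(config$n_genes - config$n_reporters, n))

  values <- matrix(NA_real_, nrow = config$n_genes, ncol = n)
  values[parts$reporter_pos, ] <- rep_mat
  values[setdiff(seq_len(config$n_genes), parts$reporter_pos), ] <- null_mat
  gene_ids <- sprintf("g%05d", seq_len(config$n_genes))
  sample_ids <- c(sprintf("ctrl_%03d", seq_len(config$n1)),
                  sprintf("case_%03d", seq_len(config$n2)))
  dimnames(values) <- list(gene_ids, sample_ids)

  expression <- as_tibble(as.data.frame(values))
  expression <- tibble(gene_id = gene_ids, !!!expression)
  structure(
    list(expression = expression,
         labels = tibble(sample_id = sample_ids,
                         group = rep(c("control", "case"),
                                     c(config$n1, config$n2))),
         reporters = gene_ids[parts$reporter_pos],
         config = config),
    class = "dids_sim"
  )
}

#' @export
print.dids_sim <- function(x, ...) {
  cat("synthetic expression dataset\n")
  print(x$config)
  invisible(x)
}
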