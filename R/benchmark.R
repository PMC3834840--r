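#' Run the full power / PPV benchmark across scenarios
#'
#' Drives [power_surface()] and [ppv_surface()] over a list of `(n1, n2)`
#' scenarios and writes, per scenario, the long-format surfaces and their
#' pairwise method differences as TSV files plus a plain-text run manifest.
#' With the same seed and arguments, two runs produce byte-identical files.
#'
#' Scenarios with at most one aberrant case per reporter
#' (`round(p_a * n2) <= 1` for some grid `p_a`) trigger a warning: the
#' absolute number of aberrant samples, not the fraction, carries the
#' signal, so power in that regime is intrinsically low.
#'
#' @param out_dir Output directory (created if needed).
#' @param scenarios List of `c(n1, n2)` pairs. Defaults to a balanced
#'   cohort, the two unbalanced cohorts and a small-sample cohort.
#' @param methods Registered method names to benchmark.
#' @param delta,p_a,alpha,top_n Evaluation grids.
#' @param n_reporters,n_null,n_genes,reporter_fraction,replicates
#'   Simulation sizes (see [power_surface()] and [ppv_surface()]).
#' @param seed Master seed; per-scenario seeds are derived from it.
#' @param copa_r COPA percentile.
#' @param run_ppv Set `FALSE` to skip the (more expensive) PPV surfaces.
#' @return Invisibly, a named list of the surfaces, one entry per scenario.
#' @export
run_benchmark <- function(out_dir,
                          scenarios = list(c(50, 50), c(25, 95),
                                           c(95, 25), c(10, 10)),
                          methods = c("dids_tanh", "copa", "os", "ort",
                                      "most", "ttest_ev", "ttest_uv",
                                      "mw", "ks"),
                          delta = 1:4,
                          p_a = seq(0.01, 0.39, by = 0.02),
                          alpha = c(1e-4, 3e-4, 1e-3, 3e-3, 0.01, 0.03, 0.1),
                          top_n = c(10, 20, 50, 100, 250),
                          n_reporters = 500, n_null = 1e5,
                          n_genes = 25000, reporter_fraction = 0.01,
                          replicates = 10, seed = NULL, copa_r = 0.90,
                          run_ppv = TRUE) {
  methods <- normalise_method(methods)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- list()
  for (si in seq_along(scenarios)) {
    sc <- scenarios[[si]]
    n1 <- sc[1]; n2 <- sc[2]
    tag <- sprintf("%d_%d", n1, n2)
    low <- p_a[round_half_up(p_a * n2) <= 1]
    if (length(low)) {
      warn(sprintf(paste0(
        "scenario (%d,%d): p_a in {%s} gives <= 1 aberrant case per ",
        "reporter; expect low power there"),
        n1, n2, paste(signif(low, 3), collapse = ", ")))
    }
    sc_seed <- derive_seed(seed, si)
    pw <- power_surface(methods, delta = delta, p_a = p_a, alpha = alpha,
                        n1 = n1, n2 = n2, n_reporters = n_reporters,
                        n_null = n_null, seed = sc_seed, copa_r = copa_r)
    write_surface_tsv(pw, file.path(out_dir, paste0("power_", tag, ".tsv")))
    write_surface_tsv(surface_differences(pw),
                      file.path(out_dir, paste0("power_diff_", tag, ".tsv")))
    results[[tag]] <- list(power = pw)
    if (run_ppv) {
      pv <- ppv_surface(methods, delta = delta, p_a = p_a, top_n = top_n,
                        n1 = n1, n2 = n2, n_genes = n_genes,
                        reporter_fraction = reporter_fraction,
                        replicates = replicates,
                        seed = derive_seed(sc_seed, 7L), copa_r = copa_r)
      write_surface_tsv(pv, file.path(out_dir, paste0("ppv_", tag, ".tsv")))
      write_surface_tsv(surface_differences(pv),
                        file.path(out_dir, paste0("ppv_diff_", tag, ".tsv")))
      results[[tag]]$ppv <- pv
    }
  }
  manifest <- c(
    paste0("dids_version\t", as.character(utils::packageVersion("dids"))),
    paste0("scenarios\t", paste(vapply(scenarios, paste, "",
                                       collapse = ","), collapse = "; ")),
    paste0("methods\t", paste(methods, collapse = ",")),
    paste0("delta\t", paste(delta, collapse = ",")),
    paste0("p_a\t", paste(p_a, collapse = ",")),
    paste0("alpha\t", paste(alpha, collapse = ",")),
    paste0("top_n\t", paste(top_n, collapse = ",")),
    paste0("n_reporters\t", n_reporters),
    paste0("n_null\t", n_null),
    paste0("n_genes\t", n_genes),
    paste0("reporter_fraction\t", reporter_fraction),
    paste0("replicates\t", replicates),
    paste0("copa_r\t", copa_r),
    paste0("seed\t", if (is.null(seed)) "none" else seed)
  )
  writeLines(manifest, file.path(out_dir, "manifest.tsv"))
  invisible(results)
}

write_surface_tsv <- function(x, path) {
  df <- as.data.frame(x)
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], signif, digits = 6)
  readr::write_tsv(df, path)
}
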