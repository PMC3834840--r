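# internal helpers shared across modules

# round-half-up; base round() is half-to-even, which would make e.g.
# round(0.05 * 50) = 2 instead of the intended 3 aberrant cases
round_half_up <- function(x) floor(x + 0.5)

row_max <- function(m) do.call(pmax, as.data.frame(m))

row_min <- function(m) do.call(pmin, as.data.frame(m))

row_median <- function(m) apply(m, 1L, stats::median)

row_quantile <- function(m, p) {
  apply(m, 1L, stats::quantile, probs = p, names = FALSE, type = 7)
}

# evaluate `code` under a temporary RNG seed without touching the global
# stream; seed = NULL means "use the current stream as-is"
with_seed_ <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

# deterministic child seed, kept inside 32-bit integer range
derive_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) + 10007 * as.double(offset)) %% 2147483629)
}

assert_scalar_prob <- function(x, name, allow_one = TRUE) {
  hi_ok <- if (allow_one) x <= 1 else x < 1
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0 || !hi_ok) {
    abort(sprintf("`%s` must be a single probability in (0, %s]",
                  name, if (allow_one) "1" else "1)"))
  }
  invisible(x)
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != trunc(x)) {
    abort(sprintf("`%s` must be a single integer >= %d", name, min))
  }
  invisible(as.integer(x))
}
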