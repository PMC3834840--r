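#' Scoring functions for excess expression
#'
#' A scoring function maps the non-negative excess expression of each outlier
#' case sample (the amount by which it exceeds the control-group extremum) to
#' its contribution to the DIDS score. All three variants are strictly
#' increasing on `[0, Inf)` and map 0 to 0; their shape tunes the statistic
#' toward different aberration patterns:
#'
#' * `"tanh"` — `f(e) = tanh(e)`: bounded contributions, favouring genes where
#'   many case samples show a modest excess; robust to single extreme values
#'   and the recommended default.
#' * `"quad"` — `f(e) = e^2`: amplifies large excess, favouring genes where a
#'   small subgroup shows very strong aberration.
#' * `"sqrt"` — `f(e) = sqrt(e)`: intermediate, compressing large excess
#'   without bounding it.
#'
#' @param scoring Name of the variant: `"tanh"`, `"quad"` or `"sqrt"`.
#'
#' @return A vectorised function of one non-negative numeric argument, with
#'   class `"dids_scoring"` and a `name` attribute.
#' @examples
#' f <- scoring_function("quad")
#' f(c(1, 4)) # 1 16
#' @export
scoring_function <- function(scoring = c("tanh", "quad", "sqrt")) {
  if (inherits(scoring, "dids_scoring")) return(scoring)
  scoring <- match.arg(scoring)
  fun <- switch(scoring,
    tanh = function(e) tanh(e),
    quad = function(e) e^2,
    sqrt = function(e) sqrt(e)
  )
  structure(fun, name = scoring, class = c("dids_scoring", "function"))
}

#' @export
print.dids_scoring <- function(x, ...) {
  cat("<dids scoring function:", attr(x, "name"), ">\n")
  invisible(x)
}

scoring_name <- function(f) attr(f, "name") %||% "custom"
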