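#' @importFrom rlang abort warn inform .data :=
#' @importFrom tibble tibble as_tibble
#' @importFrom generics tidy glance
NULL

abort_validation <- function(msg, ...) {
  abort(msg, class = c("netpharm_validation_error", "netpharm_error"), ...)
}

abort_arity <- function(msg, ...) {
  abort(msg, class = c("netpharm_arity_error", "netpharm_error"), ...)
}

abort_undefined_ratio <- function(msg, ...) {
  abort(msg, class = c("netpharm_undefined_ratio_error", "netpharm_error"), ...)
}

# normalize Unicode minus (U+2212) so predictor exports paste cleanly
normalize_minus <- function(x) gsub("−", "-", x)

check_finite <- function(x, what) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    abort_validation(sprintf("`%s` must be finite numeric; got non-finite or non-numeric values.", what))
  }
  invisible(x)
}

#' Percentage of a count over a population
#'
#' Full-precision percentage `100 * k / n`, optionally rounded for reporting.
#' Used throughout the screening reports (e.g. the fraction of a chemical
#' library passing the absorption filter).
#'
#' @param k Count (numerator).
#' @param n Population size (denominator, must be > 0).
#' @param digits Decimal places to round to; `NULL` (default) keeps full
#'   precision.
#' @return A numeric percentage on the 0-100 scale.
#' @examples
#' percent(121, 981, digits = 2)
#' @export
percent <- function(k, n, digits = NULL) {
  check_finite(k, "k")
  check_finite(n, "n")
  if (any(n <= 0)) abort_undefined_ratio("`n` must be positive to form a percentage.")
  p <- 100 * k / n
  if (!is.null(digits)) p <- round(p, digits)
  p
}
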