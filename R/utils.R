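#' Round half away from zero
#'
#' Integer rounding with the half-up rule used for all printed percentages
#' (base R's `round()` rounds half to even, which does not match how cohort
#' retention figures are conventionally reported).
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @export
round_half_up <- function(x) {
  trunc(x + sign(x) * 0.5)
}

#' Percentage with half-up rounding
#'
#' @param numerator,denominator counts; `denominator` must be positive.
#' @return integer percentage, `round_half_up(100 * numerator / denominator)`.
#' @export
funnel_percent <- function(numerator, denominator) {
  stopifnot(is.numeric(numerator), is.numeric(denominator), denominator > 0)
  round_half_up(100 * numerator / denominator)
}

#' Stage-tagged logging to stderr
#'
#' Every pipeline stage reports gene/sample counts at entry and exit so the
#' filtering funnel is reconstructible from the log.
#'
#' @param stage short stage tag.
#' @param ... message parts passed to [paste0()].
#' @keywords internal
stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

# shared argument checkers ---------------------------------------------------

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    stop(sprintf("`%s` must be a single finite number in [%s, %s]",
                 name, format(lower), format(upper)), call. = FALSE)
  }
  invisible(x)
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min ||
      x != as.integer(x)) {
    stop(sprintf("`%s` must be an integer >= %d", name, min), call. = FALSE)
  }
  invisible(as.integer(x))
}
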