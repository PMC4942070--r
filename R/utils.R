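#' Round half away from zero
#'
#' Commercial rounding: ties go away from zero (so 0.5 -> 1, 29.75 -> 29.8
#' at one decimal), unlike base [round()]'s round-half-to-even. Used for
#' presenting percentages and probabilities in tables and reports.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return `x` rounded to `digits` decimals.
#' @export
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  # nudge by a few ulps so that values stored just under a .5 tie (e.g.
  # 29.749999999999996 for an intended 29.75) still round up
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}
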