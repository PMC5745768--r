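#' Round half away from zero
#'
#' Fixed-decimal rounding with ties going away from zero (the convention of
#' most clinical tables), unlike base `round()`'s round-half-even.
#' Used only at reporting time; internal computation keeps full precision.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return Rounded numeric vector.
#' @examples
#' round_half_up(c(0.25, -0.25, 2.5), 1)  # 0.3 -0.3 2.5
#' @export
round_half_up <- function(x, digits = 1) {
  s <- 10^digits
  # pre-round far below the reporting precision so binary representation
  # error cannot push an exact .5 tie to the wrong side
  sign(x) * floor(round(abs(x) * s, 9) + 0.5) / s
}
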