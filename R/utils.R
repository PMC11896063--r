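#' Round half away from zero
#'
#' Commercial ("round half up") rounding, as used for display of index
#' values (4 decimals) and stage percentages (2 decimals). Base R's
#' `round()` rounds half to even, which disagrees with the published
#' convention on values such as 0.63555... A tolerance of 1e-8 in the last
#' retained digit absorbs binary floating-point representation error.
#'
#' @param x numeric vector.
#' @param digits number of decimal places to keep.
#' @return `x` rounded with ties going away from zero.
#' @examples
#' round_half_up(0.63555555, 4) # 0.6356
#' round(0.63555555, 4)         # 0.6356 here, but 2.5 vs 2 differ:
#' round_half_up(2.5)           # 3
#' @export
round_half_up <- function(x, digits = 0) {
  scaled <- x * 10^digits
  sign(scaled) * floor(abs(scaled) + 0.5 + 1e-8) / 10^digits
}

# roman numeral label "I", "II", ... for sub-area suffixes
roman_label <- function(i) {
  as.character(as.roman(i))
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}
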