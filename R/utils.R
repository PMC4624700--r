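#' Round to the nearest euro
#'
#' Display rounding used throughout the reported tables: halves are rounded
#' away from zero, so 546.875 becomes 547 and -38.5 becomes -39. Internal
#' computation always keeps full precision; this is applied at render time
#' only.
#'
#' @param x numeric vector of euro amounts.
#' @return integer-valued numeric vector.
#' @export
round_euro <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' Round a complication count for display
#'
#' Expected complications per catheterization are displayed with three
#' decimal places, halves away from zero.
#'
#' @param x numeric vector (complications per catheterization).
#' @param digits number of decimal places (default 3).
#' @return rounded numeric vector.
#' @export
round_compl <- function(x, digits = 3) {
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

# format euros with thousands separator for report rendering
fmt_euro <- function(x) {
  formatC(round_euro(x), format = "d", big.mark = ",")
}

fmt_compl <- function(x, digits = 3) {
  formatC(round_compl(x, digits), format = "f", digits = digits)
}

stop_ctx <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

is_prob <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x <= 1
}
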