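#' Round half away from zero
#'
#' Rounds to the nearest integer with ties at .5 resolved away from zero
#' (so 0.5 -> 1, -0.5 -> -1, 2.5 -> 3).  This is the "round off" rule used
#' when converting corrected connection values back to fiber counts; note it
#' differs from [base::round()], which rounds half to even.
#'
#' @param x Numeric vector.
#' @return Numeric vector of rounded values.
#' @export
#' @examples
#' round_half_away(c(0.5, 1.5, 2.5, -0.5, -2.5))
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' Format a significant-unit percentage
#'
#' Percentages of significant edges/nodes are printed rounded to the nearest
#' integer, or with two decimal places when below 1 percent (e.g. 151 of
#' 37,401 edges prints as "0.40").
#'
#' @param count Number of significant units.
#' @param total Total number of units tested.
#' @return Character scalar.
#' @export
format_percentage <- function(count, total) {
  stopifnot(total > 0, count >= 0, count <= total)
  pct <- 100 * count / total
  if (count == 0) {
    "0"
  } else if (pct < 1) {
    sprintf("%.2f", pct)
  } else {
    sprintf("%d", as.integer(round_half_away(pct)))
  }
}

# full-precision decimal rendering for lossless text serialization
format_full <- function(x) {
  sprintf("%.17g", x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
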