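#' Round half away from zero
#'
#' Rounding used at the presentation layer. Unlike [base::round()], which
#' rounds half to even, exact halves are rounded away from zero so that, e.g.,
#' a frequency of 0.38665 prints as 0.3867 at 4 decimals.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
#' @examples
#' roundHalfUp(116 / 300, 4)  # 0.3867
roundHalfUp <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

## presentation helpers: internal computation stays at full precision,
## rounding happens only when a table is rendered
fmtPercent <- function(f) sprintf("%.2f", roundHalfUp(100 * f, 2))
fmtFreq4 <- function(x) sprintf("%.4f", roundHalfUp(x, 4))

## deterministic numeric serialization for pipeline outputs
fmtNum <- function(x) {
  ifelse(is.na(x), "", sprintf("%.10g", x))
}

checkSymmetric2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L)))
    stop("expected a 2x2 table")
  if (any(!is.finite(tab)) || any(tab < 0))
    stop("table counts must be finite and non-negative")
  storage.mode(tab) <- "double"
  tab
}
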