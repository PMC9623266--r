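#' Round half away from zero
#'
#' Decimal rounding with ties going away from zero (the convention used for
#' the reported barrier tables), unlike [base::round()]'s round-half-even.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return numeric vector rounded to `digits` places.
#' @export
#' @examples
#' roundHalfUp(0.00165, 4)  # 0.0017, where round() gives 0.0016
roundHalfUp <- function(x, digits = 4) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

## shared input checks ------------------------------------------------------

.checkNonNegative <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0)) {
    stop("invalid count: ", what, " must be finite and non-negative",
         call. = FALSE)
  }
  invisible(x)
}

.checkProbability <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop(what, " must lie in [0, 1]", call. = FALSE)
  }
  invisible(x)
}

.speciesLabels <- c("A", "B", "H")

.hybridClasses <- c("P1", "P2", "F1", "F2", "BC1", "BC2")
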