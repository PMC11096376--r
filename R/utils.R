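# Internal helpers shared across modules.

#' Standardize a numeric vector to mean zero, unit variance
#'
#' Scaling uses the population standard deviation (denominator n), so
#' e.g. `zscore(1:3)` is `c(-1.2247, 0, 1.2247)`.
#'
#' @param x numeric vector without missing values.
#' @return numeric vector with mean 0 and population SD 1.
#' @export
zscore <- function(x) {
  if (anyNA(x)) stop("zscore: missing values not allowed")
  mu <- mean(x)
  s <- sqrt(mean((x - mu)^2))
  if (s == 0) stop("zscore: zero-variance input")
  (x - mu) / s
}

#' Round half away from zero
#'
#' `round()` in R rounds half to even; table rendering needs the
#' conventional half-away-from-zero rule (0.035 -> 0.04, -0.025 -> -0.03).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 2) {
  f <- 10^digits
  # pre-round at 9 decimals so values intended as exact halves (0.035
  # stored as 0.03499999...) round away from zero as expected
  sign(x) * floor(round(abs(x) * f, 9) + 0.5) / f
}

# Format a signed value to `digits` decimals, preserving the sign on a
# value that rounds to zero ("-0.00"), as effect tables conventionally do.
format_signed <- function(x, digits = 2) {
  r <- round_half_away(x, digits)
  out <- formatC(abs(r), format = "f", digits = digits)
  neg <- x < 0
  out[neg] <- paste0("-", out[neg])
  out
}

# Stage-aware logging used by the pipeline; quiet unless option set off.
msg <- function(..., verbose = getOption("migsem.verbose", TRUE)) {
  if (isTRUE(verbose)) message(...)
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
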