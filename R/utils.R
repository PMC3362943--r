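#' Round half-up at a fixed number of decimals
#'
#' Commercial ("half-up") rounding, as used for all printed percentages and
#' densities in the package's summary tables.  `round()` in R rounds half to
#' even, which disagrees on exact .5 boundaries.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_cm <- function(...) stop(sprintf(...), call. = FALSE)

warn_cm <- function(...) warning(sprintf(...), call. = FALSE)

#' @noRd
assert_prob <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0 | x > 1)) {
    stop_cm("'%s' must be in [0, 1]", name)
  }
  invisible(x)
}
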