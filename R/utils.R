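# Shared numeric helpers and constants.

#' Mass of a proton in Da (charge carrier of the protonated molecule)
#' @keywords internal
PROTON_MASS <- 1.007276

#' C13 - C12 isotope spacing in Da
#' @keywords internal
ISOTOPE_SPACING <- 1.003355

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; printed percentages in reports
#' follow the conventional half-up rule instead (e.g. 3.65 -> 3.7 at one
#' decimal).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_up(c(0.5, 1.5, 2.5))      # 1 2 3
#' round_half_up(3.6514, 1)             # 3.7
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Relative mass difference in ppm
#'
#' Computed on the mean of the two masses, the symmetric convention used
#' throughout the package for all ppm tolerances.
#'
#' @param a,b masses in Da (vectorized).
#' @return absolute difference in parts per million.
#' @export
ppm_diff <- function(a, b) {
  2e6 * abs(a - b) / (a + b)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# run code under a local RNG state, restoring the caller's state afterwards
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
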