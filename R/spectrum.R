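# MS/MS spectrum container.
#
# A spectrum is a lightweight S3 list: precursor m/z, retention time
# (minutes), charge, and a peak list kept sorted by fragment m/z.

#' Create an MS/MS spectrum
#'
#' @param precursor_mz precursor ion m/z in Da.
#' @param rt retention time in minutes.
#' @param mz fragment m/z values in Da.
#' @param intensity fragment intensities (>= 0), same length as `mz`.
#' @param charge precursor charge (default 1).
#' @return an object of class `ms2_spectrum`.
#' @export
#' @examples
#' sp <- ms2_spectrum(200.1, 3.2, c(81.2, 105.6), c(0.4, 1))
#' n_peaks(sp)
ms2_spectrum <- function(precursor_mz, rt = NA_real_, mz = numeric(),
                         intensity = numeric(), charge = 1L) {
  if (length(mz) != length(intensity)) {
    stopf("mz and intensity must have the same length")
  }
  if (any(intensity < 0)) stopf("intensities must be >= 0")
  if (length(precursor_mz) != 1 || !is.finite(precursor_mz) || precursor_mz <= 0) {
    stopf("precursor_mz must be a single positive number")
  }
  o <- order(mz)
  structure(
    list(
      precursor_mz = as.numeric(precursor_mz),
      rt = as.numeric(rt),
      charge = as.integer(charge),
      mz = as.numeric(mz[o]),
      intensity = as.numeric(intensity[o])
    ),
    class = "ms2_spectrum"
  )
}

#' @export
print.ms2_spectrum <- function(x, ...) {
  cat(sprintf(
    "<ms2_spectrum> precursor %.4f m/z, rt %.2f min, %d peaks\n",
    x$precursor_mz, x$rt, length(x$mz)
  ))
  invisible(x)
}

#' Number of fragment peaks in a spectrum
#' @param x an `ms2_spectrum` (or NULL).
#' @return integer peak count (0 for NULL).
#' @export
n_peaks <- function(x) {
  if (is.null(x)) return(0L)
  length(x$mz)
}

is_spectrum <- function(x) inherits(x, "ms2_spectrum")

# sqrt intensity transform + L2 normalization used by the similarity engine
scaled_intensities <- function(sp) {
  w <- sqrt(sp$intensity)
  n <- sqrt(sum(w^2))
  if (n == 0) return(w)
  w / n
}
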