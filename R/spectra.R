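#' Peak wavelength of a spectrum
#'
#' Locates the intensity maximum and refines it by fitting a parabola
#' through the three grid points bracketing the maximum, giving sub-grid
#' resolution for smooth bands.
#'
#' @param spectrum A [spectrum_trace()] with at least 3 points.
#' @return The peak wavelength in nm. When the maximum sits on the first or
#'   last grid point no refinement is possible; the edge wavelength is
#'   returned with a warning and attribute `"edge" = TRUE`.
#' @export
#' @examples
#' s <- spectrum_trace(400:500, exp(-((400:500) - 456)^2 / 200))
#' peak_wavelength(s) # 456
peak_wavelength <- function(spectrum) {
  stopifnot(inherits(spectrum, "spectrum_trace"))
  w <- spectrum$wavelength_nm; y <- spectrum$intensity
  if (length(w) < 3L) stop("need at least 3 spectral points")
  if (max(y) == min(y)) stop("no unique peak: spectrum is flat")
  k <- which.max(y)
  if (k == 1L || k == length(y)) {
    warning("intensity maximum at grid edge; returning edge wavelength")
    return(structure(w[k], edge = TRUE))
  }
  # parabolic vertex through (w[k-1..k+1], y[k-1..k+1])
  x <- w[(k - 1L):(k + 1L)] - w[k]
  z <- y[(k - 1L):(k + 1L)]
  cf <- stats::coef(stats::lm(z ~ x + I(x^2)))
  if (cf[3L] >= 0) return(w[k]) # degenerate bracket, keep grid maximum
  unname(w[k] - cf[2L] / (2 * cf[3L]))
}

#' Normalise a spectrum to unit peak height
#'
#' Divides intensities by their maximum. Idempotent and scale-invariant:
#' relative areas between any two wavelengths are preserved.
#'
#' @param spectrum A [spectrum_trace()] with positive maximum intensity.
#' @return A [spectrum_trace()] with `normalized = TRUE` and peak value 1.
#' @export
normalize_spectrum <- function(spectrum) {
  stopifnot(inherits(spectrum, "spectrum_trace"))
  m <- max(spectrum$intensity)
  if (m <= 0) stop("cannot normalise an all-zero spectrum")
  spectrum_trace(spectrum$wavelength_nm, spectrum$intensity / m,
                 normalized = TRUE)
}
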