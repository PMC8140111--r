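#' Spectrometer specification
#'
#' Describes the detection band of the spectral interrogator: a transmission
#' grating spectrometer that samples the interference spectrum evenly in
#' wavenumber (k-space). Defaults match a broadband superluminescent-diode
#' source centred at 1550 nm read over 1510--1595 nm with 166 pm pixel pitch.
#'
#' @param lambda_min_nm Shortest detected wavelength (nm).
#' @param lambda_max_nm Longest detected wavelength (nm).
#' @param pixel_pitch_pm Pixel resolution of the spectrometer (pm). Together
#'   with the band it fixes the pixel count,
#'   `floor((lambda_max - lambda_min) / pitch)`.
#' @param center_wavelength_nm Mean wavelength of the source (nm); the
#'   reference wavelength of the phase-to-optical-path-length conversion.
#' @param source_fwhm_nm Full width at half maximum of the source spectrum (nm).
#'
#' @return An object of class `spectrometer_spec`.
#' @examples
#' spec <- spectrometer_spec()
#' spec$n_pixels # 512
#' @export
spectrometer_spec <- function(lambda_min_nm = 1510,
                              lambda_max_nm = 1595,
                              pixel_pitch_pm = 166,
                              center_wavelength_nm = 1550,
                              source_fwhm_nm = 50) {
  if (!is.finite(lambda_min_nm) || !is.finite(lambda_max_nm) ||
      lambda_min_nm >= lambda_max_nm) {
    stop("degenerate spectrometer span: lambda_min must be < lambda_max")
  }
  if (!(lambda_min_nm < center_wavelength_nm &&
        center_wavelength_nm < lambda_max_nm)) {
    stop("center wavelength must lie inside the detection band")
  }
  if (pixel_pitch_pm <= 0 || source_fwhm_nm <= 0) {
    stop("pixel pitch and source FWHM must be positive")
  }
  n_pixels <- floor((lambda_max_nm - lambda_min_nm) / (pixel_pitch_pm * 1e-3))
  if (n_pixels < 2) stop("spectrometer must resolve at least 2 pixels")
  structure(
    list(
      lambda_min = lambda_min_nm * 1e-9,
      lambda_max = lambda_max_nm * 1e-9,
      pixel_pitch = pixel_pitch_pm * 1e-12,
      center_wavelength = center_wavelength_nm * 1e-9,
      source_fwhm = source_fwhm_nm * 1e-9,
      n_pixels = as.integer(n_pixels)
    ),
    class = "spectrometer_spec"
  )
}

#' @export
print.spectrometer_spec <- function(x, ...) {
  cat(sprintf(
    "<spectrometer_spec> %g-%g nm, %d pixels, source %g nm FWHM @ %g nm\n",
    x$lambda_min * 1e9, x$lambda_max * 1e9, x$n_pixels,
    x$source_fwhm * 1e9, x$center_wavelength * 1e9
  ))
  invisible(x)
}

#' Uniform wavenumber grid of a spectrometer
#'
#' The interrogator delivers spectra evenly sampled in k-space, so the grid is
#' uniform in wavenumber between `2*pi/lambda_max` and `2*pi/lambda_min`.
#'
#' @param spec A [spectrometer_spec()].
#' @return Strictly increasing numeric vector of wavenumbers (rad/m), length
#'   `spec$n_pixels`, spanning `2*pi*(1/lambda_min - 1/lambda_max)`.
#' @export
wavenumber_grid <- function(spec) {
  stopifnot(inherits(spec, "spectrometer_spec"))
  seq(2 * pi / spec$lambda_max, 2 * pi / spec$lambda_min,
      length.out = spec$n_pixels)
}

# Gaussian source envelope evaluated on a wavenumber grid. The source shape
# is specified in wavelength (FWHM about the centre wavelength).
source_envelope <- function(spec, k = wavenumber_grid(spec)) {
  lam <- 2 * pi / k
  exp(-4 * log(2) * ((lam - spec$center_wavelength) / spec$source_fwhm)^2)
}

# Wavenumber step of the grid (rad/m).
wavenumber_step <- function(spec) {
  k <- c(2 * pi / spec$lambda_max, 2 * pi / spec$lambda_min)
  (k[2] - k[1]) / (spec$n_pixels - 1)
}

#' Cavity-space resolution and unambiguous range
#'
#' A fringe of optical path length (OPL) `L` oscillates as `cos(2 k L)` across
#' the wavenumber grid, so the discrete Fourier transform of a frame maps OPL
#' onto bins of width `pi / (N dk)` and the sampling theorem bounds the
#' largest recoverable OPL at `pi / (2 dk)` (about `lambda^2 / (4 pitch)`,
#' i.e. ~3.6 mm at the default specs).
#'
#' @param spec A [spectrometer_spec()].
#' @return OPL per cavity-space bin, respectively the maximum unambiguous
#'   OPL, in metres.
#' @export
opl_bin_width <- function(spec) {
  pi / (spec$n_pixels * wavenumber_step(spec))
}

#' @rdname opl_bin_width
#' @export
nyquist_opl <- function(spec) {
  pi / (2 * wavenumber_step(spec))
}
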