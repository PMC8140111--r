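#' Cavity space of a single frame
#'
#' Fourier transform of the fringe pattern over the uniform wavenumber grid.
#' Each low-finesse cavity appears as a magnitude peak at its optical path
#' length (OPL): a fringe `cos(2 k L)` lands in the bin at OPL `L`. Frames
#' are mean-subtracted and Hann-windowed before the transform to suppress
#' leakage of the broad source envelope.
#'
#' @param frame Intensity vector (length = pixel count of `spec`).
#' @param spec A [spectrometer_spec()].
#' @return An object of class `cavity_space`: `opl_axis` (m, starting at 0,
#'   spacing [opl_bin_width()]), `magnitude`, and `complex_values`, one-sided
#'   up to the unambiguous OPL range.
#' @export
cavity_space <- function(frame, spec = spectrometer_spec()) {
  if (length(frame) != spec$n_pixels) {
    stop("frame length does not match the spectrometer pixel count")
  }
  n <- spec$n_pixels
  w <- hann_window(n)
  x <- stats::fft(w * (frame - mean(frame)))
  half <- seq_len(n %/% 2 + 1)
  structure(
    list(opl_axis = (half - 1) * opl_bin_width(spec),
         magnitude = Mod(x[half]),
         complex_values = x[half],
         spec = spec),
    class = "cavity_space"
  )
}

hann_window <- function(n) {
  0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
}

#' @export
print.cavity_space <- function(x, ...) {
  cat(sprintf("<cavity_space> %d bins, OPL 0-%.3g mm (bin %.3g um)\n",
              length(x$opl_axis), max(x$opl_axis) * 1e3,
              diff(x$opl_axis[1:2]) * 1e6))
  invisible(x)
}

#' Select a cavity peak in cavity space
#'
#' Finds the bin of maximum magnitude inside an OPL window. The peak must
#' stand out from the spectrum-wide background (median magnitude outside the
#' DC guard) by at least `prominence`, otherwise no cavity is present in the
#' window.
#'
#' @param cs A [cavity_space()].
#' @param window `c(opl_lo, opl_hi)` in metres, inside the axis range.
#' @param prominence Minimum peak-to-background ratio.
#' @param dc_guard_bins Low-OPL bins excluded as the DC/envelope residual.
#' @return Integer bin index (1-based into `cs$opl_axis`).
#' @export
select_peak <- function(cs, window, prominence = 5, dc_guard_bins = 5) {
  stopifnot(inherits(cs, "cavity_space"), length(window) == 2)
  if (window[1] >= window[2]) stop("empty OPL window")
  if (window[2] > max(cs$opl_axis)) {
    stop("window exceeds the unambiguous OPL range (see nyquist_opl)")
  }
  idx <- which(cs$opl_axis >= window[1] & cs$opl_axis <= window[2])
  idx <- setdiff(idx, seq_len(dc_guard_bins))
  if (length(idx) == 0) stop("empty OPL window")
  background <- stats::median(cs$magnitude[-seq_len(dc_guard_bins)])
  bin <- idx[which.max(cs$magnitude[idx])]
  if (cs$magnitude[bin] < prominence * background) {
    stop("no cavity found: peak magnitude below the prominence threshold")
  }
  bin
}

#' Track the interferometric phase of one cavity over a stack
#'
#' Reads the complex cavity-space value at a fixed bin for every frame
#' (mean-subtracted, Hann-windowed, single-bin discrete Fourier projection),
#' unwraps its argument over time and zeroes it at the first frame. Only
#' phase variation is meaningful; the static phase origin is arbitrary.
#'
#' @param stack An [interferogram_stack()].
#' @param bin Bin index from [select_peak()].
#' @return Data frame of class `phase_trace` with columns `time_s` and
#'   `phi_rad`; attribute `bin`. Inter-frame phase steps at or beyond 0.95 pi
#'   raise a warning (near-aliased motion cannot be unwrapped reliably).
#' @export
track_phase <- function(stack, bin) {
  stopifnot(inherits(stack, "interferogram_stack"))
  n <- stack$spec$n_pixels
  if (bin < 1 || bin > n %/% 2 + 1) stop("bin outside cavity space")
  m <- stack$frames
  w <- hann_window(n)
  ph <- -2 * pi * (bin - 1) * (seq_len(n) - 1) / n
  er <- w * cos(ph)
  ei <- w * sin(ph)
  mu <- rowMeans(m)
  zr <- as.vector(m %*% er) - mu * sum(er)
  zi <- as.vector(m %*% ei) - mu * sum(ei)
  raw <- atan2(zi, zr)
  d <- diff(raw)
  d <- d - 2 * pi * round(d / (2 * pi))
  if (length(d) && max(abs(d)) >= 0.95 * pi) {
    warning("inter-frame phase step near pi: motion is under-sampled ",
            "(aliased); unwrapped trace is unreliable")
  }
  phi <- c(0, cumsum(d))
  structure(data.frame(time_s = stack$time, phi_rad = phi),
            class = c("phase_trace", "data.frame"), bin = bin)
}

#' Phase to optical path length variation
#'
#' `dOPL(t) = phi(t) * lambda / (4 pi)`: one interferometric fringe (2 pi of
#' phase) corresponds to half a wavelength of single-pass OPL change.
#'
#' @param phi Unwrapped phase (rad); a vector or a [track_phase()] result.
#' @param lambda_m Reference wavelength (m). For calibrated demodulation use
#'   [effective_wavelength()] of the spectrometer, which accounts for the
#'   window- and envelope-weighted wavenumber centroid of the band.
#' @return OPL variation (m).
#' @export
phase_to_opl <- function(phi, lambda_m) {
  if (lambda_m <= 0) stop("wavelength must be > 0")
  if (inherits(phi, "phase_trace")) phi <- phi$phi_rad
  phi * lambda_m / (4 * pi)
}

#' Effective demodulation wavelength of a spectrometer
#'
#' The phase read at a cavity-space bin advances as `2 k_eff dOPL`, where
#' `k_eff` is the centroid of the analysis window times the source envelope
#' over the wavenumber grid. Using `2 pi / k_eff` instead of the nominal
#' source centre wavelength keeps the phase-to-OPL conversion exact to well
#' below 0.1 nm over millimetre-scale cavities.
#'
#' @param spec A [spectrometer_spec()].
#' @return Wavelength (m).
#' @export
effective_wavelength <- function(spec) {
  k <- wavenumber_grid(spec)
  w <- hann_window(spec$n_pixels) * source_envelope(spec, k)
  2 * pi / (sum(w * k) / sum(w))
}

#' OPL variation to aspirated length
#'
#' The fiber-to-sample cavity is filled with the immersion medium, so the
#' geometric motion is `dOPL / n_medium`; aspiration shortens the cavity and
#' the aspirated length is reported positive into the pipette.
#'
#' @param dopl OPL variation (m).
#' @param n_medium Refractive index of the medium (water: 1.331).
#' @return Aspirated length L_p (m), positive into the pipette.
#' @export
opl_to_displacement <- function(dopl, n_medium) {
  if (n_medium < 1) stop("medium refractive index must be >= 1")
  -dopl / n_medium
}

#' OPL variation to pressure
#'
#' The MEMS cavity is sealed (air, n = 1), so dOPL equals the membrane
#' deflection; the sensitivity constant converts nanometres of deflection to
#' pascals. Suction is positive when the cavity lengthens.
#'
#' @param dopl OPL variation (m).
#' @param sensitivity_pa_nm Membrane sensitivity (Pa/nm), default 76.59.
#' @return Pressure (Pa).
#' @export
opl_to_pressure <- function(dopl, sensitivity_pa_nm = 76.59) {
  if (sensitivity_pa_nm <= 0) stop("sensitivity must be > 0")
  sensitivity_pa_nm * dopl * 1e9
}

#' Demodulate an interferogram stack into pressure and displacement
#'
#' The full all-optical readout chain: cavity-space peak selection in the two
#' OPL windows, fixed-bin phase tracking, phase-to-OPL conversion at the
#' effective wavelength, and calibration of the sample channel (divide by the
#' medium refractive index, flip sign) and of the pressure channel (MEMS
#' sensitivity).
#'
#' @param stack An [interferogram_stack()].
#' @param sample_window,pressure_window OPL windows `c(lo, hi)` (m); defaults
#'   from `probe` via [probe_windows()] when a probe is given.
#' @param n_medium Medium refractive index.
#' @param sensitivity_pa_nm MEMS sensitivity (Pa/nm).
#' @param probe Optional [probe_config()] supplying windows and calibration.
#' @return Data frame `time_s`, `pressure_Pa`, `Lp_m`, with attribute `meta`
#'   (selected bins, windows, effective wavelength, calibration constants).
#' @export
demodulate <- function(stack, sample_window = NULL, pressure_window = NULL,
                       n_medium = 1.331, sensitivity_pa_nm = 76.59,
                       probe = NULL) {
  stopifnot(inherits(stack, "interferogram_stack"))
  if (!is.null(probe)) {
    wins <- probe_windows(probe, stack$spec)
    if (is.null(sample_window)) sample_window <- wins$sample
    if (is.null(pressure_window)) pressure_window <- wins$pressure
    n_medium <- probe$n_medium
    sensitivity_pa_nm <- probe$mems_sensitivity
  }
  if (is.null(sample_window) || is.null(pressure_window)) {
    stop("supply OPL windows or a probe configuration")
  }
  cs <- cavity_space(stack$frames[1, ], stack$spec)
  bin_s <- select_peak(cs, sample_window)
  bin_p <- select_peak(cs, pressure_window)
  lam <- effective_wavelength(stack$spec)
  dopl_s <- phase_to_opl(track_phase(stack, bin_s), lam)
  dopl_p <- phase_to_opl(track_phase(stack, bin_p), lam)
  out <- data.frame(time_s = stack$time,
                    pressure_Pa = opl_to_pressure(dopl_p, sensitivity_pa_nm),
                    Lp_m = opl_to_displacement(dopl_s, n_medium))
  attr(out, "meta") <- list(sample_bin = bin_s, pressure_bin = bin_p,
                            sample_window = sample_window,
                            pressure_window = pressure_window,
                            lambda_eff_m = lam, n_medium = n_medium,
                            sensitivity_pa_nm = sensitivity_pa_nm)
  out
}
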