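#' Low-finesse Fabry-Perot cavity
#'
#' One optical cavity of the probe: two weakly reflecting interfaces a
#' geometric distance `length_m` apart in a medium of refractive index
#' `refractive_index`. In the two-beam (low finesse) approximation the cavity
#' contributes a single fringe `V * cos(2 k n d + phi0)` to the spectrum.
#'
#' @param label Cavity name.
#' @param length_m Geometric cavity length (m), > 0.
#' @param refractive_index Refractive index of the medium between the
#'   interfaces, in \[1, 3\].
#' @param visibility Fringe contrast in \[0, 1\].
#' @param phase_offset Static interferometric phase origin (rad).
#' @return An object of class `optical_cavity`.
#' @export
optical_cavity <- function(label, length_m, refractive_index = 1,
                           visibility = 0.3, phase_offset = 0) {
  if (!is.finite(length_m) || length_m <= 0) stop("cavity length must be > 0")
  if (refractive_index < 1 || refractive_index > 3) {
    stop("refractive index must lie in [1, 3]")
  }
  if (visibility < 0 || visibility > 1) stop("visibility must lie in [0, 1]")
  structure(
    list(label = as.character(label), length = length_m,
         refractive_index = refractive_index, visibility = visibility,
         phase_offset = phase_offset),
    class = "optical_cavity"
  )
}

#' @export
print.optical_cavity <- function(x, ...) {
  cat(sprintf("<optical_cavity '%s'> d = %g um, n = %g, V = %g (OPL %g um)\n",
              x$label, x$length * 1e6, x$refractive_index, x$visibility,
              x$refractive_index * x$length * 1e6))
  invisible(x)
}

#' Aspiration probe configuration
#'
#' The probe multiplexes two working cavities on one spectrometer: the
#' fiber-to-sample cavity (filled with the immersion medium, length shrinks
#' as the sample is aspirated) and the sealed air cavity in front of the MEMS
#' pressure-sensor membrane (length grows with suction). The two rest lengths
#' are chosen different by design so their cavity-space peaks separate.
#'
#' @param pipette_radius Internal pipette radius R_p (m).
#' @param sample_cavity_rest_length Fiber-to-sample distance at rest (m).
#' @param pressure_cavity_rest_length MEMS air-cavity length at rest (m).
#' @param n_medium Refractive index of the immersion medium (water: 1.331).
#' @param mems_sensitivity Membrane sensitivity S of the MEMS pressure sensor
#'   (Pa per nm of deflection); default 76.59.
#' @param sample_visibility,mems_visibility Fringe contrast of the two
#'   working cavities.
#' @param extra_cavities Optional list of static [optical_cavity()] objects
#'   emulating parasitic reflections (e.g. ferrule or fiber-splice peaks).
#' @return An object of class `probe_config`.
#' @export
probe_config <- function(pipette_radius,
                         sample_cavity_rest_length = 300e-6,
                         pressure_cavity_rest_length = 200e-6,
                         n_medium = 1.331,
                         mems_sensitivity = 76.59,
                         sample_visibility = 0.3,
                         mems_visibility = 0.3,
                         extra_cavities = list()) {
  if (pipette_radius <= 0) stop("pipette radius must be > 0")
  if (mems_sensitivity <= 0) stop("MEMS sensitivity must be > 0")
  if (sample_cavity_rest_length <= 0 || pressure_cavity_rest_length <= 0) {
    stop("cavity rest lengths must be > 0")
  }
  if (n_medium < 1) stop("medium refractive index must be >= 1")
  stopifnot(all(vapply(extra_cavities, inherits, TRUE, "optical_cavity")))
  structure(
    list(pipette_radius = pipette_radius,
         sample_cavity_rest_length = sample_cavity_rest_length,
         pressure_cavity_rest_length = pressure_cavity_rest_length,
         n_medium = n_medium,
         mems_sensitivity = mems_sensitivity,
         sample_visibility = sample_visibility,
         mems_visibility = mems_visibility,
         extra_cavities = extra_cavities),
    class = "probe_config"
  )
}

#' @export
print.probe_config <- function(x, ...) {
  cat(sprintf(paste0(
    "<probe_config> R_p = %g um | sample cavity %g um (n = %g) | ",
    "MEMS cavity %g um, S = %g Pa/nm | %d parasitic\n"),
    x$pipette_radius * 1e6, x$sample_cavity_rest_length * 1e6, x$n_medium,
    x$pressure_cavity_rest_length * 1e6, x$mems_sensitivity,
    length(x$extra_cavities)))
  invisible(x)
}

# Rest optical path lengths of the two working cavities (m).
probe_rest_opls <- function(probe) {
  c(sample = probe$n_medium * probe$sample_cavity_rest_length,
    pressure = probe$pressure_cavity_rest_length)
}

#' Default demodulation windows of a probe
#'
#' OPL search windows centred on the rest OPL of the sample and pressure
#' cavities, for peak selection in cavity space.
#'
#' @param probe A [probe_config()].
#' @param spec A [spectrometer_spec()].
#' @param half_width_m Window half width (m of OPL). Defaults to 4
#'   cavity-space bins, which comfortably exceeds the sub-bin peak drift of
#'   aspiration-scale motion.
#' @return List with elements `sample` and `pressure`, each `c(lo, hi)` in m.
#' @export
probe_windows <- function(probe, spec = spectrometer_spec(),
                          half_width_m = 4 * opl_bin_width(spec)) {
  opls <- probe_rest_opls(probe)
  sep <- abs(opls["sample"] - opls["pressure"])
  if (sep <= 2 * half_width_m) {
    stop("sample and pressure cavity windows overlap; reduce half width ",
         "or separate the rest lengths")
  }
  list(sample = unname(opls["sample"] + c(-1, 1) * half_width_m),
       pressure = unname(opls["pressure"] + c(-1, 1) * half_width_m))
}
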