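#' Aspiration geometry parameters
#'
#' Geometry of the linearized Zhou/Plaza aspiration model: pipette radius
#' R_p, aspirated-body radius R_c (Inf for the half-space limit), and the
#' model constants beta1 = 2.0142, beta3 = 2.1187 (incompressible sample,
#' nu = 0.5).
#'
#' @param pipette_radius R_p (m), > 0.
#' @param sample_radius R_c (m) > R_p, or `Inf`.
#' @param beta1,beta3 Model constants; override only for sensitivity studies.
#' @return An object of class `geometry_params`.
#' @export
geometry_params <- function(pipette_radius, sample_radius = Inf,
                            beta1 = 2.0142, beta3 = 2.1187) {
  if (pipette_radius <= 0) stop("pipette radius must be > 0")
  if (!is.infinite(sample_radius) && sample_radius <= pipette_radius) {
    stop("sample radius must exceed the pipette radius (or be Inf)")
  }
  structure(list(pipette_radius = pipette_radius,
                 sample_radius = sample_radius,
                 beta1 = beta1, beta3 = beta3),
            class = "geometry_params")
}

#' Zhou/Plaza geometry factor
#'
#' The dimensionless factor `G = beta1 (1 - (R_p/R_c)^beta3) / 3` relating
#' suction to aspirated strain: `P / E = G L_p / R_p`. In the half-space
#' limit (R_c -> Inf) it reduces to `beta1 / 3` (~0.6714). It decreases as
#' R_p/R_c -> 1, so finite-size-corrected moduli exceed half-space fits of
#' the same data.
#'
#' @param geom A [geometry_params()].
#' @return The factor (dimensionless, > 0).
#' @export
geometry_factor <- function(geom) {
  stopifnot(inherits(geom, "geometry_params"))
  ratio <- if (is.infinite(geom$sample_radius)) 0 else
    geom$pipette_radius / geom$sample_radius
  g <- geom$beta1 * (1 - ratio^geom$beta3) / 3
  if (g <= 0) stop("geometry factor <= 0: model invalid for R_p >= R_c")
  g
}

#' Fit the elastic modulus from a pressure-aspiration curve
#'
#' Ordinary least squares of the aspirated length on pressure over the
#' loading segment (an intercept absorbs any capture offset); the modulus
#' follows from the slope `s` as `E = R_p / (G s)` with `G` the
#' [geometry_factor()].
#'
#' @param pressure Suction pressure (Pa).
#' @param lp Aspirated length (m), same time grid as `pressure`.
#' @param geom A [geometry_params()].
#' @param time Time axis (s); required when `segment` is given.
#' @param segment Optional `c(t0, t1)` restricting the fit to the loading
#'   ramp, e.g. from [ramp_window()].
#' @return An object of class `quasistatic_fit`: `E` (Pa), `slope` (m/Pa),
#'   `r_squared`, `segment`, `n`.
#' @export
fit_elastic_modulus <- function(pressure, lp, geom, time = NULL,
                                segment = NULL) {
  stopifnot(inherits(geom, "geometry_params"),
            length(pressure) == length(lp))
  if (!is.null(segment)) {
    if (is.null(time)) stop("segment selection requires a time axis")
    keep <- time >= segment[1] & time <= segment[2]
    pressure <- pressure[keep]
    lp <- lp[keep]
  }
  if (length(pressure) < 10) stop("segment shorter than 10 samples")
  fit <- stats::lm(lp ~ pressure)
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope <= 0) {
    stop("non-positive aspiration slope: no elastic response to fit")
  }
  r2 <- summary(fit)$r.squared
  structure(list(E = geom$pipette_radius / (geometry_factor(geom) * slope),
                 slope = slope, r_squared = r2,
                 segment = segment, n = length(pressure)),
            class = "quasistatic_fit")
}

#' @export
print.quasistatic_fit <- function(x, ...) {
  cat(sprintf("<quasistatic_fit> E = %.4g kPa (slope %.3g nm/Pa, r2 = %.5f, n = %d)\n",
              x$E / 1e3, x$slope * 1e9, x$r_squared, x$n))
  invisible(x)
}

#' Radial strain of a thin shell
#'
#' Normal strain `dR / R0` of a layer of rest thickness `R0` deflected by
#' `dR`; used to express how gentle an oscillatory aspiration is on a
#' ~10 um shell such as the zona pellucida.
#'
#' @param dR Deflection (m).
#' @param R0 Rest thickness (m), > 0.
#' @return Dimensionless strain.
#' @export
radial_strain <- function(dR, R0) {
  if (any(R0 <= 0)) stop("rest thickness must be > 0")
  dR / R0
}

#' Hydrostatic pressure of a water column
#'
#' `rho g h`: the pressure uncertainty contributed by a height positioning
#' error of the water reservoir (50 um of stage error is below 0.5 Pa).
#'
#' @param height_m Column height (m).
#' @param density Fluid density (kg/m^3), water by default.
#' @param g Gravitational acceleration (m/s^2).
#' @return Pressure (Pa).
#' @export
hydrostatic_pressure <- function(height_m, density = 1000, g = 9.81) {
  density * g * height_m
}
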