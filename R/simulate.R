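#' Acquisition configuration
#'
#' @param sampling_rate_hz Interferogram frame rate (Hz); the instrument
#'   records the full spectrum at every frame (default 1 kHz).
#' @param intensity_noise_sd Additive white Gaussian intensity noise per
#'   pixel, relative to the source envelope peak. The default (0.005) places
#'   the demodulated displacement noise floor well below one nanometre at
#'   1 kHz.
#' @param seed Integer RNG seed; fixes the noise and the per-cavity phase
#'   origins, so identical configurations are bit-identical.
#' @return An object of class `acquisition_config`.
#' @export
acquisition_config <- function(sampling_rate_hz = 1000,
                               intensity_noise_sd = 0.005,
                               seed = 1L) {
  if (sampling_rate_hz <= 0) stop("sampling rate must be > 0")
  if (intensity_noise_sd < 0) stop("noise sd must be >= 0")
  structure(list(sampling_rate = sampling_rate_hz,
                 intensity_noise_sd = intensity_noise_sd,
                 seed = as.integer(seed)),
            class = "acquisition_config")
}

#' Render one interferogram frame
#'
#' Two-beam, low-finesse forward model: each cavity contributes a single
#' cosine fringe, and the frame is
#' `I(k) = E0(k) * (1 + sum_i V_i cos(2 k n_i d_i + phi0_i)) + noise`
#' with `E0` the Gaussian source envelope. Higher-order reflections and
#' reflector cross-terms are neglected.
#'
#' @param cavities Non-empty list of [optical_cavity()] objects.
#' @param spec A [spectrometer_spec()].
#' @param noise_sd Additive Gaussian intensity noise sd (relative to the
#'   envelope peak); drawn from the current RNG state.
#' @return Numeric intensity vector over the spectrometer pixel grid.
#' @export
simulate_frame <- function(cavities, spec = spectrometer_spec(),
                           noise_sd = 0) {
  stopifnot(length(cavities) >= 1,
            all(vapply(cavities, inherits, TRUE, "optical_cavity")))
  vsum <- sum(vapply(cavities, function(cv) cv$visibility, 0))
  if (vsum > 1) {
    warning("total fringe visibility exceeds 1; unphysical contrast")
  }
  k <- wavenumber_grid(spec)
  fr <- rep(1, length(k))
  for (cv in cavities) {
    fr <- fr + cv$visibility *
      cos(2 * k * cv$refractive_index * cv$length + cv$phase_offset)
  }
  fr <- source_envelope(spec, k) * fr
  if (noise_sd > 0) fr <- fr + stats::rnorm(length(k), sd = noise_sd)
  fr
}

#' Mechanical response of a sample to a suction protocol
#'
#' Inverts the linearized aspiration model for the aspirated length. For an
#' elastic sample, `L_p(t) = R_p P(t) / (G E)` at all times, with `G` the
#' Zhou/Plaza geometry factor (see [geometry_factor()]). For viscoelastic
#' samples, ramps and holds follow the quasi-static modulus `|E*|` at the
#' reference frequency, and each sine segment carries the steady-state
#' oscillation `L_0 sin(w t - delta)` with `L_0 = R_p P_0 / (G |E*(w)|)` and
#' `delta = arg E*(w)`. Creep transients are not modelled.
#'
#' @param model A [sample_model()] (see [elastic_sample()]).
#' @param protocol A [pressure_protocol()].
#' @param pipette_radius Pipette radius R_p (m).
#' @param time Time grid (s).
#' @param qs_frequency_hz Reference frequency for the quasi-static baseline of
#'   viscoelastic samples; defaults to the lowest sine frequency in the
#'   protocol.
#' @return Data frame `time_s`, `pressure_Pa`, `Lp_m`.
#' @export
sample_response <- function(model, protocol, pipette_radius, time,
                            qs_frequency_hz = NULL) {
  stopifnot(inherits(model, "sample_model"),
            inherits(protocol, "pressure_protocol"))
  geom <- geometry_params(pipette_radius, model$sample_radius)
  compliance <- function(e_star_mod) {
    pipette_radius / (geometry_factor(geom) * e_star_mod)
  }
  pr <- protocol_pressure(protocol, time)
  if (model$variant == "elastic") {
    lp <- compliance(model$E) * pr$pressure_Pa
    return(data.frame(time_s = time, pressure_Pa = pr$pressure_Pa,
                      Lp_m = lp))
  }
  tab <- protocol$table
  sines <- tab[tab$type == "sine", , drop = FALSE]
  if (is.null(qs_frequency_hz)) {
    if (nrow(sines) == 0) {
      stop("viscoelastic response to a protocol without oscillations needs ",
           "an explicit qs_frequency_hz")
    }
    qs_frequency_hz <- min(sines$frequency)
  }
  e_qs <- Mod(modulus_at(model, qs_frequency_hz))
  if (e_qs == 0) stop("zero modulus magnitude")
  lp <- compliance(e_qs) * pr$baseline_Pa
  for (j in seq_len(nrow(sines))) {
    estar <- modulus_at(model, sines$frequency[j])
    if (Mod(estar) == 0) stop("zero modulus magnitude")
    delta <- Arg(estar)
    in_seg <- time >= sines$t0[j] & time <= sines$t1[j] + 1e-12
    tl <- time[in_seg] - sines$t0[j]
    lp[in_seg] <- lp[in_seg] + compliance(Mod(estar)) * sines$amplitude[j] *
      sin(2 * pi * sines$frequency[j] * tl - delta)
  }
  data.frame(time_s = time, pressure_Pa = pr$pressure_Pa, Lp_m = lp)
}

#' Simulate a full aspiration experiment
#'
#' Whole-instrument forward model: evaluates the protocol and the sample
#' response on the acquisition time grid, assembles the per-frame cavity list
#' (sample cavity at `n_medium` with length `rest - L_p(t)`; sealed MEMS air
#' cavity at `n = 1` with length `rest + P(t)/S`; static parasitic cavities),
#' renders every interferogram frame and returns the stack together with the
#' ground truth. Reproducible from the acquisition seed.
#'
#' @param probe A [probe_config()].
#' @param sample A [sample_model()].
#' @param protocol A [pressure_protocol()].
#' @param acq An [acquisition_config()].
#' @param spec A [spectrometer_spec()].
#' @param qs_frequency_hz Passed to [sample_response()].
#' @return List with elements `stack` (an `interferogram_stack`) and `truth`
#'   (data frame `time_s`, `pressure_Pa`, `Lp_m`, `sample_cavity_m`,
#'   `mems_cavity_m`).
#' @export
simulate_experiment <- function(probe, sample, protocol,
                                acq = acquisition_config(),
                                spec = spectrometer_spec(),
                                qs_frequency_hz = NULL) {
  stopifnot(inherits(probe, "probe_config"),
            inherits(acq, "acquisition_config"))
  tab <- protocol$table
  fmax <- suppressWarnings(max(tab$frequency, na.rm = TRUE))
  if (is.finite(fmax) && acq$sampling_rate <= 2 * fmax) {
    stop("sampling rate violates the Nyquist bound of the protocol")
  }
  opls <- probe_rest_opls(probe)
  if (abs(opls["sample"] - opls["pressure"]) < 2 * opl_bin_width(spec)) {
    stop("sample and pressure cavity peaks are not separable in cavity space")
  }
  if (max(opls) >= nyquist_opl(spec)) {
    stop("cavity OPL exceeds the unambiguous cavity-space range; see ",
         "nyquist_opl()")
  }

  time <- seq(0, protocol_duration(protocol), by = 1 / acq$sampling_rate)
  resp <- sample_response(sample, protocol, probe$pipette_radius, time,
                          qs_frequency_hz = qs_frequency_hz)
  # MEMS deflection: suction lengthens the sealed cavity by P/S (S in Pa/nm)
  d_mems <- probe$pressure_cavity_rest_length +
    resp$pressure_Pa / probe$mems_sensitivity * 1e-9
  d_samp <- probe$sample_cavity_rest_length - resp$Lp_m
  if (any(d_samp <= 0)) stop("aspiration exceeds the sample cavity length")

  set.seed(acq$seed)
  n_extra <- length(probe$extra_cavities)
  phi0 <- stats::runif(2 + n_extra, 0, 2 * pi)

  k <- wavenumber_grid(spec)
  env <- source_envelope(spec, k)
  fr <- 1 + probe$sample_visibility *
    cos(outer(2 * probe$n_medium * d_samp, k) + phi0[1])
  fr <- fr + probe$mems_visibility * cos(outer(2 * d_mems, k) + phi0[2])
  if (n_extra > 0) {
    for (j in seq_len(n_extra)) {
      cv <- probe$extra_cavities[[j]]
      fr <- fr + cv$visibility *
        matrix(cos(2 * k * cv$refractive_index * cv$length + phi0[2 + j]),
               nrow(fr), ncol(fr), byrow = TRUE)
    }
  }
  fr <- sweep(fr, 2, env, "*")
  if (acq$intensity_noise_sd > 0) {
    fr <- fr + matrix(stats::rnorm(length(fr), sd = acq$intensity_noise_sd),
                      nrow(fr))
  }
  truth <- cbind(resp, sample_cavity_m = d_samp, mems_cavity_m = d_mems)
  list(stack = interferogram_stack(time, fr, spec, seed = acq$seed),
       truth = truth)
}

#' Interferogram stack container
#'
#' Time-ordered spectrometer frames with acquisition metadata: the raw
#' measurement object of the instrument.
#'
#' @param time Time axis (s), one entry per frame.
#' @param frames Numeric matrix, one row per frame, one column per pixel.
#' @param spec The [spectrometer_spec()] the frames were sampled with.
#' @param seed Provenance seed (NA for recorded data).
#' @return An object of class `interferogram_stack`.
#' @export
interferogram_stack <- function(time, frames, spec = spectrometer_spec(),
                                seed = NA_integer_) {
  frames <- as.matrix(frames)
  stopifnot(length(time) == nrow(frames),
            ncol(frames) == spec$n_pixels)
  structure(list(time = as.numeric(time), frames = frames, spec = spec,
                 seed = seed),
            class = "interferogram_stack")
}

#' @export
print.interferogram_stack <- function(x, ...) {
  cat(sprintf("<interferogram_stack> %d frames x %d pixels, %.3g s (seed %s)\n",
              nrow(x$frames), ncol(x$frames), diff(range(x$time)),
              as.character(x$seed)))
  invisible(x)
}
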