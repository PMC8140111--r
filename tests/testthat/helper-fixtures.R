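# Shared builders for small synthetic experiments.

default_spec <- spectrometer_spec()

# Zhou/Plaza aspirated length, written out directly from the linearized
# model; the independent oracle for forward-model tests.
zhou_lp <- function(P, E, rp, rc = Inf, b1 = 2.0142, b3 = 2.1187) {
  ratio <- if (is.infinite(rc)) 0 else rp / rc
  3 * rp * P / (E * b1 * (1 - ratio^b3))
}

# A stack with prescribed per-frame geometric lengths for one moving cavity
# (plus optional static cavities), noise-free unless sd > 0.
stack_from_lengths <- function(lengths_m, n_cavity = 1.331, visibility = 0.3,
                               phase0 = 0.6, static_cavities = list(),
                               sd = 0, spec = default_spec,
                               sampling_rate = 1000) {
  frames <- t(vapply(lengths_m, function(d) {
    cavs <- c(list(optical_cavity("moving", d, n_cavity, visibility, phase0)),
              static_cavities)
    simulate_frame(cavs, spec, noise_sd = sd)
  }, numeric(spec$n_pixels)))
  interferogram_stack(seq_along(lengths_m) / sampling_rate -
                        1 / sampling_rate, frames, spec)
}

# Small oocyte-style DMA experiment at reduced sampling rate (cheap tests).
dma_experiment <- function(frequency_hz, e_prime, e_loss, seed = 1,
                           noise_sd = 0.005, sampling_rate = 200,
                           amplitude = 40) {
  probe <- probe_config(pipette_radius = 20e-6)
  samp <- complex_sample(frequency_hz, e_prime, e_loss)
  prot <- protocol_oocyte(frequencies_hz = frequency_hz,
                          amplitude_pa = amplitude)
  sim <- simulate_experiment(probe, samp, prot,
                             acq = acquisition_config(sampling_rate,
                                                      noise_sd, seed))
  list(sim = sim, probe = probe, protocol = prot,
       geom = geometry_params(20e-6, Inf))
}
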