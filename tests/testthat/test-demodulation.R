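test_that("cavity space of a constant frame is empty beyond DC", {
  spec <- spectrometer_spec()
  cs <- cavity_space(rep(2, spec$n_pixels), spec)
  expect_lt(max(cs$magnitude[-(1:5)]), 1e-10)
  expect_equal(cs$opl_axis[1], 0)
  expect_equal(diff(cs$opl_axis[1:2]), opl_bin_width(spec))
  expect_equal(cs$magnitude, Mod(cs$complex_values))
})

test_that("a four-cavity frame shows four local maxima at the configured OPLs", {
  spec <- spectrometer_spec()
  lens <- c(200e-6, 330e-6, 520e-6, 800e-6)
  cavs <- Map(function(d, n) optical_cavity("x", d, n, 0.2),
              lens, c(1, 1.331, 1.5, 1))
  opls <- vapply(cavs, function(cv) cv$refractive_index * cv$length, 0)
  cs <- cavity_space(simulate_frame(cavs, spec), spec)
  for (L in opls) {
    bin <- select_peak(cs, L + c(-1, 1) * 25e-6)
    expect_lt(abs(cs$opl_axis[bin] - L), opl_bin_width(spec))
  }
})

test_that("peak selection fails over empty regions and near-Nyquist windows", {
  spec <- spectrometer_spec()
  cs <- cavity_space(simulate_frame(list(optical_cavity("a", 300e-6, 1.331,
                                                        0.3)), spec), spec)
  expect_error(select_peak(cs, c(1.5e-3, 1.6e-3)), "no cavity found")
  expect_error(select_peak(cs, c(5e-4, 4e-4)), "empty")
  expect_error(select_peak(cs, c(3.5e-3, 4e-3)), "unambiguous")
})

test_that("a static cavity tracks zero phase", {
  stk <- stack_from_lengths(rep(400e-6, 50))
  pt <- track_phase(stk, select_peak(cavity_space(stk$frames[1, ],
                                                  stk$spec),
                                     1.331 * 400e-6 + c(-1, 1) * 30e-6))
  expect_equal(pt$phi_rad, rep(0, 50), tolerance = 1e-9)
})

test_that("an OPL ramp of three wavelengths unwraps to ~12 pi of phase", {
  spec <- spectrometer_spec()
  lam <- effective_wavelength(spec)
  d0 <- 400e-6
  lengths <- d0 + seq(0, 3 * lam / 1.331, length.out = 400)
  stk <- stack_from_lengths(lengths)
  bin <- select_peak(cavity_space(stk$frames[1, ], spec),
                     1.331 * d0 + c(-1, 1) * 40e-6)
  pt <- track_phase(stk, bin)
  total <- pt$phi_rad[400]
  expect_equal(total, 2 * (2 * pi / lam) * 3 * lam, tolerance = 1e-4)
  # and back through Eq.-style conversion: dOPL = 3 wavelengths
  expect_equal(phase_to_opl(total, lam), 3 * lam, tolerance = 1e-6)
})

test_that("slow nanometric sinusoid motion needs no unwrap and is recovered", {
  spec <- spectrometer_spec()
  tt <- seq(0, 2, by = 1e-3)
  lengths <- 400e-6 + 5e-9 * sin(2 * pi * 1 * tt)
  stk <- stack_from_lengths(lengths)
  bin <- select_peak(cavity_space(stk$frames[1, ], spec),
                     1.331 * 400e-6 + c(-1, 1) * 30e-6)
  expect_silent(pt <- track_phase(stk, bin))
  expect_lt(max(abs(diff(pt$phi_rad))), pi / 2)
  dopl <- phase_to_opl(pt, effective_wavelength(spec))
  d_rec <- dopl / 1.331
  fit <- fit_oscillation(d_rec, tt, 1)
  expect_equal(fit$amplitude, 5e-9, tolerance = 1e-3)
})

test_that("aliased motion is flagged instead of silently unwrapped", {
  lam <- effective_wavelength(spectrometer_spec())
  # a quarter wavelength of OPL per frame is a pi phase step
  lengths <- 400e-6 + (0:10) * lam / 4 * 0.99
  stk <- stack_from_lengths(lengths, n_cavity = 1)
  bin <- select_peak(cavity_space(stk$frames[1, ], stk$spec),
                     400e-6 + c(-1, 1) * 30e-6)
  expect_warning(track_phase(stk, bin), "aliased")
})

test_that("phase-to-OPL conversion is the quarter-wavelength-per-pi rule", {
  expect_equal(phase_to_opl(4 * pi, 1550e-9), 1550e-9)
  expect_equal(phase_to_opl(0, 1550e-9), 0)
  expect_equal(phase_to_opl(2.4, 1550e-9), 2 * phase_to_opl(1.2, 1550e-9))
  expect_error(phase_to_opl(1, -1), "wavelength")
})

test_that("calibration conversions divide by the medium RI and apply S", {
  expect_equal(opl_to_displacement(-1.331e-6, 1.331), 1e-6)
  expect_equal(abs(opl_to_displacement(3e-9, 1)), 3e-9)
  expect_equal(opl_to_pressure(1e-9, 76.59), 76.59)
  expect_equal(opl_to_pressure(0), 0)
})

test_that("noise-free simulate-demodulate round trip is sub-0.05 nm", {
  probe <- probe_config(pipette_radius = 45e-6)
  prot <- protocol_trapezoid(hold_s = 1, lead_s = 0.2)
  sim <- simulate_experiment(probe, elastic_sample(50e3, 150e-6), prot,
                             acq = acquisition_config(500, 0, 3))
  dem <- demodulate(sim$stack, probe = probe)
  err_lp <- dem$Lp_m - (sim$truth$Lp_m - sim$truth$Lp_m[1])
  err_p <- dem$pressure_Pa -
    (sim$truth$pressure_Pa - sim$truth$pressure_Pa[1])
  expect_lt(sqrt(mean(err_lp^2)), 0.05e-9)
  expect_lt(sqrt(mean(err_p^2)), 0.1)
})

test_that("round trip stays sub-0.05 nm for a 1.6 mm cavity in water", {
  probe <- probe_config(pipette_radius = 45e-6,
                        sample_cavity_rest_length = 1.6e-3)
  prot <- protocol_trapezoid(hold_s = 0.5, lead_s = 0.2)
  sim <- simulate_experiment(probe, elastic_sample(50e3, 150e-6), prot,
                             acq = acquisition_config(200, 0, 3))
  dem <- demodulate(sim$stack, probe = probe)
  err_lp <- dem$Lp_m - (sim$truth$Lp_m - sim$truth$Lp_m[1])
  expect_lt(sqrt(mean(err_lp^2)), 0.05e-9)
})

test_that("motion on one cavity leaves the other's trace unchanged", {
  spec <- spectrometer_spec()
  # sample cavity ramps 2 um; MEMS cavity static, > 5 bins away
  lengths <- 300e-6 - seq(0, 2e-6, length.out = 300)
  stk <- stack_from_lengths(lengths,
                            static_cavities = list(
                              optical_cavity("mems", 200e-6, 1, 0.3, 1.1)))
  bin_static <- select_peak(cavity_space(stk$frames[1, ], spec),
                            200e-6 + c(-1, 1) * 30e-6)
  dopl <- phase_to_opl(track_phase(stk, bin_static),
                       effective_wavelength(spec))
  expect_lt(sqrt(mean(dopl^2)), 0.1e-9)
})

test_that("cavities beyond the unambiguous OPL range are refused", {
  spec <- spectrometer_spec()
  expect_gt(nyquist_opl(spec), 3.5e-3)
  expect_lt(nyquist_opl(spec), 3.7e-3)
  probe <- probe_config(pipette_radius = 45e-6,
                        sample_cavity_rest_length = 2.9e-3)  # OPL 3.86 mm
  prot <- pressure_protocol(list(seg_hold(0.01)))
  expect_error(simulate_experiment(probe, elastic_sample(50e3), prot),
               "unambiguous")
})

test_that("demodulation with default noise keeps a sub-nanometer floor", {
  probe <- probe_config(pipette_radius = 45e-6)
  prot <- pressure_protocol(list(seg_hold(1)), preload_pa = 0)
  sim <- simulate_experiment(probe, elastic_sample(50e3), prot,
                             acq = acquisition_config(1000, 0.005, 9))
  dem <- demodulate(sim$stack, probe = probe)
  floor_sd <- stats::sd(stats::residuals(stats::lm(dem$Lp_m ~ dem$time_s)))
  expect_lt(floor_sd, 1e-9)
})
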