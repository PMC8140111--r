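test_that("wavenumber grid matches the printed spectrometer geometry", {
  spec <- spectrometer_spec()
  k <- wavenumber_grid(spec)
  # (1595 - 1510) nm / 0.166 nm = 512 pixels
  expect_identical(spec$n_pixels, 512L)
  expect_length(k, 512)
  expect_true(all(diff(k) > 0))
  expect_lt(diff(range(diff(k))), 1e-9 * mean(diff(k)))
  expect_equal(max(k) - min(k), 2 * pi * (1 / 1510e-9 - 1 / 1595e-9))
})

test_that("degenerate spectrometer spans are rejected", {
  expect_error(spectrometer_spec(lambda_min_nm = 1550, lambda_max_nm = 1550),
               "degenerate")
  expect_error(spectrometer_spec(lambda_min_nm = 1595, lambda_max_nm = 1510),
               "degenerate")
  expect_error(spectrometer_spec(center_wavelength_nm = 1700), "inside")
})

test_that("zero visibility yields the bare source envelope", {
  spec <- spectrometer_spec()
  cav <- optical_cavity("a", 300e-6, 1.331, visibility = 0)
  fr <- simulate_frame(list(cav), spec)
  env <- exp(-4 * log(2) *
               ((2 * pi / wavenumber_grid(spec) - spec$center_wavelength) /
                  spec$source_fwhm)^2)
  expect_equal(fr, env, tolerance = 1e-12)
})

test_that("a cavity's cavity-space peak lands within one bin of its OPL", {
  spec <- spectrometer_spec()
  for (d in c(150e-6, 400e-6, 1.2e-3)) {
    cav <- optical_cavity("a", d, 1.331, 0.4)
    cs <- cavity_space(simulate_frame(list(cav), spec), spec)
    peak <- which.max(cs$magnitude[-(1:5)]) + 5L
    expect_lt(abs(cs$opl_axis[peak] - 1.331 * d), opl_bin_width(spec))
  }
})

test_that("cavities of different lengths give separable magnitude peaks", {
  spec <- spectrometer_spec()
  cavs <- list(optical_cavity("sample", 300e-6, 1.331, 0.3),
               optical_cavity("mems", 200e-6, 1, 0.3))
  cs <- cavity_space(simulate_frame(cavs, spec), spec)
  b1 <- select_peak(cs, 1.331 * 300e-6 + c(-1, 1) * 30e-6)
  b2 <- select_peak(cs, 200e-6 + c(-1, 1) * 30e-6)
  expect_false(b1 == b2)
  expect_gt(abs(b1 - b2) * opl_bin_width(spec), 5 * opl_bin_width(spec))
})

test_that("total visibility above one triggers a contrast warning", {
  cavs <- list(optical_cavity("a", 300e-6, 1.331, 0.6),
               optical_cavity("b", 200e-6, 1, 0.6))
  expect_warning(simulate_frame(cavs), "visibility")
})

test_that("elastic response follows the linearized aspiration model", {
  # 50 kPa bead, R_p = 45 um, R_c = 150 um, 1 kPa suction -> ~1.45 um
  prot <- pressure_protocol(list(seg_rest(0.1), seg_ramp(1000, 1000),
                                 seg_hold(0.1)))
  tt <- seq(0, protocol_duration(prot), by = 1e-3)
  resp <- sample_response(elastic_sample(50e3, 150e-6), prot, 45e-6, tt)
  lp_peak <- resp$Lp_m[which.max(resp$pressure_Pa)]
  expect_equal(lp_peak, zhou_lp(1000, 50e3, 45e-6, 150e-6),
               tolerance = 1e-12)
  expect_equal(lp_peak, 1.45e-6, tolerance = 0.005)
  # exact proportionality at all times
  nz <- resp$pressure_Pa > 0
  expect_lt(diff(range(resp$Lp_m[nz] / resp$pressure_Pa[nz])), 1e-18)
})

test_that("oscillatory response amplitude and lag follow the complex modulus", {
  f <- c(0.25, 0.5, 1)
  samp <- power_law_sample(40.50e3, 0.0908, 4.32e3)
  prot <- protocol_dma(preload_pa = 500, amplitude_pa = 60,
                       frequencies_hz = f, n_periods = 4, rest_s = 1,
                       wait_s = 1)
  tt <- seq(0, protocol_duration(prot), by = 1 / 200)
  resp <- sample_response(samp, prot, 20e-6, tt)
  g <- geometry_factor(geometry_params(20e-6, Inf))
  sines <- prot$table[prot$table$type == "sine", ]
  for (j in seq_along(f)) {
    keep <- tt >= sines$t0[j] & tt <= sines$t1[j]
    fit_l <- fit_oscillation(resp$Lp_m[keep], tt[keep], f[j])
    fit_p <- fit_oscillation(resp$pressure_Pa[keep], tt[keep], f[j])
    estar <- power_law_eval(f[j], 40.50e3, 0.0908, 4.32e3)
    expect_equal(fit_l$amplitude, 20e-6 * 60 / (g * Mod(estar)),
                 tolerance = 1e-9)
    expect_equal(phase_lag(fit_p$phase_rad, fit_l$phase_rad), Arg(estar),
                 tolerance = 1e-9)
  }
})

test_that("a perfectly elastic sample responds in phase", {
  prot <- protocol_dma(preload_pa = 500, amplitude_pa = 60,
                       frequencies_hz = 0.5, n_periods = 3, wait_s = 1)
  tt <- seq(0, protocol_duration(prot), by = 1 / 200)
  resp <- sample_response(complex_sample(0.5, 40e3, 0), prot, 20e-6, tt)
  keep <- tt >= prot$table$t0[4]
  fp <- fit_oscillation(resp$pressure_Pa[keep], tt[keep], 0.5)
  fl <- fit_oscillation(resp$Lp_m[keep], tt[keep], 0.5)
  expect_equal(phase_lag(fp$phase_rad, fl$phase_rad), 0, tolerance = 1e-9)
})

test_that("simulated experiments honour the sign conventions and MEMS rule", {
  probe <- probe_config(pipette_radius = 45e-6)
  prot <- protocol_trapezoid(hold_s = 0.5)
  sim <- simulate_experiment(probe, elastic_sample(50e3, 150e-6), prot,
                             acq = acquisition_config(100, 0, 1))
  tr <- sim$truth
  ramp <- tr$time_s > 1 & tr$time_s < 9
  expect_true(all(diff(tr$pressure_Pa[ramp]) > 0))
  expect_true(all(diff(tr$sample_cavity_m[ramp]) < 0))  # suction shortens
  expect_true(all(diff(tr$mems_cavity_m[ramp]) > 0))    # membrane deflects
  # 76.59 Pa of suction lengthens the sealed cavity by exactly 1 nm
  dp <- diff(tr$pressure_Pa)
  dd <- diff(tr$mems_cavity_m)
  expect_equal(dd[ramp[-1]] * 1e9, dp[ramp[-1]] / 76.59, tolerance = 1e-9)
  expect_equal(tr$sample_cavity_m, probe$sample_cavity_rest_length - tr$Lp_m)
})

test_that("zero-amplitude protocols render identical noise-free frames", {
  probe <- probe_config(pipette_radius = 45e-6)
  prot <- pressure_protocol(list(seg_hold(0.05)), preload_pa = 0)
  sim <- simulate_experiment(probe, elastic_sample(50e3), prot,
                             acq = acquisition_config(1000, 0, 1))
  expect_equal(max(apply(sim$stack$frames, 2, function(x) diff(range(x)))), 0)
})

test_that("identical seeds give bit-identical stacks", {
  probe <- probe_config(pipette_radius = 45e-6)
  prot <- pressure_protocol(list(seg_hold(0.05)), preload_pa = 100)
  a <- simulate_experiment(probe, elastic_sample(50e3), prot,
                           acq = acquisition_config(1000, 0.005, 42))
  b <- simulate_experiment(probe, elastic_sample(50e3), prot,
                           acq = acquisition_config(1000, 0.005, 42))
  expect_identical(a$stack$frames, b$stack$frames)
})

test_that("vectorized rendering agrees with the single-frame model", {
  probe <- probe_config(pipette_radius = 45e-6)
  prot <- pressure_protocol(list(seg_ramp(1000, 500)), preload_pa = 0)
  acq <- acquisition_config(100, 0, 7)
  sim <- simulate_experiment(probe, elastic_sample(50e3, 150e-6), prot,
                             acq = acq)
  set.seed(7)
  phi0 <- runif(2, 0, 2 * pi)
  i <- 31
  cavs <- list(
    optical_cavity("s", sim$truth$sample_cavity_m[i], probe$n_medium,
                   probe$sample_visibility, phi0[1]),
    optical_cavity("p", sim$truth$mems_cavity_m[i], 1,
                   probe$mems_visibility, phi0[2]))
  expect_equal(sim$stack$frames[i, ], simulate_frame(cavs), tolerance = 1e-12)
})
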