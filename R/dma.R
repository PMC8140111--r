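#' Fit a single-frequency oscillation with drift correction
#'
#' Linear least squares of a trace on the basis `{sin wt, cos wt, 1, t}` at a
#' known drive frequency. The in-phase and quadrature coefficients give the
#' oscillation amplitude and phase; the `{1, t}` terms absorb the offset and
#' a linear drift (incomplete creep), which over an integer number of periods
#' is orthogonal to the oscillation and leaves amplitude and phase unbiased.
#'
#' @param x Signal values.
#' @param time Time axis (s), covering at least 2 full periods.
#' @param frequency_hz Drive frequency (Hz), known from the protocol.
#' @return An object of class `oscillation_fit`: `frequency_hz`,
#'   `omega_rad_s`, `amplitude`, `phase_rad` (in (-pi, pi]), `offset`,
#'   `drift_slope`, `residual_rms`.
#' @export
fit_oscillation <- function(x, time, frequency_hz) {
  stopifnot(length(x) == length(time), frequency_hz > 0)
  if (diff(range(time)) * frequency_hz < 2) {
    stop("trace covers fewer than 2 full periods")
  }
  w <- 2 * pi * frequency_hz
  tc <- time - time[1]
  X <- cbind(s = sin(w * tc), c = cos(w * tc), one = 1, t = tc)
  cf <- stats::lm.fit(X, x)$coefficients
  a <- cf[["s"]]; b <- cf[["c"]]
  resid <- x - X %*% cf
  structure(list(frequency_hz = frequency_hz, omega_rad_s = w,
                 amplitude = sqrt(a^2 + b^2),
                 phase_rad = atan2(b, a),
                 offset = cf[["one"]], drift_slope = cf[["t"]],
                 residual_rms = sqrt(mean(resid^2)),
                 t_origin = time[1]),
            class = "oscillation_fit")
}

#' @export
print.oscillation_fit <- function(x, ...) {
  cat(sprintf(
    "<oscillation_fit> %g Hz: amplitude %.4g, phase %.4f rad, drift %.3g /s\n",
    x$frequency_hz, x$amplitude, x$phase_rad, x$drift_slope))
  invisible(x)
}

#' Phase lag between drive and response
#'
#' `delta = delta_P - delta_L`, wrapped into (-pi, pi]. A passive
#' viscoelastic response lags the drive by 0 to pi/2; tiny negative values
#' (within `tol`) arise from noise in the perfectly elastic limit and are
#' clamped to zero with a warning, anything else is unphysical and raises an
#' error. Both phases must share the time origin, which the common
#' interferometric clock of the two channels guarantees.
#'
#' @param delta_p Pressure (drive) phase (rad).
#' @param delta_l Aspirated-length (response) phase (rad).
#' @param tol Clamping tolerance for slightly negative lags (rad).
#' @return Phase lag `delta` in `[0, pi/2]` (rad).
#' @export
phase_lag <- function(delta_p, delta_l, tol = 0.01) {
  d <- delta_p - delta_l
  d <- d - 2 * pi * round(d / (2 * pi))
  if (d < 0 && d >= -tol) {
    warning("small negative phase lag clamped to 0")
    d <- 0
  }
  if (d < 0 || d > pi / 2) {
    stop(sprintf("unphysical phase lag %.3f rad (outside [0, pi/2])", d))
  }
  d
}

#' Complex modulus from oscillation amplitudes and phase lag
#'
#' `|E*| = R_p / G * P0 / L0` with `G` the [geometry_factor()];
#' `E' = |E*| cos(delta)`, `E'' = |E*| sin(delta)`. The half-space limit is
#' honoured by `sample_radius = Inf` in the geometry.
#'
#' @param p0 Pressure oscillation amplitude (Pa), >= 0.
#' @param l0 Aspirated-length oscillation amplitude (m), > 0.
#' @param delta Phase lag (rad) in `[0, pi/2]`, from [phase_lag()].
#' @param geom A [geometry_params()].
#' @param frequency_hz Test frequency (Hz), carried through to the result.
#' @return One-row data frame of class `complex_modulus_result`:
#'   `frequency_hz`, `E_star` (Pa), `delta_rad`, `E_prime`, `E_loss`,
#'   `tan_delta`.
#' @export
complex_modulus <- function(p0, l0, delta, geom, frequency_hz = NA_real_) {
  stopifnot(inherits(geom, "geometry_params"))
  if (l0 <= 0) stop("zero aspirated-length amplitude")
  if (delta < 0 || delta > pi / 2) stop("phase lag outside [0, pi/2]")
  e_star <- geom$pipette_radius / geometry_factor(geom) * p0 / l0
  out <- data.frame(frequency_hz = frequency_hz, E_star = e_star,
                    delta_rad = delta, E_prime = e_star * cos(delta),
                    E_loss = e_star * sin(delta), tan_delta = tan(delta))
  class(out) <- c("complex_modulus_result", "data.frame")
  out
}

#' Per-frequency DMA of demodulated traces
#'
#' Runs the oscillation fit on both channels of a demodulated experiment for
#' every sine segment of the protocol, forms the phase lag and the complex
#' modulus. Segments are delimited by the protocol's rests; each frequency is
#' fitted independently.
#'
#' @param traces Data frame with `time_s`, `pressure_Pa`, `Lp_m` (e.g. from
#'   [demodulate()], optionally filtered with [lowpass()]).
#' @param protocol The [pressure_protocol()] that drove the experiment.
#' @param geom A [geometry_params()].
#' @return Data frame, one row per test frequency: amplitudes, phases, phase
#'   lag and moduli.
#' @export
dma_analyze <- function(traces, protocol, geom) {
  tab <- protocol$table
  sines <- tab[tab$type == "sine", , drop = FALSE]
  if (nrow(sines) == 0) stop("protocol contains no oscillation segments")
  res <- lapply(seq_len(nrow(sines)), function(j) {
    keep <- traces$time_s >= sines$t0[j] & traces$time_s <= sines$t1[j]
    tt <- traces$time_s[keep]
    fp <- fit_oscillation(traces$pressure_Pa[keep], tt, sines$frequency[j])
    fl <- fit_oscillation(traces$Lp_m[keep], tt, sines$frequency[j])
    delta <- phase_lag(fp$phase_rad, fl$phase_rad)
    cm <- complex_modulus(fp$amplitude, fl$amplitude, delta, geom,
                          frequency_hz = sines$frequency[j])
    cbind(data.frame(P0_Pa = fp$amplitude, L0_m = fl$amplitude,
                     delta_P_rad = fp$phase_rad, delta_L_rad = fl$phase_rad),
          cm)[, c("frequency_hz", "P0_Pa", "L0_m", "delta_P_rad",
                  "delta_L_rad", "delta_rad", "E_star", "E_prime", "E_loss",
                  "tan_delta")]
  })
  do.call(rbind, res)
}

#' Two-term power-law complex modulus
#'
#' `E*(w) = A (i w)^alpha + B (i w)^(3/4)
#'       = A w^alpha e^(i pi alpha / 2) + B w^(3/4) e^(i 3 pi / 8)`.
#' The frequency-unit convention is explicit: `"rad_s"` plugs `w = 2 pi f`
#' into the law, `"hz"` plugs `w = f`.
#'
#' @param frequency_hz Test frequency (Hz), > 0 (vectorized).
#' @param A,alpha,B Power-law parameters (Pa, -, Pa).
#' @param convention Frequency-unit convention, `"rad_s"` (default) or `"hz"`.
#' @return Complex modulus (Pa), complex vector.
#' @export
power_law_eval <- function(frequency_hz, A, alpha, B,
                           convention = c("rad_s", "hz")) {
  convention <- match.arg(convention)
  if (any(frequency_hz <= 0)) stop("frequency must be > 0")
  w <- if (convention == "rad_s") 2 * pi * frequency_hz else frequency_hz
  A * w^alpha * exp(1i * pi * alpha / 2) +
    B * w^0.75 * exp(1i * 3 * pi / 8)
}

#' Fit the two-term power law to storage/loss moduli
#'
#' Least squares on the stacked real and imaginary residuals of
#' [power_law_eval()], with `A, B >= 0` and `alpha` in `[0, 1]`. For fixed
#' `alpha` the model is linear in `(A, B)`, so the fit profiles `alpha` over
#' a grid and polishes the best point with a bounded one-dimensional
#' optimizer; negative linear solutions fall back to the boundary (`A = 0` or
#' `B = 0`).
#'
#' @param frequency_hz Test frequencies (Hz), at least 3.
#' @param e_prime Storage moduli (Pa).
#' @param e_loss Loss moduli (Pa).
#' @param convention Frequency-unit convention (see [power_law_eval()]),
#'   recorded in the result.
#' @return An object of class `power_law_fit`: `A`, `alpha`, `B`,
#'   `residual_rms` (Pa), `convention`.
#' @export
power_law_fit <- function(frequency_hz, e_prime, e_loss,
                          convention = c("rad_s", "hz")) {
  convention <- match.arg(convention)
  stopifnot(length(frequency_hz) == length(e_prime),
            length(frequency_hz) == length(e_loss))
  if (length(frequency_hz) < 3) stop("need at least 3 frequencies")
  w <- if (convention == "rad_s") 2 * pi * frequency_hz else frequency_hz
  y <- c(e_prime, e_loss)

  design <- function(a) {
    cbind(A = c(w^a * cos(pi * a / 2), w^a * sin(pi * a / 2)),
          B = c(w^0.75 * cos(3 * pi / 8), w^0.75 * sin(3 * pi / 8)))
  }
  solve_ab <- function(a) {
    X <- design(a)
    ab <- tryCatch(qr.solve(X, y), error = function(e) c(A = NA, B = NA))
    if (anyNA(ab) || any(ab < 0)) {
      # bound-constrained fallback: best of the two single-term fits
      cand <- lapply(1:2, function(drop_j) {
        Xj <- X[, -drop_j, drop = FALSE]
        cj <- max(0, sum(Xj * y) / sum(Xj^2))
        abj <- c(0, 0)
        abj[-drop_j] <- cj
        list(ab = abj, rss = sum((y - X %*% abj)^2))
      })
      cand <- cand[[which.min(vapply(cand, `[[`, 0, "rss"))]]
      return(cand)
    }
    list(ab = unname(ab), rss = sum((y - X %*% ab)^2))
  }
  rss_of <- function(a) solve_ab(a)$rss

  grid <- seq(0, 1, by = 0.02)
  a0 <- grid[which.min(vapply(grid, rss_of, 0))]
  opt <- stats::optimize(rss_of, c(max(0, a0 - 0.02), min(1, a0 + 0.02)),
                         tol = .Machine$double.eps^0.5)
  alpha <- opt$minimum
  if (rss_of(a0) < opt$objective) alpha <- a0
  s <- solve_ab(alpha)
  structure(list(A = s$ab[1], alpha = alpha, B = s$ab[2],
                 residual_rms = sqrt(s$rss / length(y)),
                 convention = convention),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf(
    "<power_law_fit> A = %.4g kPa, alpha = %.4g, B = %.4g kPa (%s; rms %.3g Pa)\n",
    x$A / 1e3, x$alpha, x$B / 1e3, x$convention, x$residual_rms))
  invisible(x)
}
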