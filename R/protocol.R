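#' Pressure protocol segments
#'
#' Suction protocols are ordered lists of piecewise segments. Pressure is the
#' suction magnitude, positive into the pipette. A `ramp` moves the baseline
#' pressure toward `target_pa` at `rate_pa_s`; `hold` and `rest` keep it;
#' `sine` superimposes an integer number of oscillation periods on the
#' current baseline.
#'
#' @param rate_pa_s Ramp rate (Pa/s), > 0.
#' @param target_pa Ramp end pressure (Pa).
#' @return A segment object, to be assembled with [pressure_protocol()].
#' @export
seg_ramp <- function(rate_pa_s, target_pa) {
  if (rate_pa_s <= 0) stop("ramp rate must be > 0")
  structure(list(type = "ramp", rate = rate_pa_s, target = target_pa),
            class = "mpa_segment")
}

#' @rdname seg_ramp
#' @param duration_s Segment duration (s), > 0.
#' @export
seg_hold <- function(duration_s) {
  if (duration_s <= 0) stop("duration must be > 0")
  structure(list(type = "hold", duration = duration_s), class = "mpa_segment")
}

#' @rdname seg_ramp
#' @export
seg_rest <- function(duration_s) {
  if (duration_s <= 0) stop("duration must be > 0")
  structure(list(type = "rest", duration = duration_s), class = "mpa_segment")
}

#' @rdname seg_ramp
#' @param amplitude_pa Oscillation amplitude (Pa), >= 0.
#' @param frequency_hz Oscillation frequency (Hz), > 0.
#' @param n_periods Number of full periods, >= 1.
#' @export
seg_sine <- function(amplitude_pa, frequency_hz, n_periods = 5) {
  if (amplitude_pa < 0) stop("amplitude must be >= 0")
  if (frequency_hz <= 0) stop("frequency must be > 0")
  if (n_periods < 1) stop("need at least one period")
  structure(list(type = "sine", amplitude = amplitude_pa,
                 frequency = frequency_hz, n_periods = n_periods),
            class = "mpa_segment")
}

#' Assemble a pressure protocol
#'
#' @param segments List of segments built with [seg_ramp()], [seg_hold()],
#'   [seg_rest()], [seg_sine()].
#' @param preload_pa Baseline suction before the first segment (Pa), e.g. the
#'   capture pressure.
#' @return An object of class `pressure_protocol` carrying a segment table
#'   with start/end times and baseline pressures.
#' @export
pressure_protocol <- function(segments, preload_pa = 0) {
  stopifnot(length(segments) >= 1,
            all(vapply(segments, inherits, TRUE, "mpa_segment")))
  base <- preload_pa
  t0 <- 0
  rows <- lapply(segments, function(s) {
    dur <- switch(s$type,
      ramp = abs(s$target - base) / s$rate,
      hold = s$duration,
      rest = s$duration,
      sine = s$n_periods / s$frequency)
    if (dur <= 0) stop("zero-length ramp: target equals current baseline")
    row <- data.frame(type = s$type, t0 = t0, t1 = t0 + dur,
                      base0 = base,
                      base1 = if (s$type == "ramp") s$target else base,
                      rate = if (s$type == "ramp")
                        s$rate * sign(s$target - base) else 0,
                      amplitude = if (s$type == "sine") s$amplitude else 0,
                      frequency = if (s$type == "sine") s$frequency else NA_real_,
                      n_periods = if (s$type == "sine") s$n_periods else NA_real_)
    t0 <<- t0 + dur
    base <<- row$base1
    row
  })
  structure(list(preload = preload_pa, table = do.call(rbind, rows)),
            class = "pressure_protocol")
}

#' @export
print.pressure_protocol <- function(x, ...) {
  cat(sprintf("<pressure_protocol> preload %g Pa, %d segments, %.3g s total\n",
              x$preload, nrow(x$table), protocol_duration(x)))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' @rdname pressure_protocol
#' @param protocol A `pressure_protocol`.
#' @return Total protocol duration (s).
#' @export
protocol_duration <- function(protocol) {
  max(protocol$table$t1)
}

#' Evaluate a protocol on a time grid
#'
#' @param protocol A [pressure_protocol()].
#' @param time Numeric vector of times (s) in `[0, protocol_duration()]`.
#' @return Data frame with columns `time_s`, `pressure_Pa` (instantaneous,
#'   including oscillation) and `baseline_Pa` (without the sine component).
#' @export
protocol_pressure <- function(protocol, time) {
  tab <- protocol$table
  if (any(time < 0 | time > protocol_duration(protocol) + 1e-9)) {
    stop("time outside protocol span")
  }
  i <- findInterval(time, tab$t0, rightmost.closed = FALSE)
  i[i < 1] <- 1L
  i[i > nrow(tab)] <- nrow(tab)
  tl <- time - tab$t0[i]
  base <- tab$base0[i] + tab$rate[i] * tl
  # ramps can overshoot the target by one sample of rounding; clamp
  ramp <- tab$type[i] == "ramp"
  base[ramp] <- ifelse(tab$rate[i][ramp] > 0,
                       pmin(base[ramp], tab$base1[i][ramp]),
                       pmax(base[ramp], tab$base1[i][ramp]))
  osc <- ifelse(tab$type[i] == "sine",
                tab$amplitude[i] * sin(2 * pi * tab$frequency[i] * tl), 0)
  data.frame(time_s = time, pressure_Pa = base + osc, baseline_Pa = base)
}

#' Protocol presets
#'
#' Ready-made suction protocols:
#' \describe{
#'   \item{`protocol_trapezoid()`}{quasi-static bead aspiration: from the
#'     capture pressure, ramp at 100 Pa/s to a 1 kPa peak, hold 10 s,
#'     symmetric release.}
#'   \item{`protocol_triangle()`}{hysteresis cycling: symmetric triangular
#'     load to 1500 Pa at 150 Pa/s, repeated 5 times.}
#'   \item{`protocol_dma()`}{dynamic mechanical analysis: ramp to a 1500 Pa
#'     preload, wait 10 s, then 5 oscillation periods (60 Pa amplitude) at
#'     each of 0.05, 0.1, 0.35, 0.75 and 1 Hz, separated by 2 s rests.}
#'   \item{`protocol_oocyte()`}{gentle capture at ~50 Pa, a 50 Pa load ramp,
#'     4 s wait, then the oscillation series at reduced amplitude.}
#' }
#'
#' @param capture_pa Capture suction preceding the test (Pa).
#' @param rate_pa_s Ramp rate (Pa/s).
#' @param peak_pa Peak suction (Pa).
#' @param hold_s Hold at peak (s).
#' @param lead_s Settling rest before the first ramp (s).
#' @return A [pressure_protocol()].
#' @export
protocol_trapezoid <- function(capture_pa = 100, rate_pa_s = 100,
                               peak_pa = 1000, hold_s = 10, lead_s = 1) {
  pressure_protocol(list(
    seg_rest(lead_s),
    seg_ramp(rate_pa_s, peak_pa),
    seg_hold(hold_s),
    seg_ramp(rate_pa_s, capture_pa)
  ), preload_pa = capture_pa)
}

#' @rdname protocol_trapezoid
#' @param cycles Number of triangular load/unload cycles.
#' @export
protocol_triangle <- function(capture_pa = 100, rate_pa_s = 150,
                              peak_pa = 1500, cycles = 5, lead_s = 1) {
  segs <- c(list(seg_rest(lead_s)),
            unlist(replicate(cycles, list(seg_ramp(rate_pa_s, peak_pa),
                                          seg_ramp(rate_pa_s, capture_pa)),
                             simplify = FALSE), recursive = FALSE))
  pressure_protocol(segs, preload_pa = capture_pa)
}

#' @rdname protocol_trapezoid
#' @param preload_pa Preload suction before the oscillations (Pa).
#' @param amplitude_pa Oscillation amplitude (Pa).
#' @param frequencies_hz Test frequencies (Hz).
#' @param n_periods Oscillation periods per frequency.
#' @param wait_s Wait after reaching the preload (s).
#' @param rest_s Rest between oscillation bursts (s).
#' @export
protocol_dma <- function(preload_pa = 1500, amplitude_pa = 60,
                         frequencies_hz = c(0.05, 0.1, 0.35, 0.75, 1),
                         n_periods = 5, rate_pa_s = 150, wait_s = 10,
                         rest_s = 2, lead_s = 1) {
  segs <- c(list(seg_rest(lead_s), seg_ramp(rate_pa_s, preload_pa),
                 seg_hold(wait_s)))
  for (j in seq_along(frequencies_hz)) {
    segs <- c(segs, list(seg_sine(amplitude_pa, frequencies_hz[j], n_periods)))
    if (j < length(frequencies_hz)) segs <- c(segs, list(seg_rest(rest_s)))
  }
  pressure_protocol(segs, preload_pa = 0)
}

#' @rdname protocol_trapezoid
#' @param load_pa Post-capture load ramp height (Pa).
#' @export
protocol_oocyte <- function(capture_pa = 50, load_pa = 50, rate_pa_s = 50,
                            amplitude_pa = 40,
                            frequencies_hz = c(0.05, 0.1, 0.35, 0.75, 1),
                            n_periods = 5, wait_s = 4, rest_s = 2,
                            lead_s = 1) {
  segs <- c(list(seg_rest(lead_s),
                 seg_ramp(rate_pa_s, capture_pa + load_pa),
                 seg_hold(wait_s)))
  for (j in seq_along(frequencies_hz)) {
    segs <- c(segs, list(seg_sine(amplitude_pa, frequencies_hz[j], n_periods)))
    if (j < length(frequencies_hz)) segs <- c(segs, list(seg_rest(rest_s)))
  }
  pressure_protocol(segs, preload_pa = capture_pa)
}

#' Time span of a loading ramp within a protocol
#'
#' Returns the `[t0, t1]` span of the `which`-th upward (loading) ramp,
#' useful for restricting quasi-static fits to the aspiration portion.
#'
#' @param protocol A [pressure_protocol()].
#' @param which Index of the loading ramp (1 = first).
#' @return Numeric `c(t0, t1)` in seconds.
#' @export
ramp_window <- function(protocol, which = 1) {
  tab <- protocol$table
  up <- which(tab$type == "ramp" & tab$rate > 0)
  if (length(up) < which) stop("protocol has no such loading ramp")
  c(tab$t0[up[which]], tab$t1[up[which]])
}
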