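#' Low-pass filter a demodulated trace
#'
#' Third-order Butterworth low-pass (maximally flat passband), applied
#' forward-backward by default so the filter is zero-phase and dynamic
#' mechanical phase lags between channels are untouched.
#'
#' @param x Numeric signal, uniformly sampled.
#' @param sampling_rate_hz Sampling rate (Hz).
#' @param cutoff_hz Cutoff frequency (Hz), below Nyquist. Default 25.
#' @param order Filter order, default 3.
#' @param zero_phase Two-pass (forward-backward, zero phase) when TRUE;
#'   single-pass causal otherwise.
#' @return Filtered signal, same length as `x`.
#' @export
lowpass <- function(x, sampling_rate_hz, cutoff_hz = 25, order = 3,
                    zero_phase = TRUE) {
  if (cutoff_hz <= 0 || cutoff_hz >= sampling_rate_hz / 2) {
    stop("cutoff must lie in (0, Nyquist)")
  }
  if (order < 1) stop("order must be >= 1")
  bf <- signal::butter(order, cutoff_hz / (sampling_rate_hz / 2),
                       type = "low")
  if (zero_phase) {
    # remove the mean before the two-pass filter to limit edge transients
    mu <- mean(x)
    signal::filtfilt(bf, x - mu) + mu
  } else {
    as.numeric(signal::filter(bf, x))
  }
}

#' Select the low-pass cutoff from a periodogram
#'
#' Inspects the periodogram of a trace, normalized to its maximum, and
#' returns the lowest frequency at which the power spectral density first
#' drops below `threshold_db` and stays below it for `run_hz` of contiguous
#' bandwidth. When the PSD never settles below the threshold (e.g. white
#' noise) the default cutoff is returned.
#'
#' @param x Numeric signal, at least `min_duration_s` long.
#' @param sampling_rate_hz Sampling rate (Hz).
#' @param threshold_db Threshold relative to the PSD maximum (dB), default -40.
#' @param run_hz Required contiguous bandwidth below threshold (Hz).
#' @param default_hz Cutoff returned when no crossing exists.
#' @param min_duration_s Minimum trace duration for a stable periodogram (s).
#' @return Cutoff frequency (Hz).
#' @export
select_cutoff <- function(x, sampling_rate_hz, threshold_db = -40,
                          run_hz = 2, default_hz = 25, min_duration_s = 10) {
  if (length(x) / sampling_rate_hz < min_duration_s) {
    stop(sprintf("trace too short for a stable periodogram (< %g s)",
                 min_duration_s))
  }
  pg <- stats::spec.pgram(x, taper = 0.1, detrend = TRUE, plot = FALSE)
  freq <- pg$freq * sampling_rate_hz
  psd_db <- 10 * log10(pg$spec / max(pg$spec))
  below <- psd_db < threshold_db
  run_bins <- max(1L, as.integer(ceiling(run_hz / diff(freq[1:2]))))
  if (sum(below) < run_bins) return(default_hz)
  # first index from which `run_bins` consecutive bins sit below threshold
  cs <- cumsum(below)
  n <- length(below)
  for (i in seq_len(n - run_bins + 1)) {
    if (cs[i + run_bins - 1] - cs[i] + below[i] == run_bins) return(freq[i])
  }
  default_hz
}
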