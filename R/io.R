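#' Read and write uniformly sampled time series
#'
#' Columnar text (CSV) with a `time_s` column first and one column per
#' channel, units encoded in the column names (`pressure_Pa`, `Lp_m`).
#' Reading checks that the time axis is strictly increasing and uniform (max
#' jitter below 1% of the sampling interval).
#'
#' @param path File path.
#' @return `read_timeseries`: a data frame with attribute
#'   `sampling_rate_hz`.
#' @export
read_timeseries <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"time_s" %in% names(df)) stop("missing 'time_s' header")
  if (ncol(df) < 2) stop("no data channels found")
  dt <- diff(df$time_s)
  if (any(dt <= 0)) stop("non-monotone time axis")
  if (max(abs(dt - stats::median(dt))) > 0.01 * stats::median(dt)) {
    stop("time axis is not uniform (jitter above 1% of the interval)")
  }
  attr(df, "sampling_rate_hz") <- 1 / stats::median(dt)
  df
}

#' @rdname read_timeseries
#' @param df Data frame whose first column is `time_s`.
#' @export
write_timeseries <- function(df, path) {
  stopifnot("time_s" %in% names(df))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Store and reload interferogram stacks as text
#'
#' For small fixtures the stack is written as a CSV (column `time_s`, then
#' one column per pixel) plus a JSON sidecar manifest carrying the
#' spectrometer metadata and the provenance seed.
#'
#' @param stack An [interferogram_stack()].
#' @param path CSV path; the manifest is written to `<path>.json`.
#' @return `read_stack`: the reconstructed stack.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "interferogram_stack"))
  df <- data.frame(time_s = stack$time, stack$frames)
  names(df)[-1] <- sprintf("px%04d", seq_len(ncol(stack$frames)))
  utils::write.csv(df, path, row.names = FALSE)
  sp <- stack$spec
  manifest <- list(
    lambda_min_nm = sp$lambda_min * 1e9, lambda_max_nm = sp$lambda_max * 1e9,
    pixel_pitch_pm = sp$pixel_pitch * 1e12,
    center_wavelength_nm = sp$center_wavelength * 1e9,
    source_fwhm_nm = sp$source_fwhm * 1e9,
    seed = if (is.na(stack$seed)) NULL else stack$seed
  )
  jsonlite::write_json(manifest, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  man <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  spec <- spectrometer_spec(man$lambda_min_nm, man$lambda_max_nm,
                            man$pixel_pitch_pm, man$center_wavelength_nm,
                            man$source_fwhm_nm)
  df <- utils::read.csv(path)
  interferogram_stack(df$time_s, as.matrix(df[, -1, drop = FALSE]), spec,
                      seed = if (is.null(man$seed)) NA_integer_ else man$seed)
}

#' Experiment presets
#'
#' Bundled probe/sample/protocol configurations for the validation
#' experiments the instrument was designed around:
#' \describe{
#'   \item{`alginate-trapezoid`}{50 kPa elastic hydrogel bead
#'     (R_c = 150 um) aspirated with a 45 um pipette through the trapezoidal
#'     quasi-static protocol.}
#'   \item{`fishroe-triangle`}{360 kPa elastic fish-roe body (R_c = 1 mm)
#'     through the triangular hysteresis protocol.}
#'   \item{`zp-dma`}{zona pellucida DMA: power-law sample
#'     (A = 40.50 kPa, alpha = 0.0908, B = 4.32 kPa, rad/s convention),
#'     half-space geometry, 20 um pipette, oocyte oscillation protocol.}
#'   \item{`oocyte-capture`}{capture and load ramp only (no oscillations),
#'     for quasi-static inspection of an oocyte-like power-law sample.}
#' }
#'
#' @param name Preset name.
#' @return List with elements `probe`, `sample`, `protocol`, `geom`,
#'   `analysis` (`"quasistatic"`, `"dma"` or `"none"`).
#' @export
mpa_preset <- function(name = c("alginate-trapezoid", "fishroe-triangle",
                                "zp-dma", "oocyte-capture")) {
  name <- match.arg(name)
  switch(name,
    "alginate-trapezoid" = list(
      probe = probe_config(pipette_radius = 45e-6),
      sample = elastic_sample(50e3, sample_radius = 150e-6),
      protocol = protocol_trapezoid(),
      geom = geometry_params(45e-6, 150e-6),
      analysis = "quasistatic"),
    "fishroe-triangle" = list(
      probe = probe_config(pipette_radius = 45e-6),
      sample = elastic_sample(360e3, sample_radius = 1e-3),
      protocol = protocol_triangle(),
      geom = geometry_params(45e-6, 1e-3),
      analysis = "quasistatic"),
    "zp-dma" = list(
      probe = probe_config(pipette_radius = 20e-6),
      sample = power_law_sample(40.50e3, 0.0908, 4.32e3),
      protocol = protocol_oocyte(),
      geom = geometry_params(20e-6, Inf),
      analysis = "dma"),
    "oocyte-capture" = list(
      probe = probe_config(pipette_radius = 20e-6),
      sample = power_law_sample(40.50e3, 0.0908, 4.32e3),
      protocol = pressure_protocol(list(seg_rest(1),
                                        seg_ramp(50, 100),
                                        seg_hold(4)),
                                   preload_pa = 50),
      geom = geometry_params(20e-6, Inf),
      qs_frequency_hz = 0.05,
      analysis = "none")
  )
}

#' Run the full pipeline on a preset or explicit configuration
#'
#' simulate -> demodulate -> low-pass filter -> quasi-static fit and/or DMA,
#' returning every intermediate product. Deterministic for a fixed seed.
#'
#' @param config Either a preset name (see [mpa_preset()]) or a list with
#'   fields `probe`, `sample`, `protocol`, `geom`, `analysis`.
#' @param seed RNG seed for the acquisition.
#' @param noise_sd Intensity noise (relative units); default of
#'   [acquisition_config()].
#' @param sampling_rate_hz Frame rate (Hz).
#' @param cutoff_hz Low-pass cutoff (Hz); `NA` skips filtering.
#' @param out_dir Optional directory: writes `truth.csv`, `demodulated.csv`
#'   and `result.json` there.
#' @return List: `config`, `truth`, `demodulated`, `filtered`, `result`
#'   (a `quasistatic_fit`, a DMA table, or NULL), and `qs_frequency_hz`.
#' @export
run_pipeline <- function(config, seed = 1L, noise_sd = 0.005,
                         sampling_rate_hz = 1000, cutoff_hz = 25,
                         out_dir = NULL) {
  if (is.character(config)) config <- mpa_preset(config)
  needed <- c("probe", "sample", "protocol", "geom", "analysis")
  missing <- setdiff(needed, names(config))
  if (length(missing)) {
    stop("configuration is missing fields: ", paste(missing, collapse = ", "))
  }
  acq <- acquisition_config(sampling_rate_hz, noise_sd, seed)
  sim <- simulate_experiment(config$probe, config$sample, config$protocol,
                             acq = acq,
                             qs_frequency_hz = config$qs_frequency_hz)
  dem <- demodulate(sim$stack, probe = config$probe)
  flt <- dem
  if (!is.na(cutoff_hz)) {
    flt$pressure_Pa <- lowpass(dem$pressure_Pa, sampling_rate_hz, cutoff_hz)
    flt$Lp_m <- lowpass(dem$Lp_m, sampling_rate_hz, cutoff_hz)
  }
  result <- switch(config$analysis,
    quasistatic = fit_elastic_modulus(flt$pressure_Pa, flt$Lp_m, config$geom,
                                      time = flt$time_s,
                                      segment = ramp_window(config$protocol)),
    dma = dma_analyze(flt, config$protocol, config$geom),
    none = NULL)
  out <- list(config = config, seed = seed, truth = sim$truth,
              demodulated = dem, filtered = flt, result = result)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_timeseries(sim$truth, file.path(out_dir, "truth.csv"))
    write_timeseries(dem, file.path(out_dir, "demodulated.csv"))
    jsonlite::write_json(
      list(seed = seed, analysis = config$analysis,
           result = result_to_list(result)),
      file.path(out_dir, "result.json"), auto_unbox = TRUE, digits = NA)
  }
  out
}

result_to_list <- function(result) {
  if (is.null(result)) return(NULL)
  if (inherits(result, "quasistatic_fit")) {
    return(list(E_Pa = result$E, slope_m_per_Pa = result$slope,
                r_squared = result$r_squared, n = result$n))
  }
  result
}
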