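#' Default evoked-response specification
#'
#' Evoked components injected by \code{\link{simulate_sensor_recording}}.
#' `common` components are added to every tone (the obligatory auditory
#' response); `deviant_extra` components are added only to deviant tones in
#' the awake state, so that the deviant-minus-standard difference wave shows
#' a negative MMN-like deflection over fronto-central sensors.  Components
#' are Gaussian bumps described by latency (ms post-onset), full width at
#' half maximum (ms) and signed amplitude (microvolt).
#'
#' @return a list with data.frames `common` and `deviant_extra`.
#' @export
default_erp_spec <- function() {
  list(
    common = data.frame(latency_ms = 100, width_ms = 60, amplitude_uv = -2),
    deviant_extra = data.frame(latency_ms = 160, width_ms = 70, amplitude_uv = -3)
  )
}

#' Simulation configuration for the synthetic oddball study
#'
#' Bundles every knob of the synthetic-data generator.  The defaults encode
#' the oddball protocol under study: blocks of 300 randomly ordered pure
#' tones (200 standards at 500 Hz, 50 + 50 deviants at 450/550 Hz), 75 ms
#' tones separated by a 1000 ms inter-stimulus interval (offset-to-onset, so
#' consecutive onsets are 1075 ms apart), EEG sampled at 1 kHz, and
#' gamma-band (30--40 Hz) ROI oscillations.
#'
#' Phase couplings between ROI pairs are specified as a data.frame
#' `coupling_spec` with columns `roi_i` (driver), `roi_j` (follower),
#' `phase_lag` (radians, in (-pi, pi]), `strength` (0..1) and `condition`
#' (`"standard"`, `"deviant"` or `"both"`).  A coupling of strength 1 locks
#' the follower's phase to driver phase + lag exactly; lower strengths add
#' wrapped-normal phase jitter with standard deviation `(1 - strength) * pi`
#' (constant within a trial), so strength 0 is indistinguishable from an
#' independent oscillator.  In the anesthesia state all strengths are
#' multiplied by `anesthesia_attenuation`.
#'
#' @param n_blocks number of stimulus blocks.
#' @param tones_per_block tones per block (default 300).
#' @param n_standard,n_deviant_low,n_deviant_high per-block counts of
#'   standard / low-pitch deviant / high-pitch deviant tones; must sum to
#'   `tones_per_block`.
#' @param tone_duration_ms tone duration in ms.
#' @param isi_ms offset-to-onset inter-stimulus interval in ms.
#' @param sampling_rate_hz EEG sampling rate in Hz.
#' @param gamma_band_hz two-element band (Hz) of the ROI oscillations.
#' @param epoch_window_ms half-open epoch window `[lo, hi)` in ms relative to
#'   tone onset used when simulating per-trial ROI signals.
#' @param coupling_spec coupling table as described above, or `NULL`.
#' @param anesthesia_attenuation factor in `[0, 1]` multiplying coupling
#'   strengths in the anesthesia state.
#' @param noise_sd standard deviation of the additive white noise on ROI and
#'   source signals (oscillation amplitude is 1).
#' @param sensor_noise_sd standard deviation of sensor noise in
#'   \code{\link{simulate_sensor_recording}}; defaults to `noise_sd`.
#' @param erp_spec evoked-component specification, see
#'   \code{\link{default_erp_spec}}.
#' @param n_rois number of cortical ROIs carried by the ROI simulator.
#' @param seed integer base seed; all generator randomness derives from it.
#' @return an object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(seed = 7)
#' cfg$tones_per_block
sim_config <- function(n_blocks = 1L,
                       tones_per_block = 300L,
                       n_standard = 200L,
                       n_deviant_low = 50L,
                       n_deviant_high = 50L,
                       tone_duration_ms = 75,
                       isi_ms = 1000,
                       sampling_rate_hz = 1000,
                       gamma_band_hz = c(30, 40),
                       epoch_window_ms = c(-100, 700),
                       coupling_spec = NULL,
                       anesthesia_attenuation = 0.3,
                       noise_sd = 0.5,
                       sensor_noise_sd = NULL,
                       erp_spec = default_erp_spec(),
                       n_rois = 148L,
                       seed = 1L) {
  cfg <- list(
    n_blocks = as.integer(n_blocks),
    tones_per_block = as.integer(tones_per_block),
    n_standard = as.integer(n_standard),
    n_deviant_low = as.integer(n_deviant_low),
    n_deviant_high = as.integer(n_deviant_high),
    tone_duration_ms = tone_duration_ms,
    isi_ms = isi_ms,
    sampling_rate_hz = sampling_rate_hz,
    gamma_band_hz = gamma_band_hz,
    epoch_window_ms = epoch_window_ms,
    coupling_spec = coupling_spec,
    anesthesia_attenuation = anesthesia_attenuation,
    noise_sd = noise_sd,
    sensor_noise_sd = if (is.null(sensor_noise_sd)) noise_sd else sensor_noise_sd,
    erp_spec = erp_spec,
    n_rois = as.integer(n_rois),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  counts <- c(cfg$n_standard, cfg$n_deviant_low, cfg$n_deviant_high)
  if (any(counts < 0L)) stop("tone counts must be non-negative")
  if (sum(counts) != cfg$tones_per_block) {
    stop(sprintf(
      "tone counts (%d standard + %d + %d deviant = %d) do not sum to tones_per_block = %d",
      cfg$n_standard, cfg$n_deviant_low, cfg$n_deviant_high,
      sum(counts), cfg$tones_per_block
    ))
  }
  if (cfg$n_blocks < 1L) stop("n_blocks must be >= 1")
  if (cfg$sampling_rate_hz <= 0) stop("sampling_rate_hz must be positive")
  if (length(cfg$gamma_band_hz) != 2L || cfg$gamma_band_hz[1] >= cfg$gamma_band_hz[2])
    stop("gamma_band_hz must be an increasing pair")
  if (length(cfg$epoch_window_ms) != 2L || cfg$epoch_window_ms[1] >= cfg$epoch_window_ms[2])
    stop("epoch_window_ms must be an increasing pair")
  if (!is.finite(cfg$anesthesia_attenuation) ||
      cfg$anesthesia_attenuation < 0 || cfg$anesthesia_attenuation > 1)
    stop("anesthesia_attenuation must lie in [0, 1]")
  if (cfg$noise_sd < 0 || cfg$sensor_noise_sd < 0) stop("noise sd must be >= 0")
  if (cfg$n_rois < 1L) stop("n_rois must be >= 1")
  if (!is.null(cfg$coupling_spec)) validate_coupling_spec(cfg$coupling_spec, cfg$n_rois)
  invisible(cfg)
}

validate_coupling_spec <- function(spec, n_rois) {
  need <- c("roi_i", "roi_j", "phase_lag", "strength", "condition")
  if (!is.data.frame(spec) || !all(need %in% names(spec)))
    stop("coupling_spec must be a data.frame with columns ",
         paste(need, collapse = ", "))
  rois <- c(spec$roi_i, spec$roi_j)
  bad <- rois[rois < 1 | rois > n_rois | rois != round(rois)]
  if (length(bad))
    stop("coupling_spec refers to unknown ROI index: ", paste(unique(bad), collapse = ", "))
  if (any(spec$roi_i == spec$roi_j)) stop("coupling_spec: roi_i and roi_j must differ")
  if (any(spec$strength < 0 | spec$strength > 1))
    stop("coupling_spec: strength must lie in [0, 1]")
  if (any(spec$phase_lag <= -pi | spec$phase_lag > pi))
    stop("coupling_spec: phase_lag must lie in (-pi, pi]")
  if (!all(spec$condition %in% c("standard", "deviant", "both")))
    stop("coupling_spec: condition must be 'standard', 'deviant' or 'both'")
  invisible(spec)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  blocks: %d x %d tones (%d standard, %d + %d deviant)\n",
              x$n_blocks, x$tones_per_block, x$n_standard,
              x$n_deviant_low, x$n_deviant_high))
  cat(sprintf("  tone %g ms, ISI %g ms, fs %g Hz, gamma %g-%g Hz\n",
              x$tone_duration_ms, x$isi_ms, x$sampling_rate_hz,
              x$gamma_band_hz[1], x$gamma_band_hz[2]))
  nc <- if (is.null(x$coupling_spec)) 0L else nrow(x$coupling_spec)
  cat(sprintf("  %d ROIs, %d couplings, anesthesia attenuation %g, noise sd %g, seed %d\n",
              x$n_rois, nc, x$anesthesia_attenuation, x$noise_sd, x$seed))
  invisible(x)
}
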