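# Sensor-space simulation: a random but conditioning-controlled leadfield
# (stand-in for a head-model forward solution, which this package never
# computes) and a continuous multichannel recording with evoked components,
# so that the preprocessing and inverse stages can be exercised end to end.

# Standard 10-10 montage names used as default sensor labels (64 channels;
# M1/M2 are the mastoids, VEO the vertical EOG).
std_1010_names <- c(
  "Fp1", "Fpz", "Fp2", "AF7", "AF3", "AFz", "AF4", "AF8",
  "F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8",
  "FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8",
  "T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8",
  "TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8",
  "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8",
  "PO7", "PO3", "POz", "PO4", "PO8", "O1", "Oz", "O2",
  "M1", "M2", "VEO"
)

#' Default sensor names for a montage of a given size
#'
#' The first `n` labels of a standard 10-10 64-channel layout (Fz is
#' included from `n >= 13`); generic labels are appended beyond 64.
#'
#' @param n number of sensors.
#' @return character vector of length `n`.
#' @export
std_channel_names <- function(n) {
  if (n <= length(std_1010_names)) return(std_1010_names[seq_len(n)])
  c(std_1010_names, sprintf("EX%02d", seq_len(n - length(std_1010_names))))
}

#' Construct a reproducible random leadfield with controlled conditioning
#'
#' Builds `gain = U diag(s) V'` from random orthonormal factors with
#' log-spaced singular values from 1 down to `1/conditioning`, so the
#' condition number of the gain is exactly `conditioning`.  With
#' `conditioning` near 1 the map is near-orthogonal and the inverse
#' round-trip is well posed.
#'
#' @param n_sensors,n_sources matrix dimensions (both >= 1).
#' @param conditioning target condition number, must be > 1.
#' @param seed integer seed.
#' @param sensor_names optional sensor labels; defaults to
#'   \code{\link{std_channel_names}}.
#' @return an object of class `leadfield`: list with `gain`
#'   (sensors x sources, microvolt per unit source amplitude),
#'   `sensor_names`, `source_ids`.
#' @export
#' @examples
#' lf <- make_leadfield(16, 40, conditioning = 5, seed = 1)
#' dim(lf$gain)
make_leadfield <- function(n_sensors, n_sources, conditioning = 10, seed = 1L,
                           sensor_names = NULL) {
  if (n_sensors < 1 || n_sources < 1)
    stop("n_sensors and n_sources must be >= 1")
  if (!is.finite(conditioning) || conditioning <= 1)
    stop("conditioning must be > 1")
  r <- min(n_sensors, n_sources)
  gain <- with_seed(derive_seed(seed, "leadfield"), {
    u <- qr.Q(qr(matrix(rnorm(n_sensors * r), n_sensors, r)))
    v <- qr.Q(qr(matrix(rnorm(n_sources * r), n_sources, r)))
    s <- exp(seq(0, -log(conditioning), length.out = r))
    u %*% (s * t(v))
  })
  if (any(colSums(abs(gain)) == 0))
    stop("degenerate leadfield: all-zero column produced")  # astronomically unlikely
  if (is.null(sensor_names)) sensor_names <- std_channel_names(n_sensors)
  stopifnot(length(sensor_names) == n_sensors)
  structure(list(gain = gain, sensor_names = sensor_names,
                 source_ids = seq_len(n_sources)),
            class = "leadfield")
}

#' @export
print.leadfield <- function(x, ...) {
  cat(sprintf("<leadfield> %d sensors x %d sources\n",
              nrow(x$gain), ncol(x$gain)))
  invisible(x)
}

#' Fronto-central evoked topography weights
#'
#' Scalp weighting of the simulated evoked components: 1 over the
#' fronto-central midline, 0.6 over the remaining frontal/central rows,
#' 0.15 elsewhere, and 0 on mastoid/EOG channels.
#'
#' @param channel_names character vector of sensor labels.
#' @return numeric weights, one per channel.
#' @export
default_topography <- function(channel_names) {
  w <- rep(0.15, length(channel_names))
  core <- c("Fz", "FCz", "Cz", "F1", "F2", "FC1", "FC2", "C1", "C2")
  w[channel_names %in% core] <- 1
  row_fc <- grepl("^(F|FC|C)[0-9z]", channel_names) & !(channel_names %in% core)
  w[row_fc] <- 0.6
  w[channel_names %in% c("M1", "M2", "VEO")] <- 0
  w
}

#' Simulate a continuous sensor-space oddball recording
#'
#' The recording is `gain %*% source_background + evoked + sensor noise`.
#' Source background is white noise with sd `config$noise_sd` per source.
#' Every tone adds the `erp_spec$common` components; deviant tones in the
#' awake state additionally add `erp_spec$deviant_extra` (the MMN-generating
#' difference component), so deviant-minus-standard averages show a negative
#' deflection at fronto-central sensors.  In the anesthesia state no extra
#' deviant component is injected, mirroring the disappearance of the MMN
#' under deep sedation.  Components are applied with the
#' \code{\link{default_topography}} scalp weighting.
#'
#' @param config a \code{\link{sim_config}}.
#' @param events an `mmn_events` data.frame.
#' @param leadfield a \code{\link{make_leadfield}} object.
#' @param state `"awake"` or `"anesthesia"`.
#' @return an object of class `eeg_recording`: list with `data`
#'   (channels x samples, microvolt), `channel_names`, `sfreq`,
#'   `reference`.
#' @export
simulate_sensor_recording <- function(config, events, leadfield,
                                      state = c("awake", "anesthesia")) {
  validate_sim_config(config)
  state <- match.arg(state)
  stopifnot(inherits(leadfield, "leadfield"))
  fs <- config$sampling_rate_hz
  n_ch <- nrow(leadfield$gain)
  n_src <- ncol(leadfield$gain)
  n_samp <- ceiling((max(events$onset_ms) + config$epoch_window_ms[2] + 200) * fs / 1000)

  rec <- matrix(0, n_ch, n_samp)
  with_seed(derive_seed(config$seed, "sensor", state), {
    if (config$noise_sd > 0) {
      src <- matrix(rnorm(n_src * n_samp, sd = config$noise_sd), n_src, n_samp)
      rec <- leadfield$gain %*% src
    }
    if (config$sensor_noise_sd > 0)
      rec <- rec + matrix(rnorm(n_ch * n_samp, sd = config$sensor_noise_sd), n_ch, n_samp)
  })

  topo <- default_topography(leadfield$sensor_names)
  post_ms <- config$epoch_window_ms[2]
  tau <- seq(0, post_ms, by = 1000 / fs)  # ms post-onset grid of the bump
  for (e in seq_len(nrow(events))) {
    comps <- config$erp_spec$common
    if (events$condition[e] == "deviant" && state == "awake")
      comps <- rbind(comps, config$erp_spec$deviant_extra)
    if (is.null(comps) || !nrow(comps)) next
    bump <- rep(0, length(tau))
    for (k in seq_len(nrow(comps))) {
      s <- comps$width_ms[k] / 2.3548  # FWHM -> sd
      bump <- bump + comps$amplitude_uv[k] * exp(-0.5 * ((tau - comps$latency_ms[k]) / s)^2)
    }
    i0 <- round(events$onset_ms[e] * fs / 1000)  # 0-based onset sample
    idx <- (i0 + 1):min(i0 + length(tau), n_samp)
    rec[, idx] <- rec[, idx] + topo %o% bump[seq_along(idx)]
  }

  structure(list(data = rec, channel_names = leadfield$sensor_names,
                 sfreq = fs, reference = "simulated average reference"),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s), reference: %s\n",
              nrow(x$data), ncol(x$data), x$sfreq,
              ncol(x$data) / x$sfreq, x$reference))
  invisible(x)
}
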