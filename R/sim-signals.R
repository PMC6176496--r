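#' Simulate per-trial gamma-band ROI signals with known coupling ground truth
#'
#' Each trial (one row of `events`) yields one epoch of `n_rois` source-space
#' signals on the half-open window `config$epoch_window_ms`.  Every ROI
#' carries a gamma-band cosine with a trial-specific frequency and an
#' independent uniform starting phase, plus white noise.  The trial frequency
#' is drawn from the DFT-resolved frequencies (integer number of cycles per
#' epoch) inside `gamma_band_hz` and is shared by all ROIs of the trial, so
#' phase relations between ROIs are constant over the epoch and the analytic
#' signal of a noise-free trial is exact.
#'
#' For every coupling row active in the trial's condition the follower's
#' starting phase is set to driver phase + `phase_lag` + wrapped-normal
#' jitter with sd `(1 - strength * attenuation) * pi`, where the attenuation
#' is `config$anesthesia_attenuation` in the anesthesia state and 1 when
#' awake.  Coupling rows are applied in table order, so chains
#' (A drives B, B drives C) behave as written.  The random stream is
#' independent of `state` and of the trial labels, so with attenuation 1 the
#' awake and anesthesia outputs are bit-identical.
#'
#' @param config a \code{\link{sim_config}}.
#' @param events an `mmn_events` data.frame (possibly a subset of a full
#'   sequence); one trial is simulated per row.
#' @param state `"awake"` or `"anesthesia"`.
#' @return an object of class `roi_signals`: list with `data` (array
#'   trials x ROIs x samples), `sfreq`, `window_ms`, `condition` and `label`
#'   per trial, `state`, `roi_ids`, and `freq_hz` per trial.
#' @export
#' @examples
#' cfg <- sim_config(tones_per_block = 6, n_standard = 4, n_deviant_low = 1,
#'                   n_deviant_high = 1, n_rois = 4, seed = 2)
#' ev <- generate_event_sequence(cfg)
#' rs <- simulate_roi_signals(cfg, ev)
#' dim(rs$data)
simulate_roi_signals <- function(config, events, state = c("awake", "anesthesia")) {
  validate_sim_config(config)
  state <- match.arg(state)
  stopifnot(is.data.frame(events), nrow(events) >= 1L, !is.null(events$condition))
  spec <- config$coupling_spec
  atten <- if (state == "anesthesia") config$anesthesia_attenuation else 1
  fs <- config$sampling_rate_hz
  win <- config$epoch_window_ms
  n_samp <- round((win[2] - win[1]) * fs / 1000)
  tau <- (seq_len(n_samp) - 1) / fs
  n_roi <- config$n_rois
  n_tr <- nrow(events)

  fgrid <- epoch_bin_freqs(config$gamma_band_hz, fs, n_samp)
  data <- array(0, dim = c(n_tr, n_roi, n_samp))
  freqs <- numeric(n_tr)
  n_cpl <- if (is.null(spec)) 0L else nrow(spec)

  with_seed(derive_seed(config$seed, "roi_signals"), {
    for (t in seq_len(n_tr)) {
      f <- fgrid[sample.int(length(fgrid), 1L)]
      freqs[t] <- f
      phi <- runif(n_roi, -pi, pi)
      if (n_cpl) {
        z <- rnorm(n_cpl)
        active <- spec$condition == "both" | spec$condition == events$condition[t]
        for (r in which(active)) {
          s_eff <- spec$strength[r] * atten
          phi[spec$roi_j[r]] <- phi[spec$roi_i[r]] + spec$phase_lag[r] +
            (1 - s_eff) * pi * z[r]
        }
      }
      sig <- cos(outer(phi, 2 * pi * f * tau, "+"))
      if (config$noise_sd > 0)
        sig <- sig + config$noise_sd * matrix(rnorm(n_roi * n_samp), n_roi, n_samp)
      data[t, , ] <- sig
    }
  })

  structure(list(
    data = data, sfreq = fs, window_ms = win,
    condition = events$condition, label = events$label,
    state = state, roi_ids = seq_len(n_roi), freq_hz = freqs
  ), class = "roi_signals")
}

# Frequencies with an integer number of cycles per epoch that fall inside
# `band`; falls back to the band midpoint (with a warning) if the epoch is
# too short to resolve any.
epoch_bin_freqs <- function(band, fs, n_samp) {
  k <- seq_len(floor(n_samp / 2) - 1L)
  f <- k * fs / n_samp
  f <- f[f >= band[1] & f <= band[2]]
  if (!length(f)) {
    warning("epoch too short to resolve a bin frequency inside the band; ",
            "using the band midpoint")
    f <- mean(band)
  }
  f
}

#' Subset the trials of a `roi_signals` object
#'
#' @param x a `roi_signals` object.
#' @param idx integer or logical trial index.
#' @return a `roi_signals` object with the selected trials.
#' @export
subset_trials <- function(x, idx) {
  stopifnot(inherits(x, "roi_signals"))
  out <- x
  out$data <- x$data[idx, , , drop = FALSE]
  out$condition <- x$condition[idx]
  out$label <- x$label[idx]
  out$freq_hz <- x$freq_hz[idx]
  out
}

#' @export
print.roi_signals <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<roi_signals> %d trials x %d ROIs x %d samples @ %g Hz, window [%g, %g) ms, state %s\n",
              d[1], d[2], d[3], x$sfreq, x$window_ms[1], x$window_ms[2], x$state))
  print(table(x$condition))
  invisible(x)
}
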