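# Preprocessing: band-pass filtering, deviant selection, epoching, baseline
# correction, artifact rejection, evoked averages, the MMN difference wave
# and the peak-centered 100 ms analysis window.

epoch_times <- function(window_ms, fs, n_samp) {
  window_ms[1] + (seq_len(n_samp) - 1) * 1000 / fs
}

# Windowed-sinc band-pass kernel (Hamming, via r-signal), transition width
# 25% of the lower band edge; length capped below the signal length.
fir_bandpass_kernel <- function(low_hz, high_hz, fs, n_samp) {
  trans <- 0.25 * low_hz
  ntaps <- ceiling(3.3 * fs / trans)
  if (ntaps %% 2 == 0) ntaps <- ntaps + 1
  cap <- n_samp - 1 - (1 - (n_samp - 1) %% 2)  # largest odd < n_samp
  if (ntaps > cap) ntaps <- cap
  if (ntaps < 3) stop("signal too short to design a band-pass filter")
  signal::fir1(ntaps - 1, c(low_hz, high_hz) / (fs / 2), type = "pass")
}

# Zero-phase application of a symmetric FIR by FFT convolution with
# reflection padding and exact group-delay compensation.
# x: samples x channels matrix.
fir_filter_zerophase <- function(x, h) {
  n <- nrow(x)
  d <- (length(h) - 1) / 2
  stopifnot(d < n)
  xp <- rbind(x[(d + 1):2, , drop = FALSE], x, x[(n - 1):(n - d), , drop = FALSE])
  np <- nrow(xp)
  nfft <- stats::nextn(np + length(h) - 1)
  hf <- stats::fft(c(h, rep(0, nfft - length(h))))
  xf <- stats::mvfft(rbind(xp, matrix(0, nfft - np, ncol(x))))
  y <- Re(stats::mvfft(xf * hf, inverse = TRUE)) / nfft
  y[(2 * d + 1):(2 * d + n), , drop = FALSE]
}

#' Zero-phase band-pass filter a continuous recording
#'
#' Applies a linear-phase windowed-sinc (Hamming) band-pass per channel with
#' exact group-delay compensation, so the output has zero phase distortion --
#' a prerequisite for downstream phase-synchronization measures.  The
#' transition width is 25% of the lower band edge and the kernel is applied
#' by FFT convolution with reflection padding.
#'
#' @param recording an `eeg_recording`.
#' @param low_hz,high_hz band edges, `0 < low < high < fs/2`.
#' @return a filtered `eeg_recording` of the same length.
#' @export
#' @examples
#' cfg <- sim_config(tones_per_block = 4, n_standard = 2, n_deviant_low = 1,
#'                   n_deviant_high = 1, seed = 1)
#' lf <- make_leadfield(8, 12, conditioning = 3, seed = 1)
#' rec <- simulate_sensor_recording(cfg, generate_event_sequence(cfg), lf)
#' filt <- bandpass_filter(rec, 0.5, 40)
bandpass_filter <- function(recording, low_hz, high_hz) {
  stopifnot(inherits(recording, "eeg_recording"))
  fs <- recording$sfreq
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < fs / 2))
    stop(sprintf("invalid band edges: need 0 < %g < %g < Nyquist (%g)",
                 low_hz, high_hz, fs / 2))
  h <- fir_bandpass_kernel(low_hz, high_hz, fs, ncol(recording$data))
  recording$data <- t(fir_filter_zerophase(t(recording$data), h))
  recording$band_hz <- c(low_hz, high_hz)
  recording
}

#' Re-reference a recording to the mastoid average
#'
#' If channels `M1` and `M2` are present, subtracts their average from every
#' channel; otherwise the data are assumed pre-referenced and returned
#' unchanged.
#'
#' @param recording an `eeg_recording`.
#' @return an `eeg_recording`.
#' @export
rereference_mastoids <- function(recording) {
  stopifnot(inherits(recording, "eeg_recording"))
  idx <- match(c("M1", "M2"), recording$channel_names)
  if (anyNA(idx)) return(recording)
  ref <- colMeans(recording$data[idx, , drop = FALSE])
  recording$data <- sweep(recording$data, 2, ref)
  recording$reference <- "linked mastoids"
  recording
}

#' Select deviants preceded by a run of standards
#'
#' Keeps only deviant events whose `min_preceding_standards` immediately
#' preceding events (within the same block) are all standard tones, the
#' usual guard against deviants in the wake of another deviant.
#'
#' @param events an `mmn_events` data.frame ordered by onset.
#' @param min_preceding_standards required run length (default 3).
#' @return the retained deviant events (possibly zero rows).
#' @export
#' @examples
#' ev <- data.frame(onset_ms = 1:4 * 1000,
#'                  label = c("standard", "standard", "standard", "deviant_low"),
#'                  condition = c("standard", "standard", "standard", "deviant"),
#'                  block = 1L)
#' nrow(select_valid_deviants(ev))  # 1
select_valid_deviants <- function(events, min_preceding_standards = 3L) {
  stopifnot(is.data.frame(events), !is.unsorted(events$onset_ms))
  m <- as.integer(min_preceding_standards)
  keep <- vapply(seq_len(nrow(events)), function(i) {
    if (events$condition[i] != "deviant") return(FALSE)
    if (i <= m) return(FALSE)
    prev <- (i - m):(i - 1)
    all(events$condition[prev] == "standard") &&
      all(events$block[prev] == events$block[i])
  }, logical(1))
  out <- events[keep, , drop = FALSE]
  class(out) <- class(events)
  out
}

#' Standards immediately preceding a set of valid deviants
#'
#' Returns, for each row of `deviants`, the event immediately preceding it
#' in `events` (a standard by construction when `deviants` came from
#' \code{\link{select_valid_deviants}}).  Used to build condition groups
#' with equal trial counts, which the wPLI estimator requires for unbiased
#' condition contrasts.
#'
#' @param events the full `mmn_events` sequence.
#' @param deviants a subset of deviant rows of `events`.
#' @return the matched standard events.
#' @export
matched_standards <- function(events, deviants) {
  pos <- match(deviants$onset_ms, events$onset_ms)
  if (anyNA(pos) || any(pos <= 1L)) stop("deviants not found in event sequence")
  out <- events[pos - 1L, , drop = FALSE]
  if (any(out$condition != "standard"))
    stop("event preceding a selected deviant is not a standard")
  class(out) <- class(events)
  out
}

#' Extract condition-labeled epochs around stimulus onsets
#'
#' Cuts one epoch per event on the half-open window `window_ms` (`t = 0` at
#' stimulus onset; at 1 kHz the default `[-100, 700)` window has 800
#' samples).  Events whose window would underrun or overrun the recording
#' are skipped and logged.
#'
#' @param recording an `eeg_recording`.
#' @param events an `mmn_events` data.frame.
#' @param window_ms half-open epoch window in ms relative to onset.
#' @param baseline_ms baseline window stored for \code{\link{baseline_correct}}.
#' @return an object of class `eeg_epochs`: list with `data` (trials x
#'   channels x samples), `channel_names`, `sfreq`, `window_ms`,
#'   `baseline_ms`, `condition`/`label`/`onset_ms` per trial and a
#'   `rejected_log` data.frame.
#' @export
extract_epochs <- function(recording, events, window_ms = c(-100, 700),
                           baseline_ms = c(-100, 0)) {
  stopifnot(inherits(recording, "eeg_recording"), is.data.frame(events))
  fs <- recording$sfreq
  n_rec <- ncol(recording$data)
  n_samp <- round((window_ms[2] - window_ms[1]) * fs / 1000)
  start0 <- round(events$onset_ms * fs / 1000) + round(window_ms[1] * fs / 1000)
  usable <- start0 >= 0 & (start0 + n_samp) <= n_rec
  log <- data.frame(
    event = which(!usable),
    onset_ms = events$onset_ms[!usable],
    reason = rep("epoch window outside recording", sum(!usable)),
    stringsAsFactors = FALSE
  )
  if (!any(usable)) stop("no usable events: every epoch window falls outside the recording")
  keep <- which(usable)
  data <- array(0, dim = c(length(keep), nrow(recording$data), n_samp))
  for (k in seq_along(keep)) {
    i0 <- start0[keep[k]]
    data[k, , ] <- recording$data[, (i0 + 1):(i0 + n_samp)]
  }
  structure(list(
    data = data, channel_names = recording$channel_names, sfreq = fs,
    window_ms = window_ms, baseline_ms = baseline_ms,
    condition = events$condition[keep], label = events$label[keep],
    onset_ms = events$onset_ms[keep], rejected_log = log
  ), class = "eeg_epochs")
}

#' Baseline-correct epochs
#'
#' Subtracts, per trial and channel, the mean over the baseline window
#' (default the first 100 ms of the epoch, `[-100, 0)` ms), so the baseline
#' mean of the output is 0 to numerical precision.  Idempotent.
#'
#' @param epochs an `eeg_epochs` object.
#' @param baseline_ms baseline window; defaults to the window stored in
#'   `epochs`.
#' @return the corrected `eeg_epochs`.
#' @export
baseline_correct <- function(epochs, baseline_ms = epochs$baseline_ms) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  tt <- epoch_times(epochs$window_ms, epochs$sfreq, dim(epochs$data)[3])
  idx <- which(tt >= baseline_ms[1] & tt < baseline_ms[2])
  if (!length(idx)) stop("baseline window contains no samples")
  mu <- apply(epochs$data[, , idx, drop = FALSE], c(1, 2), mean)
  epochs$data <- epochs$data - array(mu, dim = dim(epochs$data))
  epochs$baseline_ms <- baseline_ms
  epochs
}

#' Reject trials with excessive peak-to-peak amplitude
#'
#' Automated stand-in for manual artifact screening: removes every trial in
#' which any channel's peak-to-peak amplitude exceeds `peak_to_peak_uv`,
#' logging the trial and the first offending channel.
#'
#' @param epochs an `eeg_epochs` object.
#' @param peak_to_peak_uv rejection threshold in microvolt (default 100).
#' @return the cleaned `eeg_epochs`; errors if every trial is rejected.
#' @export
reject_artifacts <- function(epochs, peak_to_peak_uv = 100) {
  stopifnot(inherits(epochs, "eeg_epochs"), peak_to_peak_uv > 0)
  ptp <- apply(epochs$data, c(1, 2), function(v) max(v) - min(v))
  bad_trial <- apply(ptp, 1, function(p) any(p > peak_to_peak_uv))
  if (all(bad_trial)) stop("artifact rejection removed every trial (threshold ",
                           peak_to_peak_uv, " uV)")
  if (any(bad_trial)) {
    ch <- apply(ptp[bad_trial, , drop = FALSE], 1, function(p) which(p > peak_to_peak_uv)[1])
    epochs$rejected_log <- rbind(
      epochs$rejected_log,
      data.frame(event = which(bad_trial),
                 onset_ms = epochs$onset_ms[bad_trial],
                 reason = sprintf("peak-to-peak %.1f uV > %g uV on %s",
                                  ptp[cbind(which(bad_trial), ch)],
                                  peak_to_peak_uv, epochs$channel_names[ch]),
                 stringsAsFactors = FALSE)
    )
  }
  keep <- !bad_trial
  epochs$data <- epochs$data[keep, , , drop = FALSE]
  epochs$condition <- epochs$condition[keep]
  epochs$label <- epochs$label[keep]
  epochs$onset_ms <- epochs$onset_ms[keep]
  epochs
}

#' Average epochs of one condition into an evoked waveform
#'
#' @param epochs an `eeg_epochs` object.
#' @param condition condition to average (`"standard"` or `"deviant"`), or
#'   `NULL` to average all trials.
#' @return an object of class `eeg_evoked`: channels x samples mean with
#'   grid metadata and `n_trials`.
#' @export
average_evoked <- function(epochs, condition = NULL) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  idx <- if (is.null(condition)) seq_along(epochs$condition) else which(epochs$condition == condition)
  if (!length(idx)) stop("no trials with condition '", condition, "'")
  m <- apply(epochs$data[idx, , , drop = FALSE], c(2, 3), mean)
  structure(list(data = m, channel_names = epochs$channel_names,
                 sfreq = epochs$sfreq, window_ms = epochs$window_ms,
                 condition = if (is.null(condition)) "all" else condition,
                 n_trials = length(idx)),
            class = "eeg_evoked")
}

#' Mismatch negativity difference wave
#'
#' `deviant - standard`, pointwise on a common grid.
#'
#' @param deviant,standard `eeg_evoked` waveforms on identical grids.
#' @return an `eeg_evoked` with `condition = "difference"`.
#' @export
compute_mmn <- function(deviant, standard) {
  stopifnot(inherits(deviant, "eeg_evoked"), inherits(standard, "eeg_evoked"))
  if (!identical(dim(deviant$data), dim(standard$data)) ||
      !identical(deviant$window_ms, standard$window_ms) ||
      deviant$sfreq != standard$sfreq ||
      !identical(deviant$channel_names, standard$channel_names))
    stop("deviant and standard evoked waveforms are on different grids")
  out <- deviant
  out$data <- deviant$data - standard$data
  out$condition <- "difference"
  out$n_trials <- min(deviant$n_trials, standard$n_trials)
  out
}

#' Locate the MMN peak and build the 100 ms analysis window
#'
#' The peak is the time of the most negative value of the difference wave on
#' `channel` within `search_window_ms` (earliest sample on ties); the
#' analysis window is the 100 ms half-open interval centered there,
#' `[peak - 50, peak + 50)`.  Errors if that window would exceed the epoch
#' bounds.
#'
#' @param mmn an `eeg_evoked` difference wave.
#' @param channel detection channel (default `"Fz"`).
#' @param search_window_ms peak search interval in ms post-onset.
#' @return an object of class `mmn_window`: list with `peak_ms`,
#'   `window_ms = c(peak - 50, peak + 50)` and `channel`.
#' @export
find_mmn_peak <- function(mmn, channel = "Fz", search_window_ms = c(100, 250)) {
  stopifnot(inherits(mmn, "eeg_evoked"))
  ci <- match(channel, mmn$channel_names)
  if (is.na(ci)) stop("channel '", channel, "' not found")
  tt <- epoch_times(mmn$window_ms, mmn$sfreq, ncol(mmn$data))
  if (search_window_ms[1] < tt[1] || search_window_ms[2] > tt[length(tt)])
    stop("search window exceeds epoch bounds")
  idx <- which(tt >= search_window_ms[1] & tt <= search_window_ms[2])
  peak_ms <- tt[idx[which.min(mmn$data[ci, idx])]]
  win <- c(peak_ms - 50, peak_ms + 50)
  if (win[1] < mmn$window_ms[1] || win[2] > mmn$window_ms[2])
    stop(sprintf("100 ms window [%g, %g) around the peak exceeds the epoch bounds [%g, %g)",
                 win[1], win[2], mmn$window_ms[1], mmn$window_ms[2]))
  structure(list(peak_ms = peak_ms, window_ms = win, channel = channel),
            class = "mmn_window")
}

#' @export
print.mmn_window <- function(x, ...) {
  cat(sprintf("<mmn_window> peak %g ms at %s, window [%g, %g) ms\n",
              x$peak_ms, x$channel, x$window_ms[1], x$window_ms[2]))
  invisible(x)
}

#' Decide whether a subject shows an MMN waveform
#'
#' A subject is considered MMN-positive when the most negative value of the
#' difference wave inside the analysis window reaches the amplitude
#' criterion and the window mean is negative.  Subjects failing the test are
#' excluded from group analysis by \code{\link{run_pipeline}}.
#'
#' @param mmn an `eeg_evoked` difference wave.
#' @param window an `mmn_window`.
#' @param amplitude_criterion_uv trough criterion in microvolt (default -0.5).
#' @return `TRUE` or `FALSE`.
#' @export
assess_mmn_presence <- function(mmn, window, amplitude_criterion_uv = -0.5) {
  stopifnot(inherits(mmn, "eeg_evoked"), inherits(window, "mmn_window"))
  ci <- match(window$channel, mmn$channel_names)
  if (is.na(ci)) stop("channel '", window$channel, "' not found")
  tt <- epoch_times(mmn$window_ms, mmn$sfreq, ncol(mmn$data))
  idx <- which(tt >= window$window_ms[1] & tt < window$window_ms[2])
  seg <- mmn$data[ci, idx]
  min(seg) <= amplitude_criterion_uv && mean(seg) < 0
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<eeg_epochs> %d trials x %d channels x %d samples @ %g Hz, window [%g, %g) ms\n",
              d[1], d[2], d[3], x$sfreq, x$window_ms[1], x$window_ms[2]))
  print(table(x$condition))
  if (nrow(x$rejected_log)) cat(sprintf("  %d trial(s) dropped (see $rejected_log)\n",
                                        nrow(x$rejected_log)))
  invisible(x)
}

#' @export
print.eeg_evoked <- function(x, ...) {
  cat(sprintf("<eeg_evoked> '%s': %d channels x %d samples, average of %d trials\n",
              x$condition, nrow(x$data), ncol(x$data), x$n_trials))
  invisible(x)
}

#' Butterfly plot of an evoked waveform
#'
#' @param x an `eeg_evoked`.
#' @param channel optional single channel to highlight.
#' @param ... passed to \code{\link[graphics]{matplot}}.
#' @return `x`, invisibly.
#' @export
plot.eeg_evoked <- function(x, channel = NULL, ...) {
  tt <- epoch_times(x$window_ms, x$sfreq, ncol(x$data))
  graphics::matplot(tt, t(x$data), type = "l", lty = 1, col = "grey60",
                    xlab = "time (ms)", ylab = "amplitude (uV)",
                    main = paste0("evoked: ", x$condition), ...)
  graphics::abline(v = 0, lty = 2)
  if (!is.null(channel)) {
    ci <- match(channel, x$channel_names)
    if (!is.na(ci)) graphics::lines(tt, x$data[ci, ], col = "red", lwd = 2)
  }
  invisible(x)
}
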