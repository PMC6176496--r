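# Instantaneous phase via the analytic signal and the weighted phase lag
# index (wPLI).

# FFT analytic signal of each column of `x` (samples x signals).
analytic_signal <- function(x) {
  n <- nrow(x)
  h <- rep(0, n)
  h[1] <- 1
  if (n %% 2 == 0) {
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[2:((n + 1) / 2)] <- 2
  }
  stats::mvfft(stats::mvfft(x) * h, inverse = TRUE) / n
}

window_sample_idx <- function(window_ms, epoch_window_ms, fs, n_samp) {
  tt <- epoch_times(epoch_window_ms, fs, n_samp)
  idx <- which(tt >= window_ms[1] & tt < window_ms[2])
  if (!length(idx)) stop("analysis window contains no samples")
  if (window_ms[1] < tt[1] - 1e-9 || window_ms[2] > epoch_window_ms[2] + 1e-9)
    stop("analysis window lies outside the epoch")
  idx
}

#' Instantaneous phase of ROI signals over the analysis window
#'
#' Computes the analytic signal (FFT Hilbert transform) of every trial and
#' ROI over the \emph{full} epoch -- so window edges are free of transform
#' edge artifacts -- and then crops the phase `atan2(imag, real)` to the
#' analysis window.  Phases lie in `(-pi, pi]`.
#'
#' @param roi_signals a `roi_signals` object (band-limited upstream).
#' @param window an `mmn_window`, or a two-element numeric window in ms.
#' @return an object of class `phase_tensor`: list with `phases` (trials x
#'   ROIs x window samples), `window_ms`, `sfreq`, `condition`, `state`.
#' @export
#' @examples
#' cfg <- sim_config(tones_per_block = 4, n_standard = 2, n_deviant_low = 1,
#'                   n_deviant_high = 1, n_rois = 3, noise_sd = 0, seed = 3)
#' rs <- simulate_roi_signals(cfg, generate_event_sequence(cfg))
#' ph <- instantaneous_phase(rs, c(110, 210))
#' range(ph$phases)
instantaneous_phase <- function(roi_signals, window) {
  stopifnot(inherits(roi_signals, "roi_signals"))
  win_ms <- if (inherits(window, "mmn_window")) window$window_ms else window
  d <- dim(roi_signals$data)
  idx <- window_sample_idx(win_ms, roi_signals$window_ms, roi_signals$sfreq, d[3])
  # flatten trials*ROIs into columns for one batched FFT
  flat <- matrix(aperm(roi_signals$data, c(3, 2, 1)), nrow = d[3])
  zero <- which(apply(flat, 2, function(v) max(abs(v))) == 0)
  if (length(zero)) {
    tr <- ceiling(zero[1] / d[2])
    roi <- zero[1] - (tr - 1) * d[2]
    stop(sprintf("phase undefined: all-zero signal in trial %d, ROI %d", tr, roi))
  }
  a <- analytic_signal(flat)
  ph <- atan2(Im(a), Re(a))
  phases <- aperm(array(ph[idx, ], dim = c(length(idx), d[2], d[1])), c(3, 2, 1))
  structure(list(phases = phases, window_ms = win_ms, sfreq = roi_signals$sfreq,
                 condition = roi_signals$condition, state = roi_signals$state,
                 roi_ids = roi_signals$roi_ids),
            class = "phase_tensor")
}

#' Weighted phase lag index of one ROI pair
#'
#' With `d = phases_i - phases_j` over all window samples of all trials,
#' the default (`method = "pooled"`) estimator is
#' `|mean(sin(d))| / mean(|sin(d)|)`: the magnitude-weighted average sign of
#' the phase difference, pooled over trials and samples.  It equals 1 when
#' one signal leads (or lags) the other by a constant nonzero phase in
#' every trial and tends to 0 when the phase differences are completely
#' random across trials; exact zero-lag differences carry no weight, which
#' is what makes the index insensitive to volume conduction.  When the
#' denominator is exactly 0 (all `sin(d)` zero, the pure zero-lag case) the
#' result is defined as 0.
#'
#' `method = "trial"` computes the same ratio within each trial (rows of
#' the inputs) and averages the per-trial values; note that this variant
#' cannot detect cross-trial phase randomness when the lag is constant
#' within trials.
#'
#' @param phases_i,phases_j numeric vectors (one trial) or trials x samples
#'   matrices of instantaneous phases in radians.
#' @param method `"pooled"` (default) or `"trial"`.
#' @return a scalar in `[0, 1]`.
#' @export
#' @examples
#' ph <- matrix(runif(200, -pi, pi), 20, 10)
#' wpli(ph, ph - pi / 4)  # constant lag -> 1
wpli <- function(phases_i, phases_j, method = c("pooled", "trial")) {
  method <- match.arg(method)
  pi_m <- if (is.matrix(phases_i)) phases_i else matrix(phases_i, nrow = 1)
  pj_m <- if (is.matrix(phases_j)) phases_j else matrix(phases_j, nrow = 1)
  if (!identical(dim(pi_m), dim(pj_m)))
    stop("phases_i and phases_j have different dimensions")
  s <- sin(pi_m - pj_m)
  if (method == "pooled") {
    den <- sum(abs(s))
    if (den == 0) return(0)
    return(abs(sum(s)) / den)
  }
  r <- apply(s, 1, function(v) {
    den <- sum(abs(v))
    if (den == 0) 0 else abs(sum(v)) / den
  })
  mean(r)
}

#' wPLI connectivity matrix over all ROI pairs
#'
#' Computes \code{\link{wpli}} for every unordered ROI pair of a phase
#' tensor (or of `roi_signals`, from which phases are first extracted over
#' `window`).  The heavy pair loop of the pooled estimator runs in compiled
#' code.
#'
#' @param x a `roi_signals` or `phase_tensor` object.
#' @param window analysis window (required when `x` is `roi_signals`).
#' @param method see \code{\link{wpli}}.
#' @return an object of class `wpli_matrix`: list with `w` (symmetric
#'   ROIs x ROIs matrix in `[0, 1]`, zero diagonal), `n_trials`, `state`,
#'   `condition` (unique trial conditions), `method`.
#' @export
connectivity_matrix <- function(x, window = NULL, method = c("pooled", "trial")) {
  method <- match.arg(method)
  ph <- if (inherits(x, "phase_tensor")) x else {
    if (is.null(window)) stop("window is required when passing roi_signals")
    instantaneous_phase(x, window)
  }
  d <- dim(ph$phases)
  if (d[2] < 2) stop("need at least 2 ROIs")
  if (method == "pooled") {
    # rows = trial*sample observations, cols = ROIs
    flat <- matrix(aperm(ph$phases, c(3, 1, 2)), ncol = d[2])
    sums <- wpli_pair_sums(sin(flat), cos(flat))
    w <- ifelse(sums$den > 0, sums$num / sums$den, 0)
  } else {
    w <- matrix(0, d[2], d[2])
    for (i in seq_len(d[2] - 1)) {
      for (j in (i + 1):d[2]) {
        w[i, j] <- w[j, i] <- wpli(ph$phases[, i, ], ph$phases[, j, ], method = "trial")
      }
    }
  }
  diag(w) <- 0
  dimnames(w) <- list(ph$roi_ids, ph$roi_ids)
  structure(list(w = w, n_trials = d[1], state = ph$state,
                 condition = paste(unique(ph$condition), collapse = "+"),
                 window_ms = ph$window_ms, method = method),
            class = "wpli_matrix")
}

#' @export
print.wpli_matrix <- function(x, ...) {
  cat(sprintf("<wpli_matrix> %d x %d (%s), %d trials, state %s, condition %s\n",
              nrow(x$w), ncol(x$w), x$method, x$n_trials, x$state, x$condition))
  off <- x$w[upper.tri(x$w)]
  cat(sprintf("  wPLI: min %.3f, median %.3f, max %.3f\n",
              min(off), stats::median(off), max(off)))
  invisible(x)
}
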