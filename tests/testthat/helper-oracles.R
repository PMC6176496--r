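# Independent brute-force oracles and small fixture builders.

# Pooled wPLI by explicit double loop over trials and samples.
wpli_oracle <- function(ph_i, ph_j) {
  ph_i <- rbind(ph_i)
  ph_j <- rbind(ph_j)
  num <- 0
  den <- 0
  for (t in seq_len(nrow(ph_i))) {
    for (k in seq_len(ncol(ph_i))) {
      v <- sin(ph_i[t, k] - ph_j[t, k])
      num <- num + v
      den <- den + abs(v)
    }
  }
  if (den == 0) 0 else abs(num) / den
}

# Within-trial wPLI averaged across trials, by explicit loop.
wpli_oracle_trial <- function(ph_i, ph_j) {
  ph_i <- rbind(ph_i)
  ph_j <- rbind(ph_j)
  r <- numeric(nrow(ph_i))
  for (t in seq_len(nrow(ph_i))) {
    num <- 0
    den <- 0
    for (k in seq_len(ncol(ph_i))) {
      v <- sin(ph_i[t, k] - ph_j[t, k])
      num <- num + v
      den <- den + abs(v)
    }
    r[t] <- if (den == 0) 0 else abs(num) / den
  }
  mean(r)
}

# Exhaustive long/short classification of a thresholded graph.
metrics_oracle <- function(w, density, partition) {
  n <- nrow(w)
  ed <- NULL
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    ed <- rbind(ed, data.frame(i = i, j = j, w = w[i, j]))
  ed <- ed[order(-ed$w, ed$i, ed$j), ]
  m <- floor(density * n * (n - 1) / 2 + 0.5)
  ed <- ed[seq_len(m), , drop = FALSE]
  areas <- sort(unique(partition$area))
  a_of <- partition$area[match(seq_len(n), partition$roi_id)]
  S_k <- stats::setNames(numeric(length(areas)), areas)
  L_k <- stats::setNames(numeric(length(areas)), areas)
  for (r in seq_len(nrow(ed))) {
    ai <- a_of[ed$i[r]]
    aj <- a_of[ed$j[r]]
    if (ai == aj) {
      S_k[ai] <- S_k[ai] + ed$w[r]
    } else {
      L_k[ai] <- L_k[ai] + ed$w[r]
      L_k[aj] <- L_k[aj] + ed$w[r]
    }
  }
  list(S_k = S_k, L_k = L_k, S_all = sum(S_k), L_all = sum(L_k),
       total = sum(ed$w))
}

# Small partition: 14 areas x n_per_area ROIs.
make_test_partition <- function(n_per_area = 4L) {
  areas <- c(paste0("L", c("VPF", "DPF", "C", "T", "P", "O", "Cing")),
             paste0("R", c("VPF", "DPF", "C", "T", "P", "O", "Cing")))
  df <- data.frame(
    roi_id = seq_len(14L * n_per_area),
    roi_name = sprintf("roi%03d", seq_len(14L * n_per_area)),
    area = rep(areas, each = n_per_area),
    stringsAsFactors = FALSE
  )
  class(df) <- c("area_partition", "data.frame")
  df
}

# Two-ROI sinusoidal roi_signals with a prescribed per-trial phase
# difference (constant within trial); 35 Hz carrier, 1 kHz sampling,
# epoch [-100, 300) ms.
make_lagged_signals <- function(dphi, seed = 1, freq = 35, fs = 1000,
                                window_ms = c(-100, 300)) {
  n_tr <- length(dphi)
  n <- round((window_ms[2] - window_ms[1]) * fs / 1000)
  tau <- (0:(n - 1)) / fs
  arr <- array(0, c(n_tr, 2, n))
  set.seed(seed)
  for (t in seq_len(n_tr)) {
    th <- runif(1, -pi, pi)
    arr[t, 1, ] <- cos(2 * pi * freq * tau + th)
    arr[t, 2, ] <- cos(2 * pi * freq * tau + th - dphi[t])
  }
  structure(list(data = arr, sfreq = fs, window_ms = window_ms,
                 condition = rep("standard", n_tr),
                 label = rep("standard", n_tr),
                 state = "awake", roi_ids = 1:2, freq_hz = rep(freq, n_tr)),
            class = "roi_signals")
}

# Random symmetric wPLI-like matrix with zero diagonal.
random_wpli_matrix <- function(n, seed = 1) {
  set.seed(seed)
  w <- matrix(0, n, n)
  w[upper.tri(w)] <- runif(n * (n - 1) / 2)
  w <- w + t(w)
  w
}

tiny_config <- function(..., n_rois = 4L) {
  sim_config(tones_per_block = 10L, n_standard = 6L, n_deviant_low = 2L,
             n_deviant_high = 2L, n_rois = n_rois, ...)
}

unwrap_phase <- function(p) {
  d <- diff(p)
  cumsum(c(p[1], atan2(sin(d), cos(d))))
}
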