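test_that("instantaneous phase matches analytic-signal identities", {
  fs <- 1000
  tau <- (0:799) / fs
  arr <- array(0, c(1, 2, 800))
  arr[1, 1, ] <- cos(2 * pi * 35 * tau)
  arr[1, 2, ] <- sin(2 * pi * 35 * tau)
  rs <- structure(list(data = arr, sfreq = fs, window_ms = c(-100, 700),
                       condition = "standard", label = "standard",
                       state = "awake", roi_ids = 1:2, freq_hz = 35),
                  class = "roi_signals")
  ph <- instantaneous_phase(rs, c(100, 300))
  expect_true(all(ph$phases > -pi - 1e-12 & ph$phases <= pi + 1e-12))
  # phase advances linearly at 2*pi*35 rad/s
  slope <- diff(unwrap_phase(ph$phases[1, 1, ]))
  expect_equal(mean(slope), 2 * pi * 35 / fs, tolerance = 1e-6)
  # phase(sin) - phase(cos) = -pi/2 everywhere
  d <- ph$phases[1, 2, ] - ph$phases[1, 1, ]
  d <- atan2(sin(d), cos(d))
  expect_equal(max(abs(d + pi / 2)), 0, tolerance = 1e-9)
  # an all-zero trial has no phase
  arr0 <- arr
  arr0[1, 2, ] <- 0
  rs0 <- rs
  rs0$data <- arr0
  expect_error(instantaneous_phase(rs0, c(100, 300)), "trial 1, ROI 2")
})

test_that("wPLI hits its boundary values", {
  ph <- matrix(runif(50 * 100, -pi, pi), 50, 100)
  # constant nonzero lag in every trial -> exactly 1
  expect_equal(wpli(ph, ph - pi / 4), 1)
  # identically zero phase difference (volume conduction) -> 0 by convention
  expect_equal(wpli(ph, ph), 0)
  # one trial alternating +pi/2 / -pi/2 -> |0| / 1 = 0
  d <- rep(c(pi / 2, -pi / 2), 10)
  expect_equal(wpli(d, rep(0, 20)), 0)
  expect_error(wpli(ph, ph[, 1:10]), "different dimensions")
})

test_that("wPLI is invariant to common phase offsets, amplitude, and pair order", {
  set.seed(51)
  for (rep in 1:5) {
    ph_i <- matrix(runif(20 * 50, -pi, pi), 20, 50)
    ph_j <- ph_i - matrix(rnorm(20, 1, 0.5), 20, 50)
    base <- wpli(ph_i, ph_j)
    expect_gte(base, 0)
    expect_lte(base, 1)
    off <- runif(1, -3, 3)
    expect_equal(wpli(ph_i + off, ph_j + off), base, tolerance = 1e-12)
    expect_equal(wpli(ph_j, ph_i), base, tolerance = 1e-12)
  }
  # amplitude scaling of the signals leaves the phases, hence wPLI, unchanged
  rs <- make_lagged_signals(runif(10, -pi, pi), seed = 52)
  rs3 <- rs
  rs3$data <- 3.7 * rs$data
  p1 <- instantaneous_phase(rs, c(110, 210))
  p2 <- instantaneous_phase(rs3, c(110, 210))
  expect_equal(wpli(p1$phases[, 1, ], p1$phases[, 2, ]),
               wpli(p2$phases[, 1, ], p2$phases[, 2, ]), tolerance = 1e-9)
})

test_that("vectorized wPLI agrees with the brute-force loop oracle", {
  set.seed(53)
  for (rep in 1:10) {
    ph_i <- matrix(runif(30, -pi, pi), 3, 10)
    ph_j <- matrix(runif(30, -pi, pi), 3, 10)
    expect_equal(wpli(ph_i, ph_j), wpli_oracle(ph_i, ph_j), tolerance = 1e-12)
    expect_equal(wpli(ph_i, ph_j, method = "trial"),
                 wpli_oracle_trial(ph_i, ph_j), tolerance = 1e-12)
  }
})

test_that("the connectivity matrix is symmetric, bounded, and matches scalar calls", {
  rs <- make_lagged_signals(runif(12, -pi, pi), seed = 54)
  arr <- array(rnorm(12 * 5 * 400, sd = 0.2), c(12, 5, 400))
  tau <- (0:399) / 1000
  for (t in 1:12) for (r in 1:5)
    arr[t, r, ] <- arr[t, r, ] + cos(2 * pi * 35 * tau + runif(1, -pi, pi))
  rs$data <- arr
  rs$roi_ids <- 1:5
  ph <- instantaneous_phase(rs, c(110, 210))
  cm <- connectivity_matrix(ph)
  expect_equal(cm$w, t(cm$w))
  expect_true(all(diag(cm$w) == 0))
  expect_true(all(cm$w >= 0 & cm$w <= 1))
  for (i in 1:4) for (j in (i + 1):5)
    expect_equal(cm$w[i, j], wpli(ph$phases[, i, ], ph$phases[, j, ]),
                 tolerance = 1e-12)
  # the compiled kernel agrees with the loop oracle entry by entry
  for (i in 1:4) for (j in (i + 1):5)
    expect_equal(cm$w[i, j], wpli_oracle(ph$phases[, i, ], ph$phases[, j, ]),
                 tolerance = 1e-12)
  cmt <- connectivity_matrix(ph, method = "trial")
  expect_equal(cmt$w[1, 2], wpli_oracle_trial(ph$phases[, 1, ], ph$phases[, 2, ]),
               tolerance = 1e-12)
})

test_that("a planted coupling ranks among the strongest matrix entries", {
  spec <- data.frame(roi_i = 5, roi_j = 12, phase_lag = pi / 4,
                     strength = 0.95, condition = "both")
  cfg <- sim_config(tones_per_block = 100L, n_standard = 100L,
                    n_deviant_low = 0L, n_deviant_high = 0L,
                    n_rois = 20L, epoch_window_ms = c(-100, 300),
                    coupling_spec = spec, noise_sd = 0.3, seed = 55)
  ev <- generate_event_sequence(cfg)
  cm <- connectivity_matrix(simulate_roi_signals(cfg, ev), c(110, 210))
  expect_gt(cm$w[5, 12], 0.8)
  off <- cm$w[upper.tri(cm$w)]
  expect_gte(cm$w[5, 12], stats::quantile(off, 0.99))
})

test_that("i.i.d. uniform phase differences drive wPLI to zero at large n", {
  set.seed(56)
  n <- 5000
  ph_i <- matrix(0, n, 100)
  ph_j <- ph_i - matrix(runif(n, -pi, pi), n, 100)
  expect_lt(wpli(ph_i, ph_j), 0.05)
})
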