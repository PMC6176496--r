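make_rec <- function(data, fs = 1000, names = NULL) {
  if (is.null(names)) names <- sprintf("ch%02d", seq_len(nrow(data)))
  structure(list(data = data, channel_names = names, sfreq = fs,
                 reference = "test"), class = "eeg_recording")
}

test_that("band-pass filter preserves in-band amplitude, removes DC, and is zero-phase", {
  fs <- 1000
  tau <- (0:4999) / fs
  x <- sin(2 * pi * 35 * tau)
  rec <- make_rec(rbind(x))
  filt <- bandpass_filter(rec, 30, 40)
  core <- 1000:4000
  expect_equal(sqrt(mean(filt$data[1, core]^2)), sqrt(mean(x[core]^2)),
               tolerance = 0.05)

  dc <- make_rec(rbind(rep(7, 5000)))
  out <- bandpass_filter(dc, 0.5, 40)
  expect_lt(max(abs(out$data[1, 1000:4000])), 0.05 * 7)

  # symmetric impulse response: a pulse keeps its peak latency
  pulse <- rep(0, 4000)
  pulse[2000] <- 1
  pf <- bandpass_filter(make_rec(rbind(pulse)), 1, 40)
  expect_equal(which.max(pf$data[1, ]), 2000)

  expect_error(bandpass_filter(rec, 40, 30), "invalid band")
  expect_error(bandpass_filter(rec, 30, 600), "invalid band")
})

test_that("valid-deviant selection requires a preceding run of standards", {
  mk <- function(labels) {
    data.frame(onset_ms = seq_along(labels) * 1075,
               label = ifelse(labels == "S", "standard", "deviant_low"),
               condition = ifelse(labels == "S", "standard", "deviant"),
               block = 1L, stringsAsFactors = FALSE)
  }
  expect_equal(nrow(select_valid_deviants(mk(c("S", "S", "S", "D")))), 1)
  expect_equal(nrow(select_valid_deviants(mk(c("S", "S", "D")))), 0)
  ev <- mk(c("S", "S", "S", "D", "D", "S", "S", "S", "D"))
  vd <- select_valid_deviants(ev)
  expect_equal(vd$onset_ms, ev$onset_ms[c(4, 9)])
  # runs must not span block boundaries
  ev2 <- mk(c("S", "S", "S", "D"))
  ev2$block <- c(1L, 1L, 2L, 2L)
  expect_equal(nrow(select_valid_deviants(ev2)), 0)
  # matched standards are the immediately preceding events
  ms <- matched_standards(ev, vd)
  expect_equal(ms$onset_ms, ev$onset_ms[c(3, 8)])
  expect_true(all(ms$condition == "standard"))
})

test_that("epochs cover [-100, 700) ms around onset with boundary events logged", {
  n <- 10000
  rec <- make_rec(rbind(0:(n - 1), 0:(n - 1)))  # sample value = 0-based index
  ev <- data.frame(onset_ms = c(50, 5000, 9800),
                   label = "standard", condition = "standard", block = 1L)
  ep <- extract_epochs(rec, ev, c(-100, 700))
  expect_equal(dim(ep$data), c(1L, 2L, 800L))
  expect_equal(ep$data[1, 1, 1], 4900)
  expect_equal(ep$data[1, 1, 800], 5699)
  expect_equal(ep$rejected_log$onset_ms, c(50, 9800))
  expect_error(extract_epochs(rec, ev[c(1, 3), ], c(-100, 700)), "no usable events")

  evall <- data.frame(onset_ms = seq(200, 9000, by = 900),
                      label = "standard", condition = "standard", block = 1L)
  epall <- extract_epochs(rec, evall, c(-100, 700))
  expect_equal(dim(epall$data)[1], nrow(evall))
})

test_that("baseline correction zeroes the pre-stimulus mean and is idempotent", {
  rec <- make_rec(rbind(rep(7, 3000), rnorm(3000)))
  ev <- data.frame(onset_ms = c(500, 1500), label = "standard",
                   condition = "standard", block = 1L)
  ep <- baseline_correct(extract_epochs(rec, ev))
  expect_true(all(abs(ep$data[, 1, ]) < 1e-12))  # constant channel -> zero
  tt <- seq(-100, 699, by = 1)
  base <- tt >= -100 & tt < 0
  mu <- apply(ep$data[, , base, drop = FALSE], c(1, 2), mean)
  expect_true(all(abs(mu) < 1e-9))
  ep2 <- baseline_correct(ep)
  expect_equal(ep2$data, ep$data, tolerance = 1e-12)
})

test_that("artifact rejection removes spiky trials and is monotone in the threshold", {
  set.seed(1)
  rec <- make_rec(rbind(rnorm(6000, sd = 5), rnorm(6000, sd = 5)))
  ev <- data.frame(onset_ms = seq(500, 5000, by = 900), label = "standard",
                   condition = "standard", block = 1L)
  ep <- extract_epochs(rec, ev)
  spiked <- ep
  spiked$data[2, 1, 400] <- 200  # one 200 uV spike
  out <- reject_artifacts(spiked, 100)
  expect_equal(dim(out$data)[1], dim(ep$data)[1] - 1)
  expect_match(tail(out$rejected_log$reason, 1), "peak-to-peak")
  clean <- reject_artifacts(ep, 100)
  expect_equal(dim(clean$data)[1], dim(ep$data)[1])
  kept <- vapply(c(80, 60, 40, 30, 25), function(th) {
    tryCatch(dim(reject_artifacts(ep, th)$data)[1],
             error = function(e) 0)  # all rejected
  }, 0)
  expect_true(all(diff(kept) <= 0))
  expect_error(reject_artifacts(ep, 1), "every trial")
})

test_that("evoked averaging and the MMN difference wave behave algebraically", {
  rec <- make_rec(rbind(sin((1:4000) / 50), cos((1:4000) / 70)))
  ev <- data.frame(onset_ms = c(500, 500 + 1075, 500 + 2 * 1075),
                   label = c("standard", "standard", "deviant_low"),
                   condition = c("standard", "standard", "deviant"), block = 1L)
  ep <- extract_epochs(rec, ev)
  # average of identical trials equals the trial
  ep$data[2, , ] <- ep$data[1, , ]
  avg <- average_evoked(subset_epochs(ep, 1:2), "standard")
  expect_equal(avg$data, ep$data[1, , ])
  expect_equal(avg$n_trials, 2L)
  # MMN of (standard, standard) is identically zero
  std <- average_evoked(ep, "standard")
  expect_true(all(compute_mmn(std, std)$data == 0))
  # grid mismatch is an error
  other <- std
  other$window_ms <- c(-200, 600)
  expect_error(compute_mmn(other, std), "different grids")
})

test_that("MMN peak detection centers a 100 ms window with deterministic tie-break", {
  tt <- seq(-100, 699)
  mk_mmn <- function(y) {
    structure(list(data = rbind(y), channel_names = "Fz", sfreq = 1000,
                   window_ms = c(-100, 700), condition = "difference",
                   n_trials = 10L), class = "eeg_evoked")
  }
  y <- -3 * exp(-0.5 * ((tt - 160) / 20)^2)
  win <- find_mmn_peak(mk_mmn(y))
  expect_equal(win$peak_ms, 160)
  expect_equal(win$window_ms, c(110, 210))
  # equal minima at 140 and 180 ms: earliest wins
  y2 <- rep(0, length(tt))
  y2[tt %in% c(140, 180)] <- -2
  expect_equal(find_mmn_peak(mk_mmn(y2))$peak_ms, 140)
  # a window that would overrun the epoch is an error
  expect_error(find_mmn_peak(mk_mmn(y), search_window_ms = c(600, 800)),
               "exceeds epoch bounds")
  expect_error(find_mmn_peak(mk_mmn(y), channel = "Cz"), "not found")
  # degenerate flat difference wave: peak exists but presence fails
  flat <- mk_mmn(rep(0, length(tt)))
  wflat <- find_mmn_peak(flat)
  expect_false(assess_mmn_presence(flat, wflat))
  expect_true(assess_mmn_presence(mk_mmn(y), win))
})

test_that("mastoid re-referencing applies only when mastoids are present", {
  dat <- rbind(rnorm(100), rnorm(100), rnorm(100), rnorm(100))
  rec <- make_rec(dat, names = c("Fz", "Cz", "M1", "M2"))
  out <- rereference_mastoids(rec)
  ref <- colMeans(dat[3:4, ])
  expect_equal(out$data[1, ], dat[1, ] - ref)
  expect_equal(out$reference, "linked mastoids")
  rec2 <- make_rec(dat[1:2, , drop = FALSE], names = c("Fz", "Cz"))
  expect_identical(rereference_mastoids(rec2)$data, rec2$data)
})
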