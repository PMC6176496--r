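epochs_from_array <- function(arr, fs = 1000, window = c(-100, 700)) {
  structure(list(data = arr, channel_names = sprintf("ch%02d", seq_len(dim(arr)[2])),
                 sfreq = fs, window_ms = window, baseline_ms = c(-100, 0),
                 condition = rep("standard", dim(arr)[1]),
                 label = rep("standard", dim(arr)[1]),
                 onset_ms = seq_len(dim(arr)[1]) * 1000,
                 rejected_log = data.frame()),
            class = "eeg_epochs")
}

test_that("identity leadfield with vanishing regularization recovers the data", {
  lf <- list(gain = diag(8), sensor_names = sprintf("ch%02d", 1:8),
             source_ids = 1:8)
  class(lf) <- "leadfield"
  op <- compute_wmne_operator(lf, lambda_reg = 1e-12, depth_weight_gamma = 0)
  expect_equal(op$kernel, diag(8), tolerance = 1e-9)
  arr <- array(rnorm(3 * 8 * 50), c(3, 8, 50))
  est <- apply_inverse(epochs_from_array(arr), op)
  expect_equal(est$data, arr, tolerance = 1e-8)
})

test_that("a single active source is localized through a well-conditioned leadfield", {
  lf <- make_leadfield(20, 20, conditioning = 1.5, seed = 41)
  src_true <- 7
  act <- matrix(0, 20, 100)
  act[src_true, ] <- sin((1:100) / 5)
  arr <- array(0, c(1, 20, 100))
  arr[1, , ] <- lf$gain %*% act
  est <- apply_inverse(epochs_from_array(arr),
                       compute_wmne_operator(lf, lambda_reg = 1e-8))
  energy <- rowSums(est$data[1, , ]^2)
  expect_equal(which.max(energy), src_true)
})

test_that("the wMNE estimate shrinks monotonically in lambda", {
  lf <- make_leadfield(10, 30, conditioning = 8, seed = 42)
  arr <- array(rnorm(2 * 10 * 40), c(2, 10, 40))
  ep <- epochs_from_array(arr)
  norms <- vapply(c(0.001, 0.01, 0.1, 1, 10), function(l) {
    est <- apply_inverse(ep, compute_wmne_operator(lf, lambda_reg = l))
    sum(est$data^2)
  }, 0)
  expect_true(all(diff(norms) < 0))
})

test_that("the inverse is linear and commutes with averaging", {
  lf <- make_leadfield(8, 20, conditioning = 4, seed = 43)
  op <- compute_wmne_operator(lf)
  x <- array(rnorm(4 * 8 * 30), c(4, 8, 30))
  y <- array(rnorm(4 * 8 * 30), c(4, 8, 30))
  a <- 1.7; b <- -0.3
  lhs <- apply_inverse(epochs_from_array(a * x + b * y), op)$data
  rhs <- a * apply_inverse(epochs_from_array(x), op)$data +
    b * apply_inverse(epochs_from_array(y), op)$data
  expect_equal(lhs, rhs, tolerance = 1e-9)
  # zero in, zero out
  z <- apply_inverse(epochs_from_array(array(0, c(2, 8, 10))), op)
  expect_true(all(z$data == 0))
  # inverse of the average = average of the inverses
  avg_first <- apply_inverse(epochs_from_array(
    array(apply(x, c(2, 3), mean), c(1, 8, 30))), op)$data[1, , ]
  est <- apply_inverse(epochs_from_array(x), op)$data
  expect_equal(avg_first, apply(est, c(2, 3), mean), tolerance = 1e-9)
  # dimension mismatch
  expect_error(apply_inverse(epochs_from_array(array(0, c(1, 5, 10))), op),
               "expects 8 sensors")
})

test_that("ROI aggregation averages member sources and ignores source order", {
  est <- structure(list(data = array(0, c(2, 4, 10)), sfreq = 1000,
                        window_ms = c(-100, 700),
                        condition = c("standard", "deviant"),
                        label = c("standard", "deviant_low"),
                        source_ids = 1:4),
                   class = "source_estimate")
  est$data[1, , ] <- matrix(c(2, 4, 1, 3), 4, 10)
  parc <- data.frame(source_id = 1:4, roi_id = c(1, 1, 2, 2))
  roi <- aggregate_rois(est, parc)
  expect_equal(dim(roi$data), c(2L, 2L, 10L))
  expect_true(all(roi$data[1, 1, ] == 3))  # mean of 2 and 4
  expect_true(all(roi$data[1, 2, ] == 2))  # mean of 1 and 3
  # permuting the parcellation rows changes nothing
  roi2 <- aggregate_rois(est, parc[c(3, 1, 4, 2), ])
  expect_equal(roi2$data, roi$data)
  # one source per ROI is an identity relabeling
  parc1 <- data.frame(source_id = 1:4, roi_id = 1:4)
  expect_equal(aggregate_rois(est, parc1)$data, est$data)
  # an uncovered source is an error
  expect_error(aggregate_rois(est, parc[1:3, ]), "does not cover")
  expect_error(make_parcellation(1:100, 148), "at least as many sources")
  p <- make_parcellation(1:300, 148)
  expect_equal(sort(unique(p$roi_id)), 1:148)
})

test_that("the epochs -> sources -> ROIs chain is linear in the input scale", {
  lf <- make_leadfield(8, 12, conditioning = 4, seed = 44)
  op <- compute_wmne_operator(lf)
  parc <- make_parcellation(lf$source_ids, 6)
  arr <- array(rnorm(2 * 8 * 20), c(2, 8, 20))
  r1 <- aggregate_rois(apply_inverse(epochs_from_array(arr), op), parc)
  r2 <- aggregate_rois(apply_inverse(epochs_from_array(3 * arr), op), parc)
  expect_equal(r2$data, 3 * r1$data, tolerance = 1e-9)
})
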