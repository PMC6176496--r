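# Weighted minimum-norm inverse and ROI aggregation.

#' Compute a weighted minimum-norm (wMNE) inverse operator
#'
#' Builds the linear kernel `K = W L' (L W L' + lambda I)^-1` with
#' depth-weighting matrix `W = diag(||l_j||^(-2 gamma))` over the leadfield
#' columns.  `gamma = 0.5` is the usual depth-weighting exponent; `lambda`
#' defaults to `trace(L W L') / (n_sensors * snr^2)` with an assumed SNR of
#' 3 (identity noise covariance).
#'
#' @param leadfield a \code{\link{make_leadfield}} object (or a list with a
#'   `gain` matrix).
#' @param lambda_reg regularization parameter (>= 0); `NULL` for the default.
#' @param depth_weight_gamma depth-weighting exponent (default 0.5).
#' @param snr assumed amplitude SNR used for the default `lambda_reg`.
#' @return an object of class `inverse_operator`: list with `kernel`
#'   (sources x sensors), `lambda_reg`, `depth_weight_gamma`.
#' @export
#' @examples
#' lf <- make_leadfield(10, 10, conditioning = 1.05, seed = 1)
#' op <- compute_wmne_operator(lf, lambda_reg = 0, depth_weight_gamma = 0)
compute_wmne_operator <- function(leadfield, lambda_reg = NULL,
                                  depth_weight_gamma = 0.5, snr = 3) {
  gain <- leadfield$gain
  stopifnot(is.matrix(gain), all(is.finite(gain)))
  w <- colSums(gain^2)^(-depth_weight_gamma)  # ||l_j||^(-2 gamma)
  if (any(!is.finite(w))) stop("leadfield has an all-zero column; depth weights undefined")
  wlt <- w * t(gain)                          # W L'
  gram <- gain %*% wlt                        # L W L'
  if (is.null(lambda_reg)) lambda_reg <- sum(diag(gram)) / (nrow(gain) * snr^2)
  if (lambda_reg < 0) stop("lambda_reg must be >= 0")
  reg <- gram + diag(lambda_reg, nrow(gram))
  kernel <- tryCatch(
    wlt %*% solve(reg),
    error = function(e) stop("wMNE system is singular (rank-deficient leadfield with lambda_reg = ",
                             lambda_reg, "): ", conditionMessage(e))
  )
  structure(list(kernel = kernel, lambda_reg = lambda_reg,
                 depth_weight_gamma = depth_weight_gamma,
                 source_ids = leadfield$source_ids),
            class = "inverse_operator")
}

#' @export
print.inverse_operator <- function(x, ...) {
  cat(sprintf("<inverse_operator> wMNE kernel %d sources x %d sensors, lambda %.4g, gamma %g\n",
              nrow(x$kernel), ncol(x$kernel), x$lambda_reg, x$depth_weight_gamma))
  invisible(x)
}

#' Apply an inverse operator to sensor epochs
#'
#' Per-trial matrix product `kernel %*% epoch`; strictly linear in the
#' input.
#'
#' @param epochs an `eeg_epochs` object.
#' @param operator an `inverse_operator`.
#' @return an object of class `source_estimate`: list with `data`
#'   (trials x sources x samples) and the trial metadata of `epochs`.
#' @export
apply_inverse <- function(epochs, operator) {
  stopifnot(inherits(epochs, "eeg_epochs"), inherits(operator, "inverse_operator"))
  d <- dim(epochs$data)
  if (ncol(operator$kernel) != d[2])
    stop(sprintf("kernel expects %d sensors but epochs have %d channels",
                 ncol(operator$kernel), d[2]))
  n_src <- nrow(operator$kernel)
  out <- array(0, dim = c(d[1], n_src, d[3]))
  for (t in seq_len(d[1]))
    out[t, , ] <- operator$kernel %*% epochs$data[t, , ]
  structure(list(data = out, sfreq = epochs$sfreq, window_ms = epochs$window_ms,
                 condition = epochs$condition, label = epochs$label,
                 source_ids = operator$source_ids),
            class = "source_estimate")
}

#' Map dipole sources onto cortical ROIs
#'
#' @param source_ids integer or character ids of the sources.
#' @param n_rois number of ROIs (default 148, the Destrieux parcellation
#'   size).
#' @return a `parcellation` data.frame with columns `source_id`, `roi_id`;
#'   sources are assigned round-robin so every ROI is non-empty whenever
#'   there are at least `n_rois` sources.
#' @export
make_parcellation <- function(source_ids, n_rois = 148L) {
  n <- length(source_ids)
  if (n < n_rois) stop("need at least as many sources as ROIs (", n, " < ", n_rois, ")")
  structure(data.frame(source_id = source_ids,
                       roi_id = ((seq_len(n) - 1L) %% n_rois) + 1L),
            class = c("parcellation", "data.frame"))
}

#' Aggregate source estimates into ROI time series
#'
#' ROI signal = arithmetic mean of the member sources' current estimates,
#' per trial and sample.
#'
#' @param est a `source_estimate`.
#' @param parc a `parcellation` data.frame (`source_id`, `roi_id`) covering
#'   every source; every ROI must be non-empty.
#' @param state state label carried into the output (default `"awake"`).
#' @return a `roi_signals` object (trials x ROIs x samples).
#' @export
aggregate_rois <- function(est, parc, state = "awake") {
  stopifnot(inherits(est, "source_estimate"), is.data.frame(parc))
  d <- dim(est$data)
  roi_of <- parc$roi_id[match(est$source_ids, parc$source_id)]
  if (anyNA(roi_of)) stop("parcellation does not cover every source")
  rois <- sort(unique(parc$roi_id))
  if (!setequal(roi_of, rois))
    stop("empty ROI(s) in parcellation: ",
         paste(setdiff(rois, roi_of), collapse = ", "))
  n_roi <- length(rois)
  out <- array(0, dim = c(d[1], n_roi, d[3]))
  counts <- tabulate(match(roi_of, rois), nbins = n_roi)
  for (t in seq_len(d[1]))
    out[t, , ] <- rowsum(est$data[t, , ], group = match(roi_of, rois)) / counts
  structure(list(data = out, sfreq = est$sfreq, window_ms = est$window_ms,
                 condition = est$condition, label = est$label,
                 state = state, roi_ids = rois, freq_hz = rep(NA_real_, d[1])),
            class = "roi_signals")
}
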