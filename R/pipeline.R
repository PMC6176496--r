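# Run configuration and the end-to-end pipeline driver.

merge_group <- function(defaults, given, group) {
  if (is.null(given)) return(defaults)
  if (!is.list(given)) stop("config group '", group, "' must be a list")
  unknown <- setdiff(names(given), names(defaults))
  if (length(unknown))
    stop("unknown config key(s) in '", group, "': ",
         paste(unknown, collapse = ", "))
  defaults[names(given)] <- given
  defaults
}

#' Build a validated pipeline run configuration
#'
#' Collects every stage parameter in one serializable object.  Unknown keys
#' are rejected.  All randomness in a run flows from `seed` through
#' per-stage substreams (\code{\link{derive_seed}}).
#'
#' @param n_subjects cohort size.
#' @param route `"roi"` (simulate ROI epochs directly; the default study
#'   configuration) or `"sensor"` (full chain through the sensor simulation
#'   and the wMNE inverse).
#' @param seed base seed.
#' @param out_dir optional output directory.
#' @param sim overrides for \code{\link{sim_config}} fields.
#' @param preprocess,inverse,connectivity,network,stats,cohort per-stage
#'   overrides; see the defaults in the function body.
#' @return an object of class `run_config`.
#' @export
#' @examples
#' cfg <- run_config(n_subjects = 4, seed = 1)
#' cfg$preprocess$broadband_hz
run_config <- function(n_subjects = 12L,
                       route = c("roi", "sensor"),
                       seed = 1L,
                       out_dir = NULL,
                       sim = list(),
                       preprocess = list(),
                       inverse = list(),
                       connectivity = list(),
                       network = list(),
                       stats = list(),
                       cohort = list()) {
  route <- match.arg(route)
  cfg <- list(
    n_subjects = as.integer(n_subjects),
    route = route,
    seed = as.integer(seed),
    out_dir = out_dir,
    sim = merge_group(list(
      tones_per_block = 300L, n_standard = 200L, n_deviant_low = 50L,
      n_deviant_high = 50L, tone_duration_ms = 75, isi_ms = 1000,
      sampling_rate_hz = 1000, gamma_band_hz = c(30, 40),
      noise_sd = 0.5, anesthesia_attenuation = 0.3, use_default_couplings = TRUE
    ), sim, "sim"),
    preprocess = merge_group(list(
      broadband_hz = c(0.5, 40), epoch_window_ms = c(-100, 700),
      baseline_ms = c(-100, 0), reject_uv = 100,
      min_preceding_standards = 3L, mmn_channel = "Fz",
      search_window_ms = c(100, 250), presence_uv = -0.5
    ), preprocess, "preprocess"),
    inverse = merge_group(list(
      n_sensors = 24L, n_sources = 296L, conditioning = 5,
      lambda_reg = NULL, depth_weight_gamma = 0.5, snr = 3
    ), inverse, "inverse"),
    connectivity = merge_group(list(
      method = "pooled", window_peak_ms = 160
    ), connectivity, "connectivity"),
    network = merge_group(list(
      density_from = 0.06, density_to = 0.90, density_by = 0.01,
      atlas_csv = NULL
    ), network, "network"),
    stats = merge_group(list(alpha = 0.05, adjust = "none"), stats, "stats"),
    cohort = merge_group(list(
      n_trials_per_condition = 28L, epoch_window_ms = c(-100, 260)
    ), cohort, "cohort")
  )
  if (cfg$n_subjects < 1) stop("n_subjects must be >= 1")
  class(cfg) <- "run_config"
  cfg
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf("<run_config> %d subjects, route '%s', seed %d, hash %s\n",
              x$n_subjects, x$route, x$seed, config_hash(x)))
  invisible(x)
}

#' Hash of a run configuration
#'
#' MD5 of the canonical JSON serialization of the analysis parameters
#' (`out_dir` is excluded -- it does not affect the results); embedded in
#' every output file for provenance, so outputs produced under different
#' configurations can be detected (and refused) at the stats stage.
#'
#' @param config a `run_config`.
#' @return a 32-character hash string.
#' @export
config_hash <- function(config) {
  stopifnot(inherits(config, "run_config"))
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  core <- unclass(config)
  core$out_dir <- NULL
  jsonlite::write_json(core, tmp, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  unname(tools::md5sum(tmp))
}

#' Write / read a run configuration as JSON
#'
#' @param config a `run_config`.
#' @param path JSON path.
#' @return `read_run_config` returns a validated `run_config` (unknown keys
#'   in the file are rejected); `write_run_config` returns `path`
#'   invisibly.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  top_known <- names(formals(run_config))
  unknown <- setdiff(names(raw), top_known)
  if (length(unknown))
    stop("unknown config key(s) in ", path, ": ", paste(unknown, collapse = ", "))
  do.call(run_config, raw)
}

#' Subset the trials of an `eeg_epochs` object
#'
#' @param epochs an `eeg_epochs` object.
#' @param idx integer or logical trial index.
#' @return an `eeg_epochs` with the selected trials.
#' @export
subset_epochs <- function(epochs, idx) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  epochs$data <- epochs$data[idx, , , drop = FALSE]
  epochs$condition <- epochs$condition[idx]
  epochs$label <- epochs$label[idx]
  epochs$onset_ms <- epochs$onset_ms[idx]
  epochs
}

pipeline_partition <- function(config) {
  if (is.null(config$network$atlas_csv)) default_area_partition()
  else read_area_partition(config$network$atlas_csv)
}

pipeline_grid <- function(config) {
  seq(config$network$density_from, config$network$density_to,
      by = config$network$density_by)
}

# One subject of the sensor route: simulate, preprocess, invert, and return
# per-condition connectivity metrics plus the analysis windows used.
sensor_route_subject <- function(config, s, partition, grid) {
  states <- c("awake", "anesthesia")
  pp <- config$preprocess
  n_rois <- nrow(partition)
  lf <- make_leadfield(config$inverse$n_sensors, config$inverse$n_sources,
                       conditioning = config$inverse$conditioning,
                       seed = derive_seed(config$seed, "leadfield", s))
  parc <- make_parcellation(lf$source_ids, n_rois)
  peak_hw <- 50

  sessions <- list()
  for (st in states) {
    scfg <- sim_config(
      tones_per_block = config$sim$tones_per_block,
      n_standard = config$sim$n_standard,
      n_deviant_low = config$sim$n_deviant_low,
      n_deviant_high = config$sim$n_deviant_high,
      tone_duration_ms = config$sim$tone_duration_ms,
      isi_ms = config$sim$isi_ms,
      sampling_rate_hz = config$sim$sampling_rate_hz,
      gamma_band_hz = config$sim$gamma_band_hz,
      epoch_window_ms = pp$epoch_window_ms,
      noise_sd = config$sim$noise_sd,
      anesthesia_attenuation = config$sim$anesthesia_attenuation,
      seed = derive_seed(config$seed, "subject", s, st)
    )
    ev <- generate_event_sequence(scfg)
    rec <- simulate_sensor_recording(scfg, ev, lf, state = st)
    rec <- rereference_mastoids(rec)
    vd <- select_valid_deviants(ev, pp$min_preceding_standards)
    sessions[[st]] <- list(cfg = scfg, events = ev, rec = rec, deviants = vd)
  }

  # ERP stage on the awake session: broadband filter, epoch, clean, average.
  aw <- sessions$awake
  erp_rec <- bandpass_filter(aw$rec, pp$broadband_hz[1], pp$broadband_hz[2])
  ep <- extract_epochs(erp_rec, aw$events, pp$epoch_window_ms, pp$baseline_ms)
  ep <- baseline_correct(ep)
  ep <- reject_artifacts(ep, pp$reject_uv)
  std_ev <- average_evoked(ep, "standard")
  dev_ep <- subset_epochs(ep, ep$onset_ms %in% aw$deviants$onset_ms)
  if (!dim(dev_ep$data)[1]) stop("subject ", s, ": no clean valid-deviant epochs")
  dev_ev <- average_evoked(dev_ep, "deviant")
  mmn <- compute_mmn(dev_ev, std_ev)
  window <- find_mmn_peak(mmn, pp$mmn_channel, pp$search_window_ms)
  present <- assess_mmn_presence(mmn, window, pp$presence_uv)
  if (!present) return(list(excluded = TRUE, window = window))

  n_use <- min(vapply(sessions, function(x) nrow(x$deviants), 0L),
               config$cohort$n_trials_per_condition)
  if (n_use < 2) stop("subject ", s, ": fewer than 2 valid deviants")

  rows <- list()
  windows <- list()
  for (st in states) {
    ses <- sessions[[st]]
    vd <- ses$deviants[seq_len(n_use), , drop = FALSE]
    ms <- matched_standards(ses$events, vd)
    sel <- rbind(ms, vd)
    sel <- sel[order(sel$onset_ms), , drop = FALSE]
    gam <- bandpass_filter(ses$rec, config$sim$gamma_band_hz[1],
                           config$sim$gamma_band_hz[2])
    epg <- extract_epochs(gam, sel, pp$epoch_window_ms, pp$baseline_ms)
    src <- apply_inverse(epg, compute_wmne_operator(
      lf, lambda_reg = config$inverse$lambda_reg,
      depth_weight_gamma = config$inverse$depth_weight_gamma,
      snr = config$inverse$snr))
    roi <- aggregate_rois(src, parc, state = st)
    # the anesthesia state reuses the awake-derived window object verbatim
    windows[[st]] <- window
    ph <- instantaneous_phase(roi, window)
    for (cond in c("standard", "deviant")) {
      phc <- ph
      idx <- ph$condition == cond
      phc$phases <- ph$phases[idx, , , drop = FALSE]
      phc$condition <- ph$condition[idx]
      cm <- connectivity_matrix(phc, method = config$connectivity$method)
      sw <- density_sweep(cm, partition, grid)
      sm <- sw$summary
      row <- data.frame(subject = s, condition = cond, state = st,
                        n_trials = sum(idx), Ratio = sm$Ratio,
                        L_all = sm$L_all, S_all = sm$S_all,
                        stringsAsFactors = FALSE)
      lcols <- setdiff(grep("^L_", names(sm), value = TRUE), "L_all")
      rows[[length(rows) + 1]] <- cbind(row, sm[, lcols, drop = FALSE])
    }
  }
  list(excluded = FALSE, metrics = do.call(rbind, rows), windows = windows)
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes simulate -> preprocess -> inverse -> connectivity -> network ->
#' stats for `config$n_subjects` virtual subjects and both consciousness
#' states.  On the `"roi"` route, ROI epochs are simulated directly with
#' the ground-truth couplings and the analysis window is the 100 ms window
#' centered on `config$connectivity$window_peak_ms`.  On the `"sensor"`
#' route each subject's awake session runs the complete ERP chain; the MMN
#' peak detected awake defines the analysis window, which is reused
#' verbatim for the anesthesia state, and subjects without an MMN waveform
#' are excluded from the group tables (and listed in the result).
#'
#' When `config$out_dir` is set, the per-subject metrics, the five
#' comparison tables, and the configuration (with its hash) are written
#' there; reruns with the same config are byte-identical.
#'
#' @param config a \code{\link{run_config}}.
#' @return an object of class `mmn_pipeline_result`: list with `metrics`,
#'   `tables`, `windows` (per subject/state on the sensor route),
#'   `excluded` (subject ids), `config`, `config_hash`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  partition <- pipeline_partition(config)
  grid <- pipeline_grid(config)
  hash <- config_hash(config)
  excluded <- integer(0)
  windows <- list()

  if (config$route == "roi") {
    coupling <- if (isTRUE(config$sim$use_default_couplings))
      default_coupling_spec(partition) else NULL
    peak <- config$connectivity$window_peak_ms
    metrics <- simulate_cohort(
      n_subjects = config$n_subjects, partition = partition,
      coupling_spec = coupling, seed = config$seed,
      n_trials_per_condition = config$cohort$n_trials_per_condition,
      window_ms = c(peak - 50, peak + 50),
      epoch_window_ms = config$cohort$epoch_window_ms,
      anesthesia_attenuation = config$sim$anesthesia_attenuation,
      noise_sd = config$sim$noise_sd, grid = grid,
      min_preceding_standards = config$preprocess$min_preceding_standards,
      method = config$connectivity$method
    )
  } else {
    rows <- list()
    for (s in seq_len(config$n_subjects)) {
      res <- sensor_route_subject(config, s, partition, grid)
      if (res$excluded) {
        excluded <- c(excluded, s)
        message("subject ", s, " excluded: no MMN waveform")
        next
      }
      rows[[length(rows) + 1]] <- res$metrics
      windows[[as.character(s)]] <- res$windows
    }
    if (!length(rows)) stop("stats stage: every subject was excluded (no MMN)")
    metrics <- do.call(rbind, rows)
    rownames(metrics) <- NULL
  }
  attr(metrics, "config_hash") <- hash

  tables <- tryCatch(
    build_comparison_tables(metrics, alpha = config$stats$alpha,
                            adjust = config$stats$adjust),
    error = function(e) stop("stats stage failed: ", conditionMessage(e))
  )

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_metrics_csv(metrics, file.path(config$out_dir, "subject_metrics.csv"),
                      config_hash = hash)
    write_comparison_tables(tables, config$out_dir, config_hash = hash)
    write_run_config(config, file.path(config$out_dir, "run_config.json"))
  }

  structure(list(metrics = metrics, tables = tables, windows = windows,
                 excluded = excluded, config = config, config_hash = hash),
            class = "mmn_pipeline_result")
}

#' @export
print.mmn_pipeline_result <- function(x, ...) {
  cat(sprintf("<mmn_pipeline_result> %d subjects analyzed (%d excluded), route '%s'\n",
              length(unique(x$metrics$subject)), length(x$excluded),
              x$config$route))
  cat("Ratio comparison (standard vs deviant within state):\n")
  print(x$tables$ratio_by_condition, row.names = FALSE)
  invisible(x)
}
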