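# Virtual-subject cohorts: the study-level synthetic conditions.  Every
# subject runs the oddball paradigm twice (awake, anesthesia); deviant
# trials carry additional long-distance (inter-area) phase couplings that
# anesthesia attenuates, emulating the workspace-theory prediction the
# analysis is designed to detect.

take_rois <- function(by_area, cursor, area, n = 1L) {
  used <- cursor[[area]]
  avail <- by_area[[area]]
  if (is.null(avail)) stop("no ROIs in area ", area)
  if (used + n > length(avail)) stop("area ", area, " exhausted")
  cursor[[area]] <- used + n
  avail[(used + 1):(used + n)]
}

#' Default ground-truth coupling scheme for synthetic cohorts
#'
#' Builds a coupling table on the given area partition in two tiers:
#' \itemize{
#'   \item a condition-independent resting backbone: one intra-area pair
#'     per area and one homotopic inter-area pair per area family
#'     (21 couplings on the 14-area atlas), strength 0.7;
#'   \item a deviant-only "ignition" network: one hub ROI in each of the
#'     MMN-network areas (bilateral ventral/dorsal prefrontal, central,
#'     temporal, parietal) drives a distinct follower ROI in every other
#'     remaining ROI of those areas plus the cingulate (76 inter-area
#'     couplings on the shipped atlas), strength 0.95.  This emulates the
#'     workspace-theory prediction that deviant processing recruits
#'     brain-wide long-distance synchronization, which anesthesia
#'     attenuation abolishes.
#' }
#' Phase lags are spread over (0, pi/2]; every coupling has a distinct
#' follower ROI so no follower is ever re-driven.  In the anesthesia state
#' all strengths are multiplied by the config's `anesthesia_attenuation`.
#'
#' The tier sizes and strengths were fixed by a design-stage power
#' analysis: with 12 subjects and ~25 trials per condition, the deviant
#' ignition must shift the grid-mean Ratio by roughly one between-subject
#' standard deviation to be reliably detected by the paired test, which a
#' sparse effect (tens of couplings) cannot do against the estimation
#' noise of 10878 ROI pairs.
#'
#' @param partition an area partition (default the shipped 148-ROI atlas).
#' @return a coupling data.frame (`roi_i`, `roi_j`, `phase_lag`, `strength`,
#'   `condition`).
#' @export
default_coupling_spec <- function(partition = default_area_partition()) {
  by_area <- split(partition$roi_id, partition$area)
  areas <- names(by_area)
  cursor <- new.env()
  for (a in areas) cursor[[a]] <- 0L
  base_of <- function(a) sub("^[LR]", "", a)

  # backbone: one intra pair per area, one homotopic pair per area family
  intra <- do.call(rbind, lapply(areas, function(a) {
    r <- take_rois(by_area, cursor, a, 2L)
    data.frame(roi_i = r[1], roi_j = r[2], area_i = a, area_j = a,
               condition = "both", strength = 0.7, stringsAsFactors = FALSE)
  }))
  fams <- unique(base_of(areas))
  homo <- do.call(rbind, lapply(fams, function(f) {
    l <- paste0("L", f); r <- paste0("R", f)
    if (!(l %in% areas && r %in% areas)) return(NULL)
    data.frame(roi_i = take_rois(by_area, cursor, l),
               roi_j = take_rois(by_area, cursor, r),
               area_i = l, area_j = r,
               condition = "both", strength = 0.7, stringsAsFactors = FALSE)
  }))

  # deviant-only ignition: hubs drive every remaining ROI of the MMN network
  hub_areas <- intersect(c("LVPF", "RVPF", "LDPF", "RDPF", "LC", "RC",
                           "LT", "RT", "LP", "RP"), areas)
  follower_areas <- intersect(c(hub_areas, "LCing", "RCing"), areas)
  hubs <- stats::setNames(
    vapply(hub_areas, function(a) {
      # fresh hub ROI if the area still has one; otherwise reuse the area's
      # backbone driver (drivers need no exclusivity, only followers do)
      if (cursor[[a]] < length(by_area[[a]])) take_rois(by_area, cursor, a)
      else by_area[[a]][1]
    }, 0L),
    hub_areas)
  dev <- NULL
  hub_cycle <- 0L
  for (a in follower_areas) {
    n_left <- length(by_area[[a]]) - cursor[[a]]
    if (n_left <= 0) next
    for (k in seq_len(n_left)) {
      # next hub in a different area (round robin, deterministic)
      repeat {
        hub_cycle <- hub_cycle + 1L
        h <- hub_areas[(hub_cycle - 1L) %% length(hub_areas) + 1L]
        if (h != a) break
      }
      dev <- rbind(dev, data.frame(
        roi_i = hubs[[h]], roi_j = take_rois(by_area, cursor, a),
        area_i = h, area_j = a,
        condition = "deviant", strength = 0.95, stringsAsFactors = FALSE))
    }
  }

  spec <- rbind(intra, homo, dev)
  spec$phase_lag <- seq(pi / 6, pi / 2, length.out = nrow(spec))
  spec <- spec[, c("roi_i", "roi_j", "phase_lag", "strength", "condition",
                   "area_i", "area_j")]
  rownames(spec) <- NULL
  validate_coupling_spec(spec, max(partition$roi_id))
  spec
}

#' Simulate a cohort of virtual subjects and compute their network metrics
#'
#' For every subject and state an independent oddball session is drawn:
#' its own stimulus sequence, valid deviants (preceded by at least
#' `min_preceding_standards` standards), and the standards immediately
#' preceding them as the matched standard trials, so both conditions have
#' equal trial counts; counts are further equalized across states and
#' capped at `n_trials_per_condition` (the wPLI estimator's small-sample
#' bias depends on trial count, so unequal counts would masquerade as
#' condition effects).  ROI epochs are then simulated, gamma phases
#' extracted over the analysis window, the wPLI matrix computed per
#' condition, and the long/short-distance statistics summarized as the
#' mean over the density grid.
#'
#' @param n_subjects number of virtual subjects.
#' @param partition area partition.
#' @param coupling_spec ground-truth couplings (default
#'   \code{\link{default_coupling_spec}}); `NULL` for a null cohort with no
#'   couplings.
#' @param seed base seed; every subject/state draws an independent
#'   substream.
#' @param n_trials_per_condition cap on trials per condition.
#' @param window_ms analysis window in ms (default the 100 ms window around
#'   a 160 ms MMN peak).
#' @param epoch_window_ms simulated epoch support.
#' @param states states to simulate.
#' @param anesthesia_attenuation coupling attenuation under anesthesia.
#' @param noise_sd additive noise level.
#' @param grid density grid for \code{\link{density_sweep}}.
#' @param min_preceding_standards deviant validity rule.
#' @param method wPLI estimator variant.
#' @return a metrics data.frame: one row per subject x condition x state
#'   with columns `Ratio`, `L_all`, `S_all` and the 14 per-area `L_<area>`
#'   columns (grid means).
#' @export
simulate_cohort <- function(n_subjects = 12L,
                            partition = default_area_partition(),
                            coupling_spec = default_coupling_spec(partition),
                            seed = 1L,
                            n_trials_per_condition = 28L,
                            window_ms = c(110, 210),
                            epoch_window_ms = c(-100, 260),
                            states = c("awake", "anesthesia"),
                            anesthesia_attenuation = 0.3,
                            noise_sd = 0.5,
                            grid = seq(0.06, 0.90, by = 0.01),
                            min_preceding_standards = 3L,
                            method = "pooled") {
  n_rois <- nrow(partition)
  rows <- list()
  for (s in seq_len(n_subjects)) {
    cfgs <- lapply(states, function(st)
      sim_config(coupling_spec = coupling_spec,
                 anesthesia_attenuation = anesthesia_attenuation,
                 noise_sd = noise_sd, n_rois = n_rois,
                 epoch_window_ms = epoch_window_ms,
                 seed = derive_seed(seed, "subject", s, st)))
    names(cfgs) <- states
    sessions <- lapply(states, function(st) {
      ev <- generate_event_sequence(cfgs[[st]])
      vd <- select_valid_deviants(ev, min_preceding_standards)
      list(events = ev, deviants = vd)
    })
    names(sessions) <- states
    n_use <- min(vapply(sessions, function(x) nrow(x$deviants), 0L),
                 n_trials_per_condition)
    if (n_use < 2) stop("fewer than 2 valid deviants for subject ", s)
    for (st in states) {
      ses <- sessions[[st]]
      vd <- ses$deviants[seq_len(n_use), , drop = FALSE]
      ms <- matched_standards(ses$events, vd)
      sel <- rbind(ms, vd)
      sel <- sel[order(sel$onset_ms), , drop = FALSE]
      rs <- simulate_roi_signals(cfgs[[st]], sel, state = st)
      ph <- instantaneous_phase(rs, window_ms)
      for (cond in c("standard", "deviant")) {
        phc <- ph
        idx <- ph$condition == cond
        phc$phases <- ph$phases[idx, , , drop = FALSE]
        phc$condition <- ph$condition[idx]
        cm <- connectivity_matrix(phc, method = method)
        sw <- density_sweep(cm, partition, grid)
        sm <- sw$summary
        row <- data.frame(subject = s, condition = cond, state = st,
                          n_trials = sum(idx),
                          Ratio = sm$Ratio, L_all = sm$L_all, S_all = sm$S_all,
                          stringsAsFactors = FALSE)
        lcols <- grep("^L_", names(sm), value = TRUE)
        lcols <- setdiff(lcols, "L_all")
        row <- cbind(row, sm[, lcols, drop = FALSE])
        rows[[length(rows) + 1]] <- row
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
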