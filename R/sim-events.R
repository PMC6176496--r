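#' Generate an oddball stimulus event sequence
#'
#' Draws, for every block, a uniformly random permutation of the configured
#' tone labels (standard / deviant_low / deviant_high) and lays them out at a
#' fixed onset cadence: consecutive onsets are `tone_duration_ms + isi_ms`
#' apart (offset-to-onset ISI convention), with the first tone at
#' `first_onset_ms` so that the pre-stimulus epoch window never underruns the
#' recording.  Deterministic given `config$seed`.
#'
#' @param config a \code{\link{sim_config}}.
#' @param first_onset_ms onset of the first tone, ms from recording start.
#' @return an `mmn_events` data.frame with columns `onset_ms`, `label`
#'   (`standard`, `deviant_low`, `deviant_high`), `condition` (`standard` /
#'   `deviant` -- the two deviant pitches pooled) and `block`.
#' @export
#' @examples
#' ev <- generate_event_sequence(sim_config(seed = 1))
#' table(ev$label)
generate_event_sequence <- function(config, first_onset_ms = 1000) {
  validate_sim_config(config)
  soa <- config$tone_duration_ms + config$isi_ms
  labels <- with_seed(derive_seed(config$seed, "events"), {
    unlist(lapply(seq_len(config$n_blocks), function(b) {
      sample(rep(c("standard", "deviant_low", "deviant_high"),
                 c(config$n_standard, config$n_deviant_low, config$n_deviant_high)))
    }))
  })
  n <- length(labels)
  ev <- data.frame(
    onset_ms = first_onset_ms + (seq_len(n) - 1) * soa,
    label = labels,
    condition = ifelse(labels == "standard", "standard", "deviant"),
    block = rep(seq_len(config$n_blocks), each = config$tones_per_block),
    stringsAsFactors = FALSE
  )
  class(ev) <- c("mmn_events", "data.frame")
  ev
}

#' Write / read an event table as TSV
#'
#' Columns `onset_ms`, `label`, `condition`, `block`; UTF-8, '.' decimal
#' separator.  Round-trips losslessly.
#'
#' @param events an `mmn_events` data.frame.
#' @param path file path.
#' @return `read_events_tsv` returns the `mmn_events` data.frame;
#'   `write_events_tsv` returns `path` invisibly.
#' @export
write_events_tsv <- function(events, path) {
  stopifnot(is.data.frame(events))
  utils::write.table(as.data.frame(events), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  if (!file.exists(path)) stop("event file not found: ", path)
  ev <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("onset_ms", "label")
  miss <- setdiff(need, names(ev))
  if (length(miss)) stop("event file ", path, " lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (is.unsorted(ev$onset_ms, strictly = TRUE))
    stop("event file ", path, ": onsets must be strictly increasing")
  if (is.null(ev$condition))
    ev$condition <- ifelse(ev$label == "standard", "standard", "deviant")
  if (is.null(ev$block)) ev$block <- 1L
  class(ev) <- c("mmn_events", "data.frame")
  ev
}
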