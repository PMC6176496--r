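# Text-based containers for the pipeline objects.  Arrays are stored with
# explicit dimensions and full numeric precision, so every round-trip is
# lossless; each file carries a provenance block (package version, optional
# config hash).

encode_field <- function(x) {
  if (is.data.frame(x)) {
    list(`.type` = "data.frame", columns = lapply(as.list(x), encode_field))
  } else if (is.array(x) || is.matrix(x)) {
    list(`.type` = "array", dim = dim(x), data = as.vector(x),
         dimnames = dimnames(x))
  } else if (is.list(x)) {
    out <- lapply(x, encode_field)
    out[["?class"]] <- class(x)[1]
    list(`.type` = "list", value = out)
  } else x
}

decode_field <- function(x) {
  if (is.list(x) && !is.null(x[[".type"]])) {
    if (x$.type == "data.frame") {
      cols <- lapply(x$columns, decode_field)
      return(as.data.frame(cols, stringsAsFactors = FALSE, optional = TRUE))
    }
    if (x$.type == "array") {
      a <- array(unlist(x$data), dim = unlist(x$dim))
      if (!is.null(x$dimnames)) dimnames(a) <- x$dimnames
      return(a)
    }
    if (x$.type == "list") {
      v <- x$value
      cl <- v[["?class"]]
      v[["?class"]] <- NULL
      out <- lapply(v, decode_field)
      if (!is.null(cl) && !cl %in% c("list")) class(out) <- cl
      return(out)
    }
  }
  x
}

#' Write / read a pipeline object as a JSON container
#'
#' Serializes any of the package's container objects (`eeg_epochs`,
#' `roi_signals`, `wpli_matrix`, `connection_sweep`, `leadfield`,
#' `eeg_recording`, ...) to a self-describing JSON file with full numeric
#' precision; `read_container` restores a bit-identical object.
#'
#' @param x the object.
#' @param path output path (conventionally `.json`).
#' @param config_hash optional provenance hash stored alongside.
#' @return `write_container` returns `path` invisibly; `read_container`
#'   the restored object (the stored config hash, if any, is attached as
#'   attribute `config_hash`).
#' @export
write_container <- function(x, path, config_hash = NULL) {
  payload <- list(
    package = "mmnnet",
    version = as.character(utils::packageVersion("mmnnet")),
    config_hash = config_hash,
    object = encode_field(x)
  )
  # digits = I(17): full significant digits, so doubles round-trip bit-exactly
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' @rdname write_container
#' @export
read_container <- function(path) {
  if (!file.exists(path)) stop("container not found: ", path)
  payload <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE,
                                 simplifyMatrix = FALSE)
  if (is.null(payload$object))
    stop("malformed container ", path, ": no 'object' field")
  obj <- decode_field(payload$object)
  if (!is.null(payload$config_hash))
    attr(obj, "config_hash") <- payload$config_hash
  obj
}

#' Write / read a connectivity matrix as CSV
#'
#' Provenance and metadata (trial count, state, condition, estimator,
#' window) are stored in `#`-prefixed header lines; weights are written
#' with 17 significant digits, so the round-trip is bit-identical.
#'
#' @param cm a `wpli_matrix`.
#' @param path CSV path.
#' @param config_hash optional provenance hash.
#' @return `read_connectivity_csv` returns the `wpli_matrix`;
#'   `write_connectivity_csv` returns `path` invisibly.
#' @export
write_connectivity_csv <- function(cm, path, config_hash = NULL) {
  stopifnot(inherits(cm, "wpli_matrix"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  meta <- c(version = as.character(utils::packageVersion("mmnnet")),
            config_hash = if (is.null(config_hash)) "" else config_hash,
            n_trials = cm$n_trials, state = cm$state,
            condition = cm$condition, method = cm$method,
            window_lo_ms = cm$window_ms[1], window_hi_ms = cm$window_ms[2])
  writeLines(sprintf("# %s=%s", names(meta), unname(meta)), con)
  utils::write.table(format(cm$w, digits = 17, trim = TRUE, scientific = TRUE),
                     con, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_connectivity_csv
#' @export
read_connectivity_csv <- function(path) {
  if (!file.exists(path)) stop("connectivity file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  hdr <- grep("^#", lines, value = TRUE)
  kv <- sub("^# ", "", hdr)
  meta <- stats::setNames(sub("^[^=]*=", "", kv), sub("=.*$", "", kv))
  body <- lines[!grepl("^#", lines)]
  w <- as.matrix(utils::read.table(text = body, sep = ",", header = FALSE))
  dimnames(w) <- list(seq_len(nrow(w)), seq_len(ncol(w)))
  if (nrow(w) != ncol(w)) stop("malformed connectivity matrix in ", path,
                               ": not square")
  structure(list(w = w, n_trials = as.integer(meta[["n_trials"]]),
                 state = meta[["state"]], condition = meta[["condition"]],
                 window_ms = c(as.numeric(meta[["window_lo_ms"]]),
                               as.numeric(meta[["window_hi_ms"]])),
                 method = meta[["method"]]),
            class = "wpli_matrix")
}

#' Write / read per-subject metrics as CSV
#'
#' @param metrics the metrics data.frame of \code{\link{simulate_cohort}} /
#'   \code{\link{run_pipeline}}.
#' @param path CSV path.
#' @param config_hash optional provenance hash (stored in a `#` header line
#'   and re-attached as attribute on read, letting
#'   \code{\link{build_comparison_tables}} refuse mixed-config input).
#' @return `read_metrics_csv` returns the data.frame;
#'   `write_metrics_csv` returns `path` invisibly.
#' @export
write_metrics_csv <- function(metrics, path, config_hash = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# mmnnet %s config %s",
                     as.character(utils::packageVersion("mmnnet")),
                     if (is.null(config_hash)) "unspecified" else config_hash),
             con)
  utils::write.table(format(metrics, digits = 17, trim = TRUE),
                     con, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_metrics_csv
#' @export
read_metrics_csv <- function(path) {
  if (!file.exists(path)) stop("metrics file not found: ", path)
  first <- readLines(path, n = 1)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (grepl("config ", first))
    attr(df, "config_hash") <- sub(".*config ", "", first)
  df
}

#' Read a raw recording from a documented array container
#'
#' Accepts the JSON container written by \code{\link{write_container}} for
#' an `eeg_recording`.
#'
#' @param path container path.
#' @return an `eeg_recording`.
#' @export
read_raw <- function(path) {
  rec <- read_container(path)
  if (!inherits(rec, "eeg_recording"))
    stop("container ", path, " does not hold an eeg_recording (got ",
         class(rec)[1], ")")
  if (is.null(rec$sfreq) || rec$sfreq <= 0)
    stop("malformed recording ", path, ": missing or non-positive sfreq")
  rec
}
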