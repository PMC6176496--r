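# The 148-ROI cortical parcellation (Destrieux scheme) grouped into 14
# coarse areas: ventral prefrontal (VPF), dorsal prefrontal (DPF), central
# (C), temporal (T), parietal (P), occipital (O) and cingulate (Cing), per
# hemisphere.

#' Read and validate an ROI-to-area mapping CSV
#'
#' The CSV must have columns `roi_id`, `roi_name`, `area` (a `hemisphere`
#' column is optional).  ROI ids must be the unique integers `1..n` and
#' every area must be non-empty.
#'
#' @param path CSV path.
#' @param expect_rois,expect_areas expected ROI and area counts; `NULL` to
#'   skip the check.
#' @return an `area_partition` data.frame.
#' @export
read_area_partition <- function(path, expect_rois = NULL, expect_areas = NULL) {
  if (!file.exists(path)) stop("atlas mapping file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("roi_id", "roi_name", "area")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("atlas mapping ", path, " lacks column(s): ",
                         paste(miss, collapse = ", "))
  n <- nrow(df)
  if (!setequal(df$roi_id, seq_len(n))) {
    missing_ids <- setdiff(seq_len(max(df$roi_id, n)), df$roi_id)
    stop("atlas mapping must enumerate ROI ids 1..n exactly once; missing/duplicated: ",
         paste(utils::head(missing_ids, 10), collapse = ", "))
  }
  if (anyNA(df$area) || any(df$area == ""))
    stop("atlas mapping has ROIs with empty area")
  if (!is.null(expect_rois) && n != expect_rois)
    stop("atlas mapping has ", n, " ROIs, expected ", expect_rois)
  if (!is.null(expect_areas) && length(unique(df$area)) != expect_areas)
    stop("atlas mapping has ", length(unique(df$area)), " areas, expected ",
         expect_areas)
  df <- df[order(df$roi_id), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("area_partition", "data.frame")
  df
}

#' The default 148-ROI / 14-area partition
#'
#' Ships as the editable CSV `inst/extdata/destrieux_14_areas.csv`: each of
#' the 148 standard Destrieux region names (74 per hemisphere) is assigned
#' by anatomical keyword to one of the 14 areas `{VPF, DPF, C, T, P, O,
#' Cing} x {L, R}`.  The assignment is a synthetic default -- no canonical
#' table exists -- and users with their own grouping can point
#' \code{\link{read_area_partition}} at an edited copy.
#'
#' @return an `area_partition` data.frame with 148 rows and 14 areas.
#' @export
#' @examples
#' part <- default_area_partition()
#' table(part$area)
default_area_partition <- function() {
  path <- system.file("extdata", "destrieux_14_areas.csv", package = "mmnnet",
                      mustWork = TRUE)
  read_area_partition(path, expect_rois = 148L, expect_areas = 14L)
}

#' @export
print.area_partition <- function(x, ...) {
  cat(sprintf("<area_partition> %d ROIs in %d areas\n",
              nrow(x), length(unique(x$area))))
  print(table(x$area))
  invisible(x)
}
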