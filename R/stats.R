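# Group-level paired comparisons of the network statistics, mirroring the
# comparison design of the study: Ratio / L_all / S_all and per-area L_k by
# stimulus condition within each consciousness state, and by state within
# each condition.

#' Paired t-test with group summaries
#'
#' Classical paired two-sided t-test on `x - y` (via
#' \code{\link[stats]{t.test}}), reported with per-group mean and standard
#' deviation.  Subjects must be aligned by position; missing values or
#' unequal lengths are errors, never silently dropped, and a zero-variance
#' difference vector is an error (the t statistic is undefined).
#'
#' @param x,y per-subject values of the two paired conditions.
#' @param label optional comparison label.
#' @param alpha significance level for the flag (default 0.05).
#' @return a one-row data.frame of class `group_comparison` with columns
#'   `comparison`, `n`, `mean_x`, `sd_x`, `mean_y`, `sd_y`, `t`, `df`, `p`,
#'   `significant`.
#' @export
#' @examples
#' paired_ttest(c(1, 2, 4), c(0, 1, 2))  # t = 4, df = 2
paired_ttest <- function(x, y, label = "", alpha = 0.05) {
  if (length(x) != length(y))
    stop("paired samples have different lengths (", length(x), " vs ", length(y), ")")
  if (length(x) < 2) stop("paired t-test needs at least 2 subjects")
  if (anyNA(x) || anyNA(y))
    stop("missing subject values in paired comparison '", label, "'")
  d <- x - y
  if (sd(d) == 0)
    stop("zero variance of paired differences in '", label, "': t undefined")
  tt <- stats::t.test(x, y, paired = TRUE)
  out <- data.frame(
    comparison = label, n = length(x),
    mean_x = mean(x), sd_x = sd(x), mean_y = mean(y), sd_y = sd(y),
    t = unname(tt$statistic), df = unname(tt$parameter),
    p = tt$p.value, significant = tt$p.value < alpha,
    stringsAsFactors = FALSE
  )
  class(out) <- c("group_comparison", "data.frame")
  out
}

check_balanced <- function(metrics) {
  need <- c("subject", "condition", "state")
  miss <- setdiff(need, names(metrics))
  if (length(miss)) stop("metrics lack column(s): ", paste(miss, collapse = ", "))
  cells <- expand.grid(condition = c("standard", "deviant"),
                       state = c("awake", "anesthesia"),
                       stringsAsFactors = FALSE)
  subjects <- sort(unique(metrics$subject))
  missing_cells <- character(0)
  for (r in seq_len(nrow(cells))) {
    have <- metrics$subject[metrics$condition == cells$condition[r] &
                              metrics$state == cells$state[r]]
    gone <- setdiff(subjects, have)
    if (length(gone))
      missing_cells <- c(missing_cells,
                         sprintf("%s/%s: subject(s) %s", cells$state[r],
                                 cells$condition[r], paste(gone, collapse = ",")))
    if (anyDuplicated(have))
      stop("duplicated subject rows in cell ", cells$state[r], "/", cells$condition[r])
  }
  if (length(missing_cells))
    stop("unbalanced design, missing cells:\n  ",
         paste(missing_cells, collapse = "\n  "))
  subjects
}

cell_values <- function(metrics, var, condition, state, subjects) {
  sel <- metrics$condition == condition & metrics$state == state
  v <- metrics[[var]][sel][match(subjects, metrics$subject[sel])]
  v
}

#' Build the five families of paired comparison tables
#'
#' Given per-subject network metrics in all four cells (standard/deviant x
#' awake/anesthesia), emits the comparison families of the study design:
#' \describe{
#'   \item{ratio_by_condition}{Ratio, standard vs deviant, within each state.}
#'   \item{global_by_state}{S_all and L_all, awake vs anesthesia, within
#'     each condition.}
#'   \item{global_by_condition}{L_all and S_all, standard vs deviant, within
#'     each state.}
#'   \item{area_by_condition}{per-area L_k, standard vs deviant, within each
#'     state.}
#'   \item{area_by_state}{per-area L_k, awake vs anesthesia, within each
#'     condition.}
#' }
#' Each row reports group means, standard deviations, the paired t
#' statistic (first-named group minus second), degrees of freedom, the
#' two-sided p value and the significance flag at `alpha`.  Tests are
#' uncorrected by default, matching the study design of 14 per-area tests
#' at alpha = 0.05; `adjust = "BH"` switches to Benjamini-Hochberg within
#' each table (with a notice).
#'
#' @param metrics a data.frame with columns `subject`, `condition`
#'   (`standard`/`deviant`), `state` (`awake`/`anesthesia`), `Ratio`,
#'   `L_all`, `S_all` and `L_<area>` columns, one row per cell -- the
#'   format produced by \code{\link{simulate_cohort}} /
#'   \code{\link{run_pipeline}}.
#' @param alpha significance level.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return a named list of data.frames of class `mmn_comparison_tables`.
#' @export
build_comparison_tables <- function(metrics, alpha = 0.05,
                                    adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  hashes <- attr(metrics, "config_hash")
  if (!is.null(hashes) && length(unique(hashes)) > 1)
    stop("refusing to combine metrics produced under different configurations: ",
         paste(unique(hashes), collapse = ", "))
  subjects <- check_balanced(metrics)
  if (length(subjects) < 2) stop("paired t-test needs at least 2 subjects")
  area_cols <- grep("^L_[A-Za-z]", names(metrics), value = TRUE)
  area_cols <- setdiff(area_cols, "L_all")

  cmp_condition <- function(var, state) {
    x <- cell_values(metrics, var, "standard", state, subjects)
    y <- cell_values(metrics, var, "deviant", state, subjects)
    paired_ttest(x, y, label = sprintf("%s %s: standard vs deviant", state, var),
                 alpha = alpha)
  }
  cmp_state <- function(var, condition) {
    x <- cell_values(metrics, var, condition, "awake", subjects)
    y <- cell_values(metrics, var, condition, "anesthesia", subjects)
    paired_ttest(x, y, label = sprintf("%s %s: awake vs anesthesia", condition, var),
                 alpha = alpha)
  }
  tidy <- function(rows, front) {
    tab <- do.call(rbind, rows)
    rownames(tab) <- NULL
    cbind(front, tab[, setdiff(names(tab), "comparison")])
  }

  states <- c("awake", "anesthesia")
  conds <- c("standard", "deviant")
  tables <- list(
    ratio_by_condition = tidy(
      lapply(states, function(s) cmp_condition("Ratio", s)),
      data.frame(state = states, measure = "Ratio")
    ),
    global_by_state = tidy(
      unlist(lapply(c("S_all", "L_all"), function(v)
        lapply(conds, function(cc) cmp_state(v, cc))), recursive = FALSE),
      data.frame(measure = rep(c("S_all", "L_all"), each = 2),
                 condition = rep(conds, 2))
    ),
    global_by_condition = tidy(
      unlist(lapply(states, function(s)
        lapply(c("L_all", "S_all"), function(v) cmp_condition(v, s))),
        recursive = FALSE),
      data.frame(state = rep(states, each = 2),
                 measure = rep(c("L_all", "S_all"), 2))
    ),
    area_by_condition = tidy(
      unlist(lapply(states, function(s)
        lapply(area_cols, function(v) cmp_condition(v, s))), recursive = FALSE),
      data.frame(state = rep(states, each = length(area_cols)),
                 area = rep(sub("^L_", "", area_cols), 2))
    ),
    area_by_state = tidy(
      unlist(lapply(conds, function(cc)
        lapply(area_cols, function(v) cmp_state(v, cc))), recursive = FALSE),
      data.frame(condition = rep(conds, each = length(area_cols)),
                 area = rep(sub("^L_", "", area_cols), 2))
    )
  )
  if (adjust == "BH") {
    message("applying Benjamini-Hochberg correction within each comparison table")
    tables <- lapply(tables, function(tab) {
      tab$p_adj <- stats::p.adjust(tab$p, method = "BH")
      tab$significant <- tab$p_adj < alpha
      tab
    })
  }
  class(tables) <- "mmn_comparison_tables"
  attr(tables, "alpha") <- alpha
  attr(tables, "adjust") <- adjust
  tables
}

#' @export
print.mmn_comparison_tables <- function(x, ...) {
  for (nm in names(x)) {
    cat("==", nm, "==\n")
    tab <- x[[nm]]
    num <- vapply(tab, is.numeric, TRUE)
    tab[num] <- lapply(tab[num], function(v) round(v, 4))
    print(tab, row.names = FALSE)
    cat("\n")
  }
  invisible(x)
}

#' Write comparison tables to CSV files
#'
#' One CSV per table (`<prefix><name>.csv`), columns as printed; a
#' provenance comment line with the package version and config hash (when
#' available) precedes the header.
#'
#' @param tables an `mmn_comparison_tables` list.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @param config_hash optional provenance hash embedded in the files.
#' @return the written paths, invisibly.
#' @export
write_comparison_tables <- function(tables, dir, prefix = "table_",
                                    config_hash = NULL) {
  stopifnot(inherits(tables, "mmn_comparison_tables"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (nm in names(tables)) {
    path <- file.path(dir, paste0(prefix, nm, ".csv"))
    con <- file(path, open = "wt", encoding = "UTF-8")
    writeLines(sprintf("# mmnnet %s%s", as.character(utils::packageVersion("mmnnet")),
                       if (is.null(config_hash)) "" else paste0(" config ", config_hash)),
               con)
    utils::write.table(format(tables[[nm]], digits = 15, trim = TRUE, scientific = FALSE),
                       con, sep = ",", quote = FALSE, row.names = FALSE)
    close(con)
    paths <- c(paths, path)
  }
  invisible(paths)
}
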