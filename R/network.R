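# Density thresholding and long/short-distance connection statistics over
# the 14 cortical areas.

#' Minimum admissible connection density
#'
#' Small-world network integrity requires the average degree to exceed
#' `2 ln N`; the corresponding edge density is `2 ln(N) / (N - 1)`.  For the
#' 148-node parcellation this is about 0.068, conventionally displayed as
#' the truncated integer percent "6%".
#'
#' @param n_nodes number of network nodes (>= 3).
#' @return the density as a fraction, with attribute `percent_label` (the
#'   truncated integer percent used for display).
#' @export
#' @examples
#' minimum_density(148)  # ~0.068, label "6%"
minimum_density <- function(n_nodes) {
  if (n_nodes < 3) stop("n_nodes must be >= 3")
  d <- 2 * log(n_nodes) / (n_nodes - 1)
  structure(d, percent_label = paste0(floor(100 * d), "%"))
}

edges_from_matrix <- function(w) {
  n <- nrow(w)
  ut <- upper.tri(w)
  data.frame(i = row(w)[ut], j = col(w)[ut], w = w[ut])
}

#' Threshold a connectivity matrix to a target edge density
#'
#' Keeps the `floor(density * N(N-1)/2 + 0.5)` strongest off-diagonal
#' weights; ties are broken lexicographically on the ROI index pair for
#' determinism.  Densities below \code{\link{minimum_density}} are allowed
#' but provoke a warning, since such networks may fragment.
#'
#' @param w a `wpli_matrix` or a symmetric numeric matrix.
#' @param density target edge density in `(0, 1]`.
#' @return an object of class `thresholded_graph`: list with `edges`
#'   (data.frame `i`, `j`, `w`, strongest first), `density`, `n_nodes`,
#'   `n_kept`, `total_weight`.
#' @export
threshold_by_density <- function(w, density) {
  wm <- if (inherits(w, "wpli_matrix")) w$w else w
  stopifnot(is.matrix(wm), nrow(wm) == ncol(wm))
  if (!(density > 0 && density <= 1)) stop("density must lie in (0, 1]")
  n <- nrow(wm)
  dmin <- minimum_density(n)
  if (density < dmin)
    warning(sprintf("density %.3f is below the minimum density %.3f (average degree 2 ln N)",
                    density, dmin))
  ed <- edges_from_matrix(wm)
  ed <- ed[order(-ed$w, ed$i, ed$j), , drop = FALSE]
  m <- as.integer(floor(density * n * (n - 1) / 2 + 0.5))
  kept <- ed[seq_len(m), , drop = FALSE]
  rownames(kept) <- NULL
  structure(list(edges = kept, density = density, n_nodes = n,
                 n_kept = m, total_weight = sum(kept$w)),
            class = "thresholded_graph")
}

#' @export
print.thresholded_graph <- function(x, ...) {
  cat(sprintf("<thresholded_graph> %d nodes, %d/%d edges kept (density %.3f), total weight %.3f\n",
              x$n_nodes, x$n_kept, x$n_nodes * (x$n_nodes - 1) / 2,
              x$density, x$total_weight))
  invisible(x)
}

area_lookup <- function(partition, n_nodes) {
  stopifnot(is.data.frame(partition), all(c("roi_id", "area") %in% names(partition)))
  a <- partition$area[match(seq_len(n_nodes), partition$roi_id)]
  if (anyNA(a)) stop("partition does not cover ROI(s): ",
                     paste(which(is.na(a)), collapse = ", "))
  a
}

#' Long/short-distance connection statistics of a thresholded network
#'
#' An edge is \emph{short-distance} when both endpoints lie in the same one
#' of the 14 cortical areas and \emph{long-distance} otherwise.  Per area
#' `k`, `S_k` sums the kept weights of its internal edges and `L_k` sums
#' the kept weights of edges with exactly one endpoint in area `k`.  The
#' whole-brain totals are `L_all = sum(L_k)` -- every inter-area edge
#' therefore counts towards both endpoint areas -- `S_all = sum(S_k)` and
#' `Ratio = L_all / S_all`.  The conservation identity
#' `S_all + L_all / 2 = total kept weight` always holds.  When `S_all` is 0
#' the Ratio is undefined and returned as `NA` with a warning.
#'
#' @param graph a `thresholded_graph`.
#' @param partition an area partition data.frame (`roi_id`, `area`), see
#'   \code{\link{default_area_partition}}.
#' @return an object of class `connection_metrics`: list with named vectors
#'   `L_k`, `S_k`, scalars `L_all`, `S_all`, `Ratio`, and the `density`.
#' @export
#' @examples
#' w <- matrix(0, 4, 4)
#' w[1, 2] <- w[2, 1] <- 0.9; w[3, 4] <- w[4, 3] <- 0.8
#' w[1, 3] <- w[3, 1] <- 0.5; w[2, 4] <- w[4, 2] <- 0.3
#' part <- data.frame(roi_id = 1:4, area = c("A", "A", "B", "B"))
#' m <- area_metrics(threshold_by_density(w, 2 / 3), part)
#' m$Ratio  # 1.6 / 1.7
area_metrics <- function(graph, partition) {
  stopifnot(inherits(graph, "thresholded_graph"))
  a <- area_lookup(partition, graph$n_nodes)
  areas <- sort(unique(partition$area))
  e <- graph$edges
  ai <- a[e$i]
  aj <- a[e$j]
  intra <- ai == aj
  S_k <- vapply(areas, function(k) sum(e$w[intra & ai == k]), 0)
  L_k <- vapply(areas, function(k) sum(e$w[!intra & (ai == k | aj == k)]), 0)
  S_all <- sum(S_k)
  L_all <- sum(L_k)
  ratio <- if (S_all == 0) {
    warning("S_all is 0: Ratio undefined, returning NA")
    NA_real_
  } else L_all / S_all
  structure(list(L_k = L_k, S_k = S_k, L_all = L_all, S_all = S_all,
                 Ratio = ratio, density = graph$density,
                 n_kept = graph$n_kept, total_weight = graph$total_weight),
            class = "connection_metrics")
}

#' @export
print.connection_metrics <- function(x, ...) {
  cat(sprintf("<connection_metrics> density %.3f: L_all %.3f, S_all %.3f, Ratio %s\n",
              x$density, x$L_all, x$S_all,
              if (is.na(x$Ratio)) "NA" else sprintf("%.3f", x$Ratio)))
  invisible(x)
}

#' Connection metrics across a density sweep
#'
#' Computes \code{\link{area_metrics}} at every density of `grid` (default
#' 6% to 90% in 1% steps) in a single pass: edges are sorted once and the
#' per-area intra/inter weight sums accumulated cumulatively, so the sweep
#' costs no more than one thresholding.  The summary row is the arithmetic
#' mean over the grid (the Ratio mean skips densities where it is
#' undefined).
#'
#' @param w a `wpli_matrix` or symmetric numeric matrix.
#' @param partition area partition data.frame (`roi_id`, `area`).
#' @param grid densities in `(0, 1]`.
#' @return an object of class `connection_sweep`: list with `per_density`
#'   (one row per density: `density`, `L_all`, `S_all`, `Ratio`, `L_<area>`
#'   and `S_<area>` columns) and `summary` (one-row grid mean).
#' @export
density_sweep <- function(w, partition, grid = seq(0.06, 0.90, by = 0.01)) {
  wm <- if (inherits(w, "wpli_matrix")) w$w else w
  stopifnot(is.matrix(wm), nrow(wm) == ncol(wm))
  if (!length(grid)) stop("empty density grid")
  if (any(grid <= 0 | grid > 1)) stop("densities must lie in (0, 1]")
  n <- nrow(wm)
  a <- area_lookup(partition, n)
  areas <- sort(unique(partition$area))
  ed <- edges_from_matrix(wm)
  ed <- ed[order(-ed$w, ed$i, ed$j), , drop = FALSE]
  ai <- a[ed$i]
  aj <- a[ed$j]
  intra <- ai == aj
  n_pairs <- nrow(ed)

  cum_S <- sapply(areas, function(k) cumsum(ed$w * (intra & ai == k)))
  cum_L <- sapply(areas, function(k) cumsum(ed$w * (!intra & (ai == k | aj == k))))
  cum_tot <- cumsum(ed$w)

  m_of <- function(d) floor(d * n_pairs + 0.5)
  rows <- lapply(grid, function(d) {
    m <- m_of(d)
    S_k <- if (m > 0) cum_S[m, ] else rep(0, length(areas))
    L_k <- if (m > 0) cum_L[m, ] else rep(0, length(areas))
    S_all <- sum(S_k)
    L_all <- sum(L_k)
    c(density = d, L_all = L_all, S_all = S_all,
      Ratio = if (S_all == 0) NA_real_ else L_all / S_all,
      stats::setNames(L_k, paste0("L_", areas)),
      stats::setNames(S_k, paste0("S_", areas)))
  })
  per_density <- as.data.frame(do.call(rbind, rows))
  if (anyNA(per_density$Ratio))
    warning("Ratio undefined (S_all = 0) at ", sum(is.na(per_density$Ratio)),
            " density value(s)")
  summary <- per_density[1, , drop = FALSE]
  summary[1, ] <- colMeans(per_density, na.rm = TRUE)
  summary$density <- NA_real_
  rownames(summary) <- "grid_mean"
  structure(list(per_density = per_density, summary = summary, grid = grid,
                 n_nodes = n, areas = areas),
            class = "connection_sweep")
}

#' @export
print.connection_sweep <- function(x, ...) {
  cat(sprintf("<connection_sweep> %d densities (%.2f..%.2f) on %d nodes\n",
              length(x$grid), min(x$grid), max(x$grid), x$n_nodes))
  cat(sprintf("  grid-mean: L_all %.3f, S_all %.3f, Ratio %.3f\n",
              x$summary$L_all, x$summary$S_all, x$summary$Ratio))
  invisible(x)
}

#' Plot a density sweep
#'
#' L_all, S_all and Ratio as functions of connection density.
#'
#' @param x a `connection_sweep`.
#' @param ... passed to \code{\link[graphics]{matplot}}.
#' @return `x`, invisibly.
#' @export
plot.connection_sweep <- function(x, ...) {
  pd <- x$per_density
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::matplot(pd$density, cbind(pd$L_all, pd$S_all), type = "l", lty = 1,
                    col = c("firebrick", "steelblue"),
                    xlab = "density", ylab = "summed wPLI", ...)
  graphics::legend("topleft", c("L_all", "S_all"), lty = 1,
                   col = c("firebrick", "steelblue"), bty = "n")
  graphics::plot(pd$density, pd$Ratio, type = "l", xlab = "density", ylab = "Ratio")
  invisible(x)
}
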