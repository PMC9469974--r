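#' Percentile training-presence threshold of a suitability surface
#'
#' The 10-percentile training-presence rule: the threshold is the
#' suitability value below which 10% of the presence points used to train
#' the distribution model fall; cells at or above it are classed suitable.
#' The default convention takes the k-th smallest presence suitability with
#' k = ceiling(percentile * n); `method = "interp"` uses the linearly
#' interpolated percentile instead.
#'
#' @param suitability A [raster_layer()] in \[0, 1\].
#' @param presences Data.frame with projected `x`, `y` of presence points.
#' @param percentile Training-presence percentile (default 0.10).
#' @param method `"order"` (k-th order statistic) or `"interp"`.
#' @return The threshold tau.
#' @export
ten_percentile_threshold <- function(suitability, presences,
                                     percentile = 0.10,
                                     method = c("order", "interp")) {
  method <- match.arg(method)
  cells <- cell_from_xy(suitability$grid, presences$x, presences$y)
  vals <- suitability$values[cells[!is.na(cells)]]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0)
    stop("no presence falls on a non-nodata suitability cell")
  if (method == "order") {
    k <- ceiling(percentile * length(vals))
    sort(vals)[max(1L, k)]
  } else {
    unname(stats::quantile(vals, percentile, type = 7))
  }
}

#' Binarize a suitability surface at a threshold
#'
#' @param suitability A [raster_layer()].
#' @param tau Threshold; cells with value >= tau become 1, others 0. Nodata
#'   propagates.
#' @return A binary [raster_layer()].
#' @export
binarize <- function(suitability, tau) {
  if (!is.finite(tau)) stop("tau must be finite")
  v <- suitability$values
  out <- ifelse(is.na(v), NA_real_, as.numeric(v >= tau))
  raster_layer(out, suitability$grid)
}

#' Restrict a binary habitat map to natural land cover
#'
#' @param binary Binary [raster_layer()] (output of [binarize()]).
#' @param landcover Categorical [raster_layer()] on the same grid.
#' @param natural_classes Land-cover class values catalogued as natural.
#' @return Binary [raster_layer()]: 1 iff suitable AND natural.
#' @export
mask_natural <- function(binary, landcover, natural_classes) {
  stopifnot_same_grid(binary, landcover)
  v <- binary$values
  nat <- matrix(landcover$values %in% natural_classes,
                nrow(v), ncol(v))
  out <- ifelse(is.na(v), NA_real_, as.numeric(v > 0 & nat))
  raster_layer(out, binary$grid)
}

#' Extract habitat cores from a binary habitat raster
#'
#' Connected components of suitable natural cells become candidate patches;
#' those meeting the minimum-area rule become habitat cores, numbered in
#' decreasing area order. The default minimum of 17 km^2 corresponds to one
#' maximum reported home range, i.e. patches viable for at least one
#' individual; the default queen (8) adjacency keeps diagonally touching
#' habitat joined, consistent with diagonal corridor moves.
#'
#' @param binary Binary [raster_layer()].
#' @param min_area_km2 Minimum core area in km^2 (inclusive; default 17).
#' @param connectivity 4 or 8 (default 8).
#' @return A `core_set`: list with `cores` (data.frame `core_id`, `n_cells`,
#'   `area_km2`), `cells` (list of cell-index vectors, parallel to `cores`),
#'   `discards` (data.frame of sub-threshold components), `labels` (label
#'   matrix), `grid`, `connectivity`.
#' @export
extract_cores <- function(binary, min_area_km2 = 17, connectivity = 8) {
  if (!is.finite(min_area_km2) || min_area_km2 <= 0)
    stop("min_area_km2 must be positive")
  g <- binary$grid
  labels <- label_components(binary$values, connectivity)
  ca <- cell_area_km2(g)
  empty <- list(
    cores = data.frame(core_id = integer(), n_cells = integer(),
                       area_km2 = numeric()),
    cells = list(),
    discards = data.frame(n_cells = integer(), area_km2 = numeric()),
    labels = labels, grid = g, connectivity = connectivity
  )
  n_comp <- max(labels)
  if (n_comp == 0) return(structure(empty, class = "core_set"))
  sizes <- tabulate(labels[labels > 0L], nbins = n_comp)
  areas <- sizes * ca
  keep <- which(areas >= min_area_km2)
  keep <- keep[order(-areas[keep], keep)]
  drop <- which(areas < min_area_km2)
  cells_by_comp <- split(seq_along(labels)[labels > 0L], labels[labels > 0L])
  structure(list(
    cores = data.frame(core_id = seq_along(keep),
                       n_cells = sizes[keep],
                       area_km2 = areas[keep]),
    cells = unname(cells_by_comp[as.character(keep)]),
    discards = data.frame(n_cells = sizes[drop], area_km2 = areas[drop]),
    labels = labels, grid = g, connectivity = connectivity
  ), class = "core_set")
}

#' @export
print.core_set <- function(x, ...) {
  cat(sprintf("<core_set> %d cores (%.2f km2 total), %d sub-threshold components\n",
              nrow(x$cores), sum(x$cores$area_km2), nrow(x$discards)))
  invisible(x)
}

#' Per-core and whole-landscape habitat statistics
#'
#' @param cores A `core_set` from [extract_cores()].
#' @param footprint Human-footprint [raster_layer()] on the same grid.
#' @param top_k How many largest cores to report the cumulative area share
#'   of (default 12).
#' @return List: `per_core` (`core_id`, `n_cells`, `area_km2`,
#'   `mean_footprint`), `summary` (count, mean/sd area, total area, share
#'   of total area in the `top_k` largest cores), `size_classes` (counts in
#'   <20, 20-100, 100-1000, >=1000 km2).
#' @export
core_statistics <- function(cores, footprint, top_k = 12) {
  if (!same_grid(cores$grid, footprint$grid))
    stop("footprint raster is not on the core grid")
  per <- cores$cores
  per$mean_footprint <- vapply(
    cores$cells, function(cl) mean(footprint$values[cl], na.rm = TRUE),
    numeric(1)
  )
  if (nrow(per) == 0) per$mean_footprint <- numeric(0)
  breaks <- c(0, 20, 100, 1000, Inf)
  labs <- c("<20", "20-100", "100-1000", ">=1000")
  counts <- if (nrow(per)) table(cut(per$area_km2, breaks, labs, right = FALSE))
            else stats::setNames(rep(0L, 4), labs)
  total <- sum(per$area_km2)
  top_share <- if (nrow(per)) {
    sum(utils::head(sort(per$area_km2, decreasing = TRUE), top_k)) /
      max(total, .Machine$double.eps)
  } else 0
  list(
    per_core = per,
    summary = list(
      n_cores = nrow(per),
      mean_area_km2 = if (nrow(per)) mean(per$area_km2) else NA_real_,
      sd_area_km2 = if (nrow(per) > 1) stats::sd(per$area_km2) else NA_real_,
      total_area_km2 = total,
      top_k = top_k,
      top_k_share = top_share
    ),
    size_classes = data.frame(class = labs, n = as.integer(counts))
  )
}
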