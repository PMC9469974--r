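# exact area of the union of axis-aligned rectangles, by coordinate
# compression: partition the bounding box by every rectangle edge and sum
# the sub-cells covered by at least one rectangle
rect_union_area <- function(xmin, xmax, ymin, ymax) {
  keep <- xmax > xmin & ymax > ymin
  xmin <- xmin[keep]; xmax <- xmax[keep]
  ymin <- ymin[keep]; ymax <- ymax[keep]
  n <- length(xmin)
  if (n == 0) return(0)
  if (n == 1) return((xmax - xmin) * (ymax - ymin))
  xs <- sort(unique(c(xmin, xmax)))
  ys <- sort(unique(c(ymin, ymax)))
  wx <- diff(xs); wy <- diff(ys)
  xc <- (xs[-1] + xs[-length(xs)]) / 2
  yc <- (ys[-1] + ys[-length(ys)]) / 2
  covered <- matrix(FALSE, length(xc), length(yc))
  for (i in seq_len(n)) {
    ix <- xc > xmin[i] & xc < xmax[i]
    iy <- yc > ymin[i] & yc < ymax[i]
    covered[ix, iy] <- TRUE
  }
  sum(outer(wx, wy) * covered)
}

# clip rectangles b against one rectangle a; returns clipped rects (may be
# degenerate, filtered by rect_union_area)
clip_rects <- function(ax0, ax1, ay0, ay1, bx0, bx1, by0, by1) {
  data.frame(xmin = pmax(ax0, bx0), xmax = pmin(ax1, bx1),
             ymin = pmax(ay0, by0), ymax = pmin(ay1, by1))
}

#' Overlay protected areas on habitat cores
#'
#' Computes, exactly (analytic rectangle clipping on the square-cell core
#' geometry), the intersection area of every (core, protected area) pair
#' with positive overlap, and the per-core protected proportion p_i from
#' the geometric *union* of all protected areas (double counting of
#' overlapping protected areas removed).
#'
#' @param cores A `core_set` from [extract_cores()].
#' @param pas Protected-area table (rectangles: `pa_id`, `xmin`, `xmax`,
#'   `ymin`, `ymax` plus attributes; see [generate_protected_areas()]).
#' @return List: `pairs` (data.frame `core_id`, `pa_id`, `area_km2`),
#'   `per_core` (`core_id`, `area_km2`, `protected_km2`, `p`), `pas`.
#' @export
overlay_protection <- function(cores, pas) {
  if (nrow(pas) > 0) {
    bad <- pas$xmax <= pas$xmin | pas$ymax <= pas$ymin
    if (any(bad))
      stop("invalid (empty) protected-area geometry: ",
           paste(pas$pa_id[bad], collapse = ", "))
  }
  g <- cores$grid
  per_core <- cores$cores[, c("core_id", "area_km2")]
  per_core$protected_km2 <- 0
  per_core$p <- 0
  pairs <- data.frame(core_id = integer(), pa_id = character(),
                      area_km2 = numeric())
  if (nrow(pas) == 0 || nrow(per_core) == 0)
    return(list(pairs = pairs, per_core = per_core, pas = pas))

  for (i in seq_len(nrow(per_core))) {
    rects <- cell_rect(g, cores$cells[[i]])
    # per-PA intersection with this core's cells (vectorised over cells)
    for (j in seq_len(nrow(pas))) {
      w <- pmin(rects$xmax, pas$xmax[j]) - pmax(rects$xmin, pas$xmin[j])
      h <- pmin(rects$ymax, pas$ymax[j]) - pmax(rects$ymin, pas$ymin[j])
      a <- sum(pmax(0, w) * pmax(0, h)) / 1e6
      if (a > 1e-6 * 1e-6)  # geometric tolerance for zero-area slivers
        pairs <- rbind(pairs, data.frame(core_id = per_core$core_id[i],
                                         pa_id = pas$pa_id[j], area_km2 = a))
    }
    # union over PAs: per-cell clipped areas are vectorised per PA; only
    # cells overlapped by two or more PAs need the exact rectangle union
    touching <- which(pas$xmin < max(rects$xmax) & pas$xmax > min(rects$xmin) &
                      pas$ymin < max(rects$ymax) & pas$ymax > min(rects$ymin))
    if (length(touching)) {
      nc <- nrow(rects)
      areas <- matrix(0, nc, length(touching))
      for (k in seq_along(touching)) {
        j <- touching[k]
        w <- pmax(0, pmin(rects$xmax, pas$xmax[j]) - pmax(rects$xmin, pas$xmin[j]))
        h <- pmax(0, pmin(rects$ymax, pas$ymax[j]) - pmax(rects$ymin, pas$ymin[j]))
        areas[, k] <- w * h
      }
      hit <- areas > 0
      n_hit <- rowSums(hit)
      u <- sum(areas[n_hit == 1L, , drop = FALSE])
      for (cidx in which(n_hit >= 2L)) {
        js <- touching[hit[cidx, ]]
        cl <- clip_rects(rects$xmin[cidx], rects$xmax[cidx],
                         rects$ymin[cidx], rects$ymax[cidx],
                         pas$xmin[js], pas$xmax[js],
                         pas$ymin[js], pas$ymax[js])
        u <- u + rect_union_area(cl$xmin, cl$xmax, cl$ymin, cl$ymax)
      }
      per_core$protected_km2[i] <- u / 1e6
      per_core$p[i] <- min(1, (u / 1e6) / per_core$area_km2[i])
    }
  }
  list(pairs = pairs, per_core = per_core, pas = pas)
}

#' Protection breakdown from a protected-area attribute table
#'
#' Pure-arithmetic gap-analysis summary: given per-protected-area (or
#' per-category) protected areas in km^2 and the total range area, reports
#' the total protected share and its decomposition by governance level,
#' protection type and land regime, plus a per-category table. Percentages
#' are reported with half-up rounding to 2 decimals alongside the raw
#' values. Note the additive convention: each protected area's area counts
#' independently, so category rows sum to the column total even where
#' protected areas overlap on the ground.
#'
#' @param pa_table Data.frame with `level`, `category`, `protection`,
#'   `regime`, `area_km2` and optionally `n_areas` (default 1 per row).
#' @param total_range_km2 Total range (or total core habitat) area, > 0.
#' @return List: `total_km2`, `n_areas`, `pct_total`, `pct_by_level`,
#'   `pct_by_protection`, `pct_by_regime`, `by_category` (data.frame),
#'   and `raw` (unrounded percentages).
#' @export
protection_breakdown <- function(pa_table, total_range_km2) {
  if (!is.finite(total_range_km2) || total_range_km2 <= 0)
    stop("total_range_km2 must be positive")
  if (is.null(pa_table$n_areas)) pa_table$n_areas <- 1L
  pct <- function(a) 100 * a / total_range_km2
  agg <- function(field) {
    s <- tapply(pa_table$area_km2, pa_table[[field]], sum)
    stats::setNames(round_half_up(pct(as.numeric(s)), 2), names(s))
  }
  agg_raw <- function(field) {
    s <- tapply(pa_table$area_km2, pa_table[[field]], sum)
    stats::setNames(pct(as.numeric(s)), names(s))
  }
  by_cat <- stats::aggregate(
    cbind(area_km2, n_areas) ~ level + category, data = pa_table, FUN = sum)
  by_cat <- by_cat[order(-by_cat$area_km2), ]
  rownames(by_cat) <- NULL
  total <- sum(pa_table$area_km2)
  list(
    total_km2 = total,
    n_areas = sum(pa_table$n_areas),
    pct_total = round_half_up(pct(total), 2),
    pct_by_level = agg("level"),
    pct_by_protection = agg("protection"),
    pct_by_regime = agg("regime"),
    by_category = by_cat,
    raw = list(pct_total = pct(total), pct_by_level = agg_raw("level"),
               pct_by_protection = agg_raw("protection"),
               pct_by_regime = agg_raw("regime"))
  )
}

#' Full protection report for a core set
#'
#' Combines the geometric overlay with the attribute breakdown. Headline
#' per-core coverage uses the geometric union of protected areas (no double
#' counting), while the category/level/regime decomposition counts each
#' protected area's intersection independently, so its rows sum to the
#' sum-of-intersections total — the dual convention of national
#' protected-area accounting tables.
#'
#' @param overlay Result of [overlay_protection()].
#' @param total_range_km2 Denominator for percentages; defaults to the
#'   total core area.
#' @return List: `breakdown` (see [protection_breakdown()]; on per-PA
#'   intersection areas), `per_core`, `n_protected_cores`,
#'   `fraction_protected_cores`, `mean_p`, `sd_p`, `mean_pas_per_core`,
#'   `sd_pas_per_core`, `union_km2` (union-based protected area inside
#'   cores), `total_range_km2`.
#' @export
protection_summary <- function(overlay, total_range_km2 = NULL) {
  per_core <- overlay$per_core
  if (is.null(total_range_km2)) total_range_km2 <- sum(per_core$area_km2)
  pairs <- overlay$pairs
  n_pas_per_core <- rep(0L, nrow(per_core))
  if (nrow(pairs)) {
    tab <- table(factor(pairs$core_id, levels = per_core$core_id))
    n_pas_per_core <- as.integer(tab)
  }
  breakdown <- if (nrow(pairs)) {
    per_pa <- stats::aggregate(area_km2 ~ pa_id, data = pairs, FUN = sum)
    attrs <- overlay$pas[match(per_pa$pa_id, overlay$pas$pa_id),
                         c("level", "category", "protection", "regime")]
    protection_breakdown(cbind(per_pa, attrs), total_range_km2)
  } else NULL
  list(
    breakdown = breakdown,
    per_core = per_core,
    n_protected_cores = sum(per_core$p > 0),
    fraction_protected_cores = if (nrow(per_core))
      sum(per_core$p > 0) / nrow(per_core) else NA_real_,
    mean_p = if (nrow(per_core)) mean(per_core$p) else NA_real_,
    sd_p = if (nrow(per_core) > 1) stats::sd(per_core$p) else NA_real_,
    mean_pas_per_core = if (nrow(per_core)) mean(n_pas_per_core) else NA_real_,
    sd_pas_per_core = if (nrow(per_core) > 1) stats::sd(n_pas_per_core)
                      else NA_real_,
    union_km2 = sum(per_core$protected_km2),
    total_range_km2 = total_range_km2
  )
}

#' Temporal evolution of protected-area coverage over cores
#'
#' For each establishment year present in the protected-area table, the
#' cumulative protected area inside cores (geometric union of all
#' protected areas established up to and including that year) and the
#' cumulative number of distinct cores touched. Both series are monotone
#' non-decreasing. Protected areas without a year are excluded with a
#' warning.
#'
#' @param cores A `core_set`.
#' @param pas Protected-area table with a `year` column.
#' @return Data.frame: `year`, `protected_km2`, `n_cores`.
#' @export
temporal_protection <- function(cores, pas) {
  if (nrow(pas) == 0)
    return(data.frame(year = integer(), protected_km2 = numeric(),
                      n_cores = integer()))
  if (any(is.na(pas$year))) {
    warning(sum(is.na(pas$year)),
            " protected area(s) without establishment year excluded")
    pas <- pas[!is.na(pas$year), , drop = FALSE]
  }
  years <- sort(unique(pas$year))
  rows <- lapply(years, function(y) {
    ov <- overlay_protection(cores, pas[pas$year <= y, , drop = FALSE])
    data.frame(year = y,
               protected_km2 = sum(ov$per_core$protected_km2),
               n_cores = sum(ov$per_core$p > 0))
  })
  do.call(rbind, rows)
}

#' Load the bundled national protected-area accounting table
#'
#' A per-category summary (governance level, category, protection type,
#' land regime, protected area in km^2 and number of areas) of the
#' protected-area system overlapping the species range, as used for the
#' arithmetic gap-analysis checks.
#'
#' @param path CSV path; defaults to the copy shipped with the package.
#' @return Data.frame suitable for [protection_breakdown()].
#' @export
load_pa_summary <- function(path = system.file(
    "extdata", "protected_areas_national_summary.csv", package = "coreconn")) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Load the bundled stronghold protected-area table
#'
#' The named large protected areas (seven national parks plus one regional
#' natural park) that together account for the largest share of protected
#' range.
#'
#' @param path CSV path; defaults to the copy shipped with the package.
#' @return Data.frame: `name`, `level`, `area_km2`.
#' @export
load_strongholds <- function(path = system.file(
    "extdata", "stronghold_areas.csv", package = "coreconn")) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
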