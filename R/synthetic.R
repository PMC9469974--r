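#' Simulation configuration for the synthetic landscape generator
#'
#' Bundles every knob of the synthetic world: grid geometry, spatial
#' autocorrelation of the random fields, planted habitat patches, the
#' human-footprint background, occurrence-record metadata frequencies and
#' protected-area counts. Two runs with an identical configuration are
#' bit-identical. Categorical draws use one seeded generator stream in a
#' documented order (landscape, then records, then protected areas), each
#' stage re-seeded from `seed` + a fixed stage offset so a stage can be
#' regenerated on its own.
#'
#' @param seed Integer seed fixing every draw.
#' @param grid A [grid_spec()].
#' @param autocorr_length Gaussian smoothing scale of the random fields, in
#'   metres. Default 5000 m gives landscape-scale structure on a 1-km grid.
#' @param n_planted_patches Number of planted high-suitability natural
#'   patches with known geometry.
#' @param patch_area_range Min/max planted patch area in km^2. The default
#'   spans the minimum-core rule (17 km^2) up to mid-sized patches.
#' @param footprint_background Named numeric `c(mean=, spread=)` of the
#'   0-100 human-footprint index outside planted patches.
#' @param n_records Number of occurrence records to draw.
#' @param metadata_frequencies List with named probability vectors
#'   `evidence`, `source`, `precision`; each must sum to 1 over the
#'   recognised categories (see [classify_reliability()]).
#' @param coordinate_error_fraction Probability that a record's coordinates
#'   are missing (blank locality), as happens in compiled museum datasets.
#' @param n_protected_areas Number of rectangular protected areas.
#' @param pa_year_range Min/max establishment year.
#' @param background_max Upper bound of background (unplanted) suitability;
#'   kept below `design_threshold` so planted structure is recoverable.
#' @param patch_suitability Min/max suitability assigned inside planted
#'   patches.
#' @param design_threshold The generator's design suitability threshold:
#'   planted patches always exceed it, background never does.
#' @param natural_background_prob Fraction of the background catalogued as
#'   natural cover.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed,
                       grid = grid_spec(100, 100, 1000),
                       autocorr_length = 5000,
                       n_planted_patches = 5,
                       patch_area_range = c(17, 60),
                       footprint_background = c(mean = 40, spread = 25),
                       n_records = 200,
                       metadata_frequencies = default_metadata_frequencies(),
                       coordinate_error_fraction = 0.05,
                       n_protected_areas = 8,
                       pa_year_range = c(1938, 2018),
                       background_max = 0.45,
                       patch_suitability = c(0.75, 0.95),
                       design_threshold = 0.5) {
  stopifnot(inherits(grid, "grid_spec"))
  if (coordinate_error_fraction < 0 || coordinate_error_fraction > 1)
    stop("coordinate_error_fraction must be in [0, 1]")
  for (nm in c("evidence", "source", "precision")) {
    p <- metadata_frequencies[[nm]]
    if (is.null(p) || any(p < 0) || abs(sum(p) - 1) > 1e-8)
      stop("metadata_frequencies$", nm, " must be non-negative and sum to 1")
  }
  if (n_records < 0) stop("n_records must be non-negative")
  if (n_protected_areas > 0 && (length(pa_year_range) != 2 ||
                                pa_year_range[2] < pa_year_range[1]))
    stop("pa_year_range must be a non-empty year interval")
  if (background_max >= design_threshold)
    warning("background_max >= design_threshold: planted patches will not ",
            "be separable from background at the design threshold")
  structure(list(
    seed = as.integer(seed), grid = grid, autocorr_length = autocorr_length,
    n_planted_patches = n_planted_patches, patch_area_range = patch_area_range,
    footprint_background = footprint_background, n_records = n_records,
    metadata_frequencies = metadata_frequencies,
    coordinate_error_fraction = coordinate_error_fraction,
    n_protected_areas = n_protected_areas, pa_year_range = pa_year_range,
    background_max = background_max, patch_suitability = patch_suitability,
    design_threshold = design_threshold,
    natural_background_prob = 0.6
  ), class = "sim_config")
}

#' Default record-metadata category frequencies
#'
#' A realistic mix for a compiled national carnivore dataset: museum
#' specimens and camera-trap (machine) records dominate the reliable end,
#' with a tail of human observations and imprecise localities.
#' @return Named list of probability vectors.
#' @export
default_metadata_frequencies <- function() {
  list(
    evidence = c(preserved_specimen = 0.25, machine_observation = 0.30,
                 material_sample = 0.15, human_observation = 0.25,
                 no_data = 0.05),
    source = c(peer_reviewed = 0.30, expert_validated = 0.20, museum = 0.20,
               gbif = 0.20, technical = 0.10),
    precision = c(dept_and_municipality = 0.50, department = 0.20,
                  municipality = 0.20, none = 0.10)
  )
}

# white noise convolved with a separable Gaussian kernel, replicate-padded
# at the edges; the standard quick neutral-landscape construction
gaussian_smooth <- function(m, sigma_cells) {
  if (sigma_cells <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma_cells))
  k <- stats::dnorm(seq(-r, r), sd = sigma_cells)
  k <- k / sum(k)
  pad <- function(v) c(rep(v[1], r), v, rep(v[length(v)], r))
  conv1 <- function(v) {
    out <- stats::filter(pad(v), k, sides = 2)
    as.numeric(out[(r + 1):(r + length(v))])
  }
  m <- apply(m, 2, conv1)            # down columns
  t(apply(m, 1, conv1))              # along rows
}

rescale01 <- function(m) {
  rng <- range(m, na.rm = TRUE)
  if (diff(rng) == 0) return(m * 0)
  (m - rng[1]) / diff(rng)
}

# place n non-overlapping near-square patches of the requested cell counts,
# separated by >= 2 cells so component recovery is unambiguous
place_patches <- function(grid, n_cells_wanted) {
  nr <- grid$n_rows; nc <- grid$n_cols
  occupied <- matrix(FALSE, nr, nc)   # patch cells plus their buffer
  cells_list <- vector("list", length(n_cells_wanted))
  for (i in seq_along(n_cells_wanted)) {
    n_cells <- n_cells_wanted[i]
    w <- max(1L, round(sqrt(n_cells)))
    h <- ceiling(n_cells / w)
    if (w > nc || h > nr)
      stop("patch of ", n_cells, " cells exceeds grid capacity")
    placed <- FALSE
    for (try in 1:500) {
      r0 <- sample.int(nr - h + 1L, 1L)
      c0 <- sample.int(nc - w + 1L, 1L)
      rb <- max(1L, r0 - 2L):min(nr, r0 + h + 1L)
      cb <- max(1L, c0 - 2L):min(nc, c0 + w + 1L)
      if (any(occupied[rb, cb])) next
      rows <- rep(r0:(r0 + h - 1L), each = w)
      cols <- rep(c0:(c0 + w - 1L), times = h)
      keep <- seq_len(n_cells)        # trim trailing cells of the last row
      cells <- (rows[keep] + (cols[keep] - 1L) * nr)
      occupied[rb, cb] <- TRUE
      cells_list[[i]] <- sort(cells)
      placed <- TRUE
      break
    }
    if (!placed)
      stop("could not place ", length(n_cells_wanted),
           " patches: patch areas exceed grid capacity")
  }
  cells_list
}

#' Generate a synthetic landscape pack
#'
#' Produces, on one shared grid: a continuous habitat-suitability surface in
#' \[0, 1\] (smoothed white noise with planted high-suitability patches of
#' known geometry), a categorical land-cover raster with a natural/
#' transformed flag, a 0-100 human-footprint raster (low inside planted
#' patches, higher outside) and a registry of the planted patches.
#'
#' @param config A [sim_config()].
#' @return A `landscape_pack` list with elements `suitability`, `landcover`,
#'   `footprint` (all [raster_layer()]), `natural_classes`, `patch_registry`
#'   (data.frame: `patch_id`, `n_cells`, `area_km2`), `patch_cells` (list of
#'   cell-index vectors), `grid` and `config`.
#' @export
generate_landscape <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  g <- config$grid
  set.seed(config$seed)
  nr <- g$n_rows; nc <- g$n_cols
  sigma <- config$autocorr_length / g$cell_size

  suit <- rescale01(gaussian_smooth(matrix(stats::rnorm(nr * nc), nr, nc), sigma)) *
    config$background_max
  nat_field <- rescale01(gaussian_smooth(matrix(stats::rnorm(nr * nc), nr, nc), sigma))
  fp_field <- rescale01(gaussian_smooth(matrix(stats::rnorm(nr * nc), nr, nc), sigma))

  # land cover: 1 montane forest (natural), 2 paramo/shrub (natural),
  # 3 cropland/pasture, 4 built-up
  lc <- matrix(3, nr, nc)
  natural_bg <- nat_field >= stats::quantile(nat_field,
                                             1 - config$natural_background_prob)
  lc[natural_bg] <- ifelse(nat_field[natural_bg] >
                             stats::quantile(nat_field, 0.85), 2, 1)
  lc[!natural_bg & fp_field > stats::quantile(fp_field, 0.95)] <- 4

  fb <- config$footprint_background
  fp <- fb[["mean"]] + (fp_field - 0.5) * 2 * fb[["spread"]]
  fp[] <- pmin(100, pmax(0, fp))   # clamp in place to keep matrix dims

  registry <- data.frame(patch_id = integer(), n_cells = integer(),
                         area_km2 = numeric())
  patch_cells <- list()
  if (config$n_planted_patches > 0) {
    areas <- stats::runif(config$n_planted_patches,
                          config$patch_area_range[1], config$patch_area_range[2])
    n_cells <- pmax(1L, round(areas / cell_area_km2(g)))
    patch_cells <- place_patches(g, n_cells)
    for (i in seq_along(patch_cells)) {
      cl <- patch_cells[[i]]
      suit[cl] <- stats::runif(length(cl), config$patch_suitability[1],
                               config$patch_suitability[2])
      lc[cl] <- 1
      fp[cl] <- fp[cl] * 0.2          # footprint is low inside intact habitat
    }
    registry <- data.frame(patch_id = seq_along(patch_cells),
                           n_cells = lengths(patch_cells),
                           area_km2 = lengths(patch_cells) * cell_area_km2(g))
  }

  structure(list(
    suitability = raster_layer(suit, g),
    landcover = raster_layer(lc, g),
    footprint = raster_layer(fp, g),
    natural_classes = c(1, 2),
    patch_registry = registry,
    patch_cells = patch_cells,
    grid = g,
    config = config
  ), class = "landscape_pack")
}

#' Draw synthetic occurrence records over a landscape
#'
#' Locations are sampled with probability proportional to suitability and
#' jittered within their cell; each record carries evidence, source and
#' geographic-precision attributes drawn from the configured frequencies. A
#' `coordinate_error_fraction` share of rows has blank coordinates,
#' mimicking compiled records without usable localities.
#'
#' @param pack A `landscape_pack`.
#' @param config The same [sim_config()] used to build the pack.
#' @return Data.frame: `record_id`, `x`, `y`, `year`, `evidence`, `source`,
#'   `precision`.
#' @export
generate_occurrences <- function(pack, config) {
  if (config$n_records < 0) stop("n_records must be non-negative")
  set.seed(config$seed + 1L)         # record stage of the seeded stream
  n <- config$n_records
  cols <- c("record_id", "x", "y", "year", "evidence", "source", "precision")
  if (n == 0) {
    df <- data.frame(record_id = character(), x = numeric(), y = numeric(),
                     year = integer(), evidence = character(),
                     source = character(), precision = character())
    return(df[cols])
  }
  g <- pack$grid
  s <- as.numeric(pack$suitability$values)
  s[is.na(s)] <- 0
  cells <- sample.int(length(s), n, replace = TRUE, prob = s)
  ctr <- cell_centers(g, cells)
  jit <- g$cell_size * 0.49
  x <- ctr$x + stats::runif(n, -jit, jit)
  y <- ctr$y + stats::runif(n, -jit, jit)
  mf <- config$metadata_frequencies
  draw <- function(p) sample(names(p), n, replace = TRUE, prob = p)
  missing <- stats::runif(n) < config$coordinate_error_fraction
  x[missing] <- NA_real_
  y[missing] <- NA_real_
  data.frame(
    record_id = sprintf("rec%04d", seq_len(n)),
    x = x, y = y,
    year = sample(1951:2019, n, replace = TRUE),
    evidence = draw(mf$evidence),
    source = draw(mf$source),
    precision = draw(mf$precision)
  )
}

#' Generate synthetic protected areas
#'
#' Rectangular protected areas placed inside the grid extent, attributed
#' with governance level, management category, protection type (dedicated
#' strict protection vs mixed use), land regime (public/private) and an
#' establishment year from `pa_year_range`. The attribute mix mirrors a
#' national system where strict public protection sits at the national
#' level and mixed-use private figures dominate the regional/local levels.
#'
#' @param pack A `landscape_pack`.
#' @param config The same [sim_config()] used to build the pack.
#' @return Data.frame: `pa_id`, `xmin`, `xmax`, `ymin`, `ymax`, `level`,
#'   `category`, `protection`, `regime`, `year`.
#' @export
generate_protected_areas <- function(pack, config) {
  n <- config$n_protected_areas
  empty <- data.frame(pa_id = character(), xmin = numeric(), xmax = numeric(),
                      ymin = numeric(), ymax = numeric(), level = character(),
                      category = character(), protection = character(),
                      regime = character(), year = integer())
  if (n == 0) return(empty)
  if (length(config$pa_year_range) != 2)
    stop("pa_year_range must give a year interval when n_protected_areas > 0")
  set.seed(config$seed + 2L)         # protected-area stage of the stream
  g <- pack$grid
  cs <- g$cell_size
  xmax_g <- g$origin_x + g$n_cols * cs
  ymin_g <- g$origin_y - g$n_rows * cs
  w <- stats::runif(n, 3, 15) * cs
  h <- stats::runif(n, 3, 15) * cs
  x0 <- stats::runif(n, g$origin_x, pmax(g$origin_x, xmax_g - w))
  y0 <- stats::runif(n, ymin_g, pmax(ymin_g, g$origin_y - h))
  level <- sample(c("national", "regional", "local"), n, replace = TRUE,
                  prob = c(0.3, 0.4, 0.3))
  category <- ifelse(level == "national",
                     sample(c("national_park", "flora_fauna_sanctuary"), n,
                            replace = TRUE, prob = c(0.8, 0.2)),
              ifelse(level == "regional",
                     sample(c("regional_park", "integrated_management_district"),
                            n, replace = TRUE),
                     "civil_society_reserve"))
  protection <- ifelse(level == "national", "dedicated", "mixed")
  regime <- ifelse(protection == "dedicated", "public", "private")
  yr <- config$pa_year_range
  data.frame(
    pa_id = sprintf("pa%03d", seq_len(n)),
    xmin = x0, xmax = x0 + w, ymin = y0, ymax = y0 + h,
    level = level, category = category, protection = protection,
    regime = regime,
    year = if (yr[1] == yr[2]) rep(yr[1], n) else
      sample(seq(yr[1], yr[2]), n, replace = TRUE)
  )
}
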