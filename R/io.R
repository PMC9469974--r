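#' Write a raster layer as an ESRI ASCII grid
#'
#' Plain-text interchange format readable by every desktop GIS. Nodata is
#' written as -9999. The grid geometry (`xllcorner`, `yllcorner`,
#' `cellsize`) round-trips losslessly; the CRS identifier is stored in a
#' sidecar comment line is not part of the .asc standard, so it is carried
#' by [read_raster_asc()]'s `crs_id` argument instead.
#'
#' @param raster A [raster_layer()].
#' @param path Output file path (conventionally `.asc`).
#' @param nodata Nodata sentinel value.
#' @export
write_raster_asc <- function(raster, path, nodata = -9999) {
  g <- raster$grid
  v <- raster$values
  v[is.na(v)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", g$n_cols),
    sprintf("nrows %d", g$n_rows),
    sprintf("xllcorner %.10g", g$origin_x),
    sprintf("yllcorner %.10g", g$origin_y - g$n_rows * g$cell_size),
    sprintf("cellsize %.10g", g$cell_size),
    sprintf("NODATA_value %g", nodata)
  ), con)
  # one text row per raster row, top row first
  writeLines(apply(v, 1, function(r) paste(format(r, digits = 17, trim = TRUE,
                                                  scientific = FALSE),
                                           collapse = " ")), con)
  invisible(path)
}

#' Read an ESRI ASCII grid into a raster layer
#'
#' @param path File written by [write_raster_asc()] (or any conforming .asc).
#' @param crs_id CRS identifier to attach (the format itself carries none).
#' @return A [raster_layer()].
#' @export
read_raster_asc <- function(path, crs_id = "EPSG:3116") {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("malformed ASCII grid header: missing ",
         paste(setdiff(need, names(hdr)), collapse = ", "))
  body <- lines[i:length(lines)]
  vals <- scan(text = paste(body, collapse = "\n"), quiet = TRUE)
  nr <- hdr$nrows; nc <- hdr$ncols
  if (length(vals) != nr * nc) stop("ASCII grid body does not match header dims")
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  g <- grid_spec(nr, nc, hdr$cellsize,
                 origin_x = hdr$xllcorner,
                 origin_y = hdr$yllcorner + nr * hdr$cellsize,
                 crs_id = crs_id)
  raster_layer(m, g)
}

#' Write rectangular protected areas as GeoJSON
#'
#' Each protected area becomes a Polygon feature (closed 5-point ring) with
#' its attributes (`pa_id`, `level`, `category`, `protection`, `regime`,
#' `year`) as properties.
#'
#' @param pas Protected-area table from [generate_protected_areas()] (or any
#'   data.frame with `xmin`, `xmax`, `ymin`, `ymax` plus attribute columns).
#' @param path Output path.
#' @export
write_pas_geojson <- function(pas, path) {
  feats <- lapply(seq_len(nrow(pas)), function(i) {
    r <- pas[i, ]
    ring <- list(
      c(r$xmin, r$ymin), c(r$xmax, r$ymin), c(r$xmax, r$ymax),
      c(r$xmin, r$ymax), c(r$xmin, r$ymin)
    )
    list(
      type = "Feature",
      properties = list(pa_id = r$pa_id, level = r$level, category = r$category,
                        protection = r$protection, regime = r$regime,
                        year = r$year),
      geometry = list(type = "Polygon", coordinates = list(ring))
    )
  })
  fc <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read rectangular protected areas from GeoJSON
#'
#' Inverse of [write_pas_geojson()]: reconstructs the bounding rectangle of
#' each Polygon feature and its properties.
#'
#' @param path GeoJSON file.
#' @return A protected-area data.frame.
#' @export
read_pas_geojson <- function(path) {
  fc <- jsonlite::read_json(path)
  if (is.null(fc$type) || fc$type != "FeatureCollection")
    stop("not a GeoJSON FeatureCollection: ", path)
  rows <- lapply(fc$features, function(f) {
    ring <- f$geometry$coordinates[[1]]
    xs <- vapply(ring, function(p) as.numeric(p[[1]]), numeric(1))
    ys <- vapply(ring, function(p) as.numeric(p[[2]]), numeric(1))
    p <- f$properties
    data.frame(pa_id = p$pa_id, xmin = min(xs), xmax = max(xs),
               ymin = min(ys), ymax = max(ys), level = p$level,
               category = p$category, protection = p$protection,
               regime = p$regime, year = as.integer(p$year))
  })
  do.call(rbind, rows)
}

#' Write habitat cores as GeoJSON
#'
#' Each core is a MultiPolygon of its member cell squares (not dissolved)
#' with the attribute table columns as properties.
#'
#' @param cores A `core_set` from [extract_cores()].
#' @param path Output path.
#' @export
write_cores_geojson <- function(cores, path) {
  g <- cores$grid
  feats <- lapply(seq_len(nrow(cores$cores)), function(i) {
    rects <- cell_rect(g, cores$cells[[i]])
    polys <- lapply(seq_len(nrow(rects)), function(j) {
      r <- rects[j, ]
      list(list(c(r$xmin, r$ymin), c(r$xmax, r$ymin), c(r$xmax, r$ymax),
                c(r$xmin, r$ymax), c(r$xmin, r$ymin)))
    })
    list(type = "Feature",
         properties = as.list(cores$cores[i, , drop = FALSE]),
         geometry = list(type = "MultiPolygon", coordinates = polys))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an occurrence-record CSV with schema validation
#'
#' @param path CSV with at least `record_id`, `x`, `y`, `year`, `evidence`,
#'   `source`, `precision` columns.
#' @return A data.frame of occurrence records.
#' @export
read_records_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("record_id", "x", "y", "year", "evidence", "source", "precision")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("records CSV is missing mandatory column(s): ",
         paste(missing, collapse = ", "))
  df
}
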