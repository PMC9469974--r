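#' Grid specification for a projected raster stack
#'
#' All rasters in one analysis share a single `grid_spec`: a regular grid of
#' square cells in a projected coordinate reference system, anchored at the
#' top-left corner. Cell area in km^2 is `(cell_size / 1000)^2`.
#'
#' @param n_rows,n_cols Grid dimensions (>= 1).
#' @param cell_size Cell edge length in metres (> 0).
#' @param origin_x,origin_y Projected coordinates of the top-left corner. By
#'   default the grid spans `[0, n_cols * cell_size] x [0, n_rows * cell_size]`.
#' @param crs_id Identifier of the projected CRS. The default is the
#'   Colombian national projection (MAGNA-SIRGAS / Colombia Bogota zone);
#'   any label is accepted — it is metadata, never used for reprojection.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(n_rows, n_cols, cell_size,
                      origin_x = 0, origin_y = NULL,
                      crs_id = "EPSG:3116") {
  n_rows <- as.integer(n_rows)
  n_cols <- as.integer(n_cols)
  if (is.na(n_rows) || is.na(n_cols) || n_rows < 1L || n_cols < 1L)
    stop("grid dimensions must be positive integers")
  if (!is.finite(cell_size) || cell_size <= 0)
    stop("cell_size must be a positive length in metres")
  if (is.null(origin_y)) origin_y <- n_rows * cell_size
  structure(
    list(n_rows = n_rows, n_cols = n_cols, cell_size = as.numeric(cell_size),
         origin_x = as.numeric(origin_x), origin_y = as.numeric(origin_y),
         crs_id = as.character(crs_id)),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells of %g m (%s)\n",
              x$n_rows, x$n_cols, x$cell_size, x$crs_id))
  invisible(x)
}

#' Cell area of a grid in km^2
#' @param grid A [grid_spec()].
#' @export
cell_area_km2 <- function(grid) (grid$cell_size / 1000)^2

#' Compare two grid specifications for equality
#' @param a,b [grid_spec()] objects.
#' @export
same_grid <- function(a, b) {
  isTRUE(all.equal(unclass(a), unclass(b), tolerance = 1e-9))
}

#' A single-band raster layer on a shared grid
#'
#' A thin matrix-backed container: `values` is an `n_rows x n_cols` numeric
#' matrix (row 1 is the top of the map), `NA` marks nodata. Linear cell
#' indices follow R's column-major order (`cell = row + (col - 1) * n_rows`).
#'
#' @param values Numeric matrix matching the grid dimensions.
#' @param grid A [grid_spec()].
#' @return An object of class `raster_layer`.
#' @export
raster_layer <- function(values, grid) {
  values <- as.matrix(values)
  if (!inherits(grid, "grid_spec")) stop("grid must be a grid_spec")
  if (nrow(values) != grid$n_rows || ncol(values) != grid$n_cols)
    stop(sprintf("values are %d x %d but grid is %d x %d",
                 nrow(values), ncol(values), grid$n_rows, grid$n_cols))
  storage.mode(values) <- "double"
  structure(list(values = values, grid = grid), class = "raster_layer")
}

#' @export
print.raster_layer <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("<raster_layer> %d x %d, range [%g, %g], %d nodata cells\n",
              x$grid$n_rows, x$grid$n_cols,
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA,
              sum(is.na(x$values))))
  invisible(x)
}

stopifnot_same_grid <- function(a, b) {
  if (!same_grid(a$grid, b$grid)) stop("rasters are not on the same grid_spec")
  invisible(TRUE)
}

#' Projected coordinates of cell centers
#'
#' @param grid A [grid_spec()].
#' @param cells Linear (column-major) cell indices.
#' @return A data.frame with columns `x`, `y`.
#' @export
cell_centers <- function(grid, cells) {
  cells <- as.integer(cells)
  row <- (cells - 1L) %% grid$n_rows + 1L
  col <- (cells - 1L) %/% grid$n_rows + 1L
  data.frame(
    x = grid$origin_x + (col - 0.5) * grid$cell_size,
    y = grid$origin_y - (row - 0.5) * grid$cell_size
  )
}

#' Linear cell index containing each projected point
#'
#' Uses the floor convention: a point exactly on a cell boundary belongs to
#' the cell to its right (increasing x) / below (decreasing y). Points
#' outside the grid extent map to `NA`.
#'
#' @param grid A [grid_spec()].
#' @param x,y Projected coordinates.
#' @export
cell_from_xy <- function(grid, x, y) {
  col <- floor((x - grid$origin_x) / grid$cell_size) + 1
  row <- floor((grid$origin_y - y) / grid$cell_size) + 1
  # the far boundary of the grid itself still belongs to the last cell
  col[x == grid$origin_x + grid$n_cols * grid$cell_size] <- grid$n_cols
  row[y == grid$origin_y - grid$n_rows * grid$cell_size] <- grid$n_rows
  bad <- is.na(col) | is.na(row) |
    col < 1 | col > grid$n_cols | row < 1 | row > grid$n_rows
  idx <- as.integer(row + (col - 1) * grid$n_rows)
  idx[bad] <- NA_integer_
  idx
}

#' Bounding rectangles of grid cells
#'
#' @param grid A [grid_spec()].
#' @param cells Linear cell indices.
#' @return A data.frame with `xmin`, `xmax`, `ymin`, `ymax` per cell.
#' @export
cell_rect <- function(grid, cells) {
  cells <- as.integer(cells)
  row <- (cells - 1L) %% grid$n_rows + 1L
  col <- (cells - 1L) %/% grid$n_rows + 1L
  cs <- grid$cell_size
  data.frame(
    xmin = grid$origin_x + (col - 1) * cs,
    xmax = grid$origin_x + col * cs,
    ymin = grid$origin_y - row * cs,
    ymax = grid$origin_y - (row - 1) * cs
  )
}

#' Label connected components of a binary raster
#'
#' Flood-fill labelling of TRUE/1 cells under rook (4) or queen (8)
#' adjacency. Written here because no connected-component labeller for
#' matrices ships with the installed stack.
#'
#' @param mask Logical or 0/1 matrix; `NA` treated as background.
#' @param connectivity 4 or 8.
#' @return Integer matrix of component labels (0 = background), labelled in
#'   scan order.
#' @export
label_components <- function(mask, connectivity = 8) {
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8")
  m <- !is.na(mask) & mask > 0
  nr <- nrow(m); nc <- ncol(m)
  labels <- matrix(0L, nr, nc)
  if (connectivity == 4) {
    dr <- c(-1L, 1L, 0L, 0L); dc <- c(0L, 0L, -1L, 1L)
  } else {
    dr <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
    dc <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  }
  stack <- integer(nr * nc)
  lab <- 0L
  for (start in which(m)) {
    if (labels[start] != 0L) next
    lab <- lab + 1L
    top <- 1L
    stack[1L] <- start
    labels[start] <- lab
    while (top > 0L) {
      cur <- stack[top]; top <- top - 1L
      r <- (cur - 1L) %% nr + 1L
      cl <- (cur - 1L) %/% nr + 1L
      for (k in seq_along(dr)) {
        r2 <- r + dr[k]; c2 <- cl + dc[k]
        if (r2 < 1L || r2 > nr || c2 < 1L || c2 > nc) next
        nb <- r2 + (c2 - 1L) * nr
        if (m[nb] && labels[nb] == 0L) {
          labels[nb] <- lab
          top <- top + 1L
          stack[top] <- nb
        }
      }
    }
  }
  labels
}

# round half away from zero (printed-report convention); base round() is
# half-to-even, which printed conservation summaries do not use
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
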