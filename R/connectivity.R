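#' Rescale a human-footprint raster to a 1-100 resistance surface
#'
#' Linear transformation of the footprint index onto the standard 1-100
#' resistance scale: R = 1 + 99 (HF - HF_min) / (HF_max - HF_min) over
#' non-nodata cells. A constant footprint degenerates to R = 1 everywhere
#' (frictionless but traversable). Nodata stays nodata and is treated as
#' impassable by [cost_distance()].
#'
#' @param footprint [raster_layer()] with values in \[0, 100\].
#' @return Resistance [raster_layer()] in \[1, 100\].
#' @export
footprint_to_resistance <- function(footprint) {
  v <- footprint$values
  if (all(is.na(v))) stop("footprint raster is all nodata")
  rng <- range(v, na.rm = TRUE)
  out <- if (diff(rng) == 0) ifelse(is.na(v), NA_real_, 1)
         else 1 + 99 * (v - rng[1]) / diff(rng)
  raster_layer(out, footprint$grid)
}

#' Cost-weighted distance from a set of source cells
#'
#' Multi-source Dijkstra over the 8-neighbour lattice: the accumulated cost
#' of a path is the sum of step costs, each the mean of the two endpoint
#' resistances times the centre distance (cell_size, or sqrt(2) x cell_size
#' diagonally). Cells listed in `zero_cells` (e.g. habitat-core interiors)
#' are traversed at zero internal cost so the distance measures the
#' intervening matrix only.
#'
#' @param resistance Resistance [raster_layer()]; nodata is impassable.
#' @param source_cells Linear cell indices of the source set (non-empty).
#' @param zero_cells Optional cell indices whose resistance is set to 0.
#' @return List: `cwd` ([raster_layer()], `Inf` where unreachable), `back`
#'   (integer back-link matrix: predecessor cell index, 0 on sources, `NA`
#'   unreachable), `grid`.
#' @export
cost_distance <- function(resistance, source_cells, zero_cells = NULL) {
  source_cells <- as.integer(source_cells)
  if (length(source_cells) == 0) stop("source_cells must be non-empty")
  v <- resistance$values
  if (all(is.na(v[source_cells])))
    stop("all source cells are on nodata resistance")
  if (!is.null(zero_cells)) v[as.integer(zero_cells)] <- 0
  res <- grid_cost_distance_cpp(v, source_cells, resistance$grid$cell_size)
  list(cwd = raster_layer(res$cwd, resistance$grid), back = res$back,
       grid = resistance$grid)
}

#' Reconstruct a least-cost path from a cost-distance solve
#'
#' @param cd Result of [cost_distance()].
#' @param target_cell Linear index of the destination cell.
#' @return Integer vector of cell indices from a source cell to
#'   `target_cell` (inclusive), or `NULL` if unreachable.
#' @export
least_cost_path <- function(cd, target_cell) {
  bl <- cd$back
  cur <- as.integer(target_cell)
  if (is.na(bl[cur])) return(NULL)
  path <- integer(0)
  while (cur != 0L) {
    path <- c(path, cur)
    cur <- bl[cur]
    if (is.na(cur)) return(NULL)
  }
  rev(path)
}

# geometric length (m) of a cell-path polyline through cell centres
path_length_m <- function(grid, cells) {
  if (length(cells) < 2) return(0)
  p <- cell_centers(grid, cells)
  sum(sqrt(diff(p$x)^2 + diff(p$y)^2))
}

# boundary cells of a core: member cells with at least one rook neighbour
# outside the core (or on the grid edge)
boundary_cells <- function(grid, cells) {
  nr <- grid$n_rows
  inside <- logical(nr * grid$n_cols)
  inside[cells] <- TRUE
  row <- (cells - 1L) %% nr + 1L
  col <- (cells - 1L) %/% nr + 1L
  on_edge <- row == 1L | row == nr | col == 1L | col == grid$n_cols
  nb_out <- rep(FALSE, length(cells))
  for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
    r2 <- row + d[1]; c2 <- col + d[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= grid$n_cols
    nb <- r2 + (c2 - 1L) * nr
    out <- ok & !inside[ifelse(ok, nb, 1L)]
    nb_out <- nb_out | out
  }
  cells[on_edge | nb_out]
}

# minimum edge-to-edge Euclidean distance (m) between two cores, exact for
# square cells: rectangle-to-rectangle distance over boundary cells
min_edge_distance_m <- function(grid, cells_a, cells_b) {
  cs <- grid$cell_size
  pa <- cell_centers(grid, cells_a)
  pb <- cell_centers(grid, cells_b)
  dx <- pmax(0, abs(outer(pa$x, pb$x, "-")) - cs)
  dy <- pmax(0, abs(outer(pa$y, pb$y, "-")) - cs)
  sqrt(min(dx^2 + dy^2))
}

#' Build the corridor network between habitat cores
#'
#' Candidate pairs are cores whose minimum edge-to-edge Euclidean distance
#' does not exceed the dispersal limit (default 15 km, the distance
#' reachable by an individual with a median home range of 4.5 km^2). For
#' each candidate pair the least-cost path across the resistance surface is
#' traced with every core interior set to zero internal cost; a link whose
#' path crosses a third core is dropped (that pair is connected
#' transitively through the intermediate core).
#'
#' @param cores A `core_set` from [extract_cores()].
#' @param resistance Resistance [raster_layer()] on the same grid.
#' @param max_euclid_km Dispersal pruning distance in km (default 15).
#' @return A `corridor_network`: list with `nodes` (core table), `edges`
#'   (data.frame `core_a`, `core_b`, `cwd`, `euclid_km`, `path_km`),
#'   `paths` (list of least-cost-path cell vectors, parallel to `edges`),
#'   `grid`.
#' @export
build_network <- function(cores, resistance, max_euclid_km = 15) {
  if (!same_grid(cores$grid, resistance$grid))
    stop("resistance raster is not on the core grid")
  g <- cores$grid
  n <- nrow(cores$cores)
  empty_edges <- data.frame(core_a = integer(), core_b = integer(),
                            cwd = numeric(), euclid_km = numeric(),
                            path_km = numeric())
  net <- structure(list(nodes = cores$cores, edges = empty_edges,
                        paths = list(), grid = g),
                   class = "corridor_network")
  if (n < 2) return(net)

  bnd <- lapply(cores$cells, function(cl) boundary_cells(g, cl))
  # bounding boxes for a cheap prefilter
  bbox <- t(vapply(cores$cells, function(cl) {
    p <- cell_centers(g, cl)
    c(min(p$x), max(p$x), min(p$y), max(p$y))
  }, numeric(4)))
  max_m <- max_euclid_km * 1000
  cand <- list()
  for (a in 1:(n - 1)) for (b in (a + 1):n) {
    gap_x <- max(0, max(bbox[a, 1], bbox[b, 1]) - min(bbox[a, 2], bbox[b, 2]))
    gap_y <- max(0, max(bbox[a, 3], bbox[b, 3]) - min(bbox[a, 4], bbox[b, 4]))
    if (sqrt(gap_x^2 + gap_y^2) - g$cell_size > max_m) next
    d <- min_edge_distance_m(g, bnd[[a]], bnd[[b]])
    if (d <= max_m) cand[[length(cand) + 1]] <- c(a, b, d)
  }
  if (length(cand) == 0) return(net)
  cand <- do.call(rbind, cand)

  all_core_cells <- unlist(cores$cells)
  membership <- integer(g$n_rows * g$n_cols)
  for (i in seq_len(n)) membership[cores$cells[[i]]] <- i

  edges <- list(); paths <- list()
  for (a in sort(unique(cand[, 1]))) {
    cd <- cost_distance(resistance, cores$cells[[a]],
                        zero_cells = all_core_cells)
    for (j in which(cand[, 1] == a)) {
      b <- cand[j, 2]
      tcells <- cores$cells[[b]]
      cwd_b <- cd$cwd$values[tcells]
      if (all(!is.finite(cwd_b))) next
      tcell <- tcells[which.min(cwd_b)]
      path <- least_cost_path(cd, tcell)
      if (is.null(path)) next
      through <- membership[path]
      if (any(!(through %in% c(0L, a, b)))) next  # crosses a third core
      edges[[length(edges) + 1]] <- data.frame(
        core_a = a, core_b = b, cwd = min(cwd_b, na.rm = TRUE),
        euclid_km = cand[j, 3] / 1000,
        path_km = path_length_m(g, path) / 1000
      )
      paths[[length(paths) + 1]] <- path
    }
  }
  if (length(edges)) {
    net$edges <- do.call(rbind, edges)
    net$paths <- paths
  }
  net
}

#' @export
print.corridor_network <- function(x, ...) {
  cat(sprintf("<corridor_network> %d cores, %d links\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Least-cost corridor surface between two cores
#'
#' The corridor is the swath of cells whose combined cost-weighted distance
#' to both cores exceeds the least-cost-path cost by at most `cutoff`:
#' cells with `cwd_a + cwd_b - lcp_cost <= cutoff`. A cutoff of 0 returns
#' exactly the least-cost-path locus (ties included).
#'
#' @param cwd_a,cwd_b Cost-weighted distance [raster_layer()]s from each
#'   core (see [cost_distance()]).
#' @param cutoff Cost slack (>= 0).
#' @return List: `cells` (linear indices of corridor cells), `lcp_cost`.
#' @export
corridor_surface <- function(cwd_a, cwd_b, cutoff) {
  stopifnot_same_grid(cwd_a, cwd_b)
  if (is.na(cutoff) || cutoff < 0) stop("cutoff must be non-negative")
  total <- cwd_a$values + cwd_b$values
  lcp <- min(total, na.rm = TRUE)
  if (!is.finite(lcp)) stop("cores are mutually unreachable")
  cells <- which(!is.na(total) & total - lcp <= cutoff)
  list(cells = cells, lcp_cost = lcp)
}

#' Current-flow analysis of a corridor network
#'
#' Models the corridor graph as a resistor network: each link is a resistor
#' with resistance equal to its cost-weighted distance (conductance
#' 1/cwd). For every unordered pair of cores in the same component a unit
#' current is injected at one and extracted at the other by solving the
#' graph-Laplacian system; each link's per-pair current is conductance
#' times the potential difference. Aggregating over all pairs gives the
#' link's potential current flow and each core's current-flow centrality
#' (CF centrality): terminals count the full injected unit, interior cores
#' half the sum of absolute incident currents. Components are solved
#' independently; isolated cores get centrality 0.
#'
#' @param network A `corridor_network` from [build_network()].
#' @return The network with `edges$current` and `nodes$centrality` filled,
#'   plus `components` (per-core component id).
#' @export
current_flow <- function(network) {
  edges <- network$edges
  nodes <- network$nodes
  n <- nrow(nodes)
  nodes$centrality <- rep(0, n)
  if (nrow(edges) == 0) {
    network$nodes <- nodes
    network$components <- seq_len(n)
    return(network)
  }
  if (any(!is.finite(edges$cwd) | edges$cwd <= 0))
    stop("every link must have finite positive cwd (zero-resistance edge)")
  edges$current <- 0
  gr <- igraph::graph_from_data_frame(
    data.frame(from = as.character(edges$core_a),
               to = as.character(edges$core_b)),
    directed = FALSE,
    vertices = data.frame(name = as.character(nodes$core_id))
  )
  comp <- igraph::components(gr)$membership
  comp_of_node <- comp[as.character(nodes$core_id)]

  for (cid in unique(comp_of_node)) {
    members <- nodes$core_id[comp_of_node == cid]
    if (length(members) < 2) next
    local <- stats::setNames(seq_along(members), members)
    e_in <- which(edges$core_a %in% members & edges$core_b %in% members)
    eu <- local[as.character(edges$core_a[e_in])]
    ev <- local[as.character(edges$core_b[e_in])]
    cond <- 1 / edges$cwd[e_in]
    m <- length(members)
    L <- matrix(0, m, m)
    for (k in seq_along(e_in)) {
      L[eu[k], eu[k]] <- L[eu[k], eu[k]] + cond[k]
      L[ev[k], ev[k]] <- L[ev[k], ev[k]] + cond[k]
      L[eu[k], ev[k]] <- L[eu[k], ev[k]] - cond[k]
      L[ev[k], eu[k]] <- L[ev[k], eu[k]] - cond[k]
    }
    pairs <- utils::combn(m, 2)
    np <- ncol(pairs)
    B <- matrix(0, m, np)
    B[cbind(pairs[1, ], seq_len(np))] <- 1
    B[cbind(pairs[2, ], seq_len(np))] <- -1
    # ground node 1 and solve all injections at once
    X <- matrix(0, m, np)
    X[-1, ] <- solve(L[-1, -1, drop = FALSE], B[-1, , drop = FALSE])
    # per-pair edge currents (E x P)
    I <- cond * (X[eu, , drop = FALSE] - X[ev, , drop = FALSE])
    absI <- abs(I)
    edges$current[e_in] <- edges$current[e_in] + rowSums(absI)
    # node throughput: half the absolute incident current, terminals = 1
    thr <- matrix(0, m, np)
    for (k in seq_along(e_in)) {
      thr[eu[k], ] <- thr[eu[k], ] + absI[k, ]
      thr[ev[k], ] <- thr[ev[k], ] + absI[k, ]
    }
    thr <- thr / 2
    thr[cbind(pairs[1, ], seq_len(np))] <- 1
    thr[cbind(pairs[2, ], seq_len(np))] <- 1
    idx <- match(members, nodes$core_id)
    nodes$centrality[idx] <- nodes$centrality[idx] + rowSums(thr)
  }
  network$edges <- edges
  network$nodes <- nodes
  network$components <- unname(comp_of_node)
  network
}

#' Summary statistics of a corridor network
#'
#' @param network A `corridor_network`, ideally after [current_flow()].
#' @return List: link count, mean/sd of Euclidean and path lengths and of
#'   link current, number and fraction of cores with at least one link,
#'   mean/sd links per core, maximum links on one core.
#' @export
network_summary <- function(network) {
  edges <- network$edges
  n <- nrow(network$nodes)
  deg <- rep(0L, n)
  if (nrow(edges)) {
    t1 <- table(factor(edges$core_a, levels = network$nodes$core_id))
    t2 <- table(factor(edges$core_b, levels = network$nodes$core_id))
    deg <- as.integer(t1 + t2)
  }
  msd <- function(v) if (length(v) == 0) c(mean = NA_real_, sd = NA_real_)
                     else c(mean = mean(v),
                            sd = if (length(v) > 1) stats::sd(v) else NA_real_)
  list(
    n_links = nrow(edges),
    euclid_km = msd(edges$euclid_km),
    path_km = msd(edges$path_km),
    current = if (!is.null(edges$current)) msd(edges$current)
              else c(mean = NA_real_, sd = NA_real_),
    n_cores = n,
    n_linked = sum(deg > 0),
    fraction_linked = if (n > 0) sum(deg > 0) / n else NA_real_,
    links_per_core = msd(deg),
    max_links = if (n > 0) max(deg) else NA_integer_
  )
}
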