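# Independent oracles and small fixture builders used across the suite.

# Brute-force least-cost distance on a small resistance grid: depth-first
# enumeration of all simple 8-neighbour paths with branch-and-bound
# pruning. Independent of the Dijkstra implementation under test.
brute_force_cwd <- function(res, source, target, cell_size) {
  nr <- nrow(res); nc <- ncol(res)
  best <- Inf
  visited <- rep(FALSE, nr * nc)
  dfs <- function(u, cost) {
    if (cost >= best) return(invisible())
    if (u == target) {
      best <<- cost
      return(invisible())
    }
    r <- (u - 1) %% nr + 1
    cl <- (u - 1) %/% nr + 1
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      r2 <- r + dr; c2 <- cl + dc
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      v <- r2 + (c2 - 1) * nr
      if (visited[v]) next
      mult <- if (dr != 0 && dc != 0) sqrt(2) else 1
      visited[v] <<- TRUE
      dfs(v, cost + 0.5 * (res[u] + res[v]) * cell_size * mult)
      visited[v] <<- FALSE
    }
  }
  visited[source] <- TRUE
  dfs(source, 0)
  best
}

# Dense Kirchhoff oracle for current flow on one connected graph:
# Moore-Penrose pseudoinverse of the Laplacian (MASS::ginv), per-pair
# potentials, aggregated absolute currents and node throughputs.
kirchhoff_oracle <- function(node_ids, edges) {
  n <- length(node_ids)
  idx <- stats::setNames(seq_len(n), node_ids)
  L <- matrix(0, n, n)
  cond <- 1 / edges$cwd
  for (k in seq_len(nrow(edges))) {
    i <- idx[as.character(edges$core_a[k])]
    j <- idx[as.character(edges$core_b[k])]
    L[i, i] <- L[i, i] + cond[k]
    L[j, j] <- L[j, j] + cond[k]
    L[i, j] <- L[i, j] - cond[k]
    L[j, i] <- L[j, i] - cond[k]
  }
  G <- MASS::ginv(L)
  centrality <- rep(0, n)
  link_current <- rep(0, nrow(edges))
  for (s in 1:(n - 1)) for (t in (s + 1):n) {
    b <- rep(0, n); b[s] <- 1; b[t] <- -1
    x <- as.numeric(G %*% b)
    I <- cond * (x[idx[as.character(edges$core_a)]] -
                   x[idx[as.character(edges$core_b)]])
    link_current <- link_current + abs(I)
    thr <- rep(0, n)
    for (k in seq_len(nrow(edges))) {
      i <- idx[as.character(edges$core_a[k])]
      j <- idx[as.character(edges$core_b[k])]
      thr[i] <- thr[i] + abs(I[k])
      thr[j] <- thr[j] + abs(I[k])
    }
    thr <- thr / 2
    thr[s] <- 1; thr[t] <- 1
    centrality <- centrality + thr
  }
  list(centrality = centrality, link_current = link_current)
}

# random connected resistor graph with n nodes: a random spanning tree plus
# extra random edges
random_resistor_graph <- function(n, extra = 2) {
  edges <- data.frame(core_a = integer(), core_b = integer(), cwd = numeric())
  for (v in 2:n) {
    u <- sample.int(v - 1, 1)
    edges <- rbind(edges, data.frame(core_a = u, core_b = v,
                                     cwd = stats::runif(1, 0.5, 5)))
  }
  for (k in seq_len(extra)) {
    uv <- sort(sample.int(n, 2))
    edges <- rbind(edges, data.frame(core_a = uv[1], core_b = uv[2],
                                     cwd = stats::runif(1, 0.5, 5)))
  }
  edges
}

# wrap an edge table as a minimal corridor_network for current_flow()
as_network <- function(node_ids, edges, grid = grid_spec(1, 1, 1000)) {
  structure(list(
    nodes = data.frame(core_id = node_ids),
    edges = edges, paths = vector("list", nrow(edges)), grid = grid
  ), class = "corridor_network")
}

# uniform raster helper
uniform_raster <- function(value, nr, nc, cell = 1000) {
  raster_layer(matrix(value, nr, nc), grid_spec(nr, nc, cell))
}

# a core_set built directly from explicit cell sets on a given binary grid
core_set_from_cells <- function(grid, cell_sets, min_area_km2 = 1e-9) {
  m <- matrix(0, grid$n_rows, grid$n_cols)
  for (cl in cell_sets) m[cl] <- 1
  extract_cores(raster_layer(m, grid), min_area_km2 = min_area_km2)
}

# landscape recovery config: planted patches above the design threshold on
# a sub-threshold background
recovery_config <- function(seed, k = 5, grid = grid_spec(100, 100, 1000)) {
  sim_config(seed = seed, grid = grid, n_planted_patches = k,
             patch_area_range = c(17, 60), n_records = 0,
             n_protected_areas = 0)
}

recovered_cores <- function(cfg) {
  pack <- generate_landscape(cfg)
  bin <- binarize(pack$suitability, cfg$design_threshold)
  masked <- mask_natural(bin, pack$landcover, pack$natural_classes)
  list(pack = pack,
       cores = extract_cores(masked, min_area_km2 = 17, connectivity = 8))
}
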