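test_that("footprint-to-resistance is the documented 1-100 linear rescale", {
  g <- grid_spec(2, 3, 1000)
  fp <- raster_layer(matrix(c(10, 20, 30, 40, 50, 70), 2, 3), g)
  r <- footprint_to_resistance(fp)
  expect_equal(min(r$values), 1)          # HF_min -> 1
  expect_equal(max(r$values), 100)        # HF_max -> 100
  expect_equal(r$values[fp$values == 40], 50.5)  # midway -> 50.5
  # constant footprint degenerates to frictionless R = 1
  flat <- footprint_to_resistance(raster_layer(matrix(7, 2, 3), g))
  expect_true(all(flat$values == 1))
  # nodata propagates
  m <- matrix(c(0, 50, 100, NA), 2, 2)
  rn <- footprint_to_resistance(raster_layer(m, grid_spec(2, 2, 1000)))
  expect_true(is.na(rn$values[2, 2]))
  expect_error(footprint_to_resistance(
    raster_layer(matrix(NA_real_, 2, 2), grid_spec(2, 2, 1000))), "nodata")
})

test_that("cost distance reduces to metric distance on uniform resistance", {
  r <- uniform_raster(1, 5, 5, cell = 1000)
  cd <- cost_distance(r, source_cells = 1)   # top-left cell
  # two rook steps -> 2000; one diagonal step -> 1000 * sqrt(2)
  expect_equal(cd$cwd$values[3, 1], 2000)
  expect_equal(cd$cwd$values[2, 2], 1000 * sqrt(2), tolerance = 1e-9)
  expect_equal(cd$cwd$values[1, 1], 0)
  # least-cost path to the far corner is the diagonal
  path <- least_cost_path(cd, cell_from_xy(r$grid, 4500, 500))
  expect_length(path, 5)
})

test_that("cost distance equals brute-force path enumeration around a
           high-resistance wall", {
  # 4 x 4 grid with a vertical wall forcing a detour
  res <- matrix(1, 4, 4)
  res[1:3, 2] <- 500
  r <- raster_layer(res, grid_spec(4, 4, 1000))
  cd <- cost_distance(r, source_cells = 1)
  for (target in c(13, 16, 4)) {
    expect_equal(cd$cwd$values[target],
                 brute_force_cwd(res, 1, target, 1000), tolerance = 1e-9)
  }
})

test_that("cost distance marks unreachable cells and honours zero-cost
           interiors", {
  res <- matrix(1, 3, 5)
  res[, 3] <- NA                       # impassable barrier column
  r <- raster_layer(res, grid_spec(3, 5, 1000))
  cd <- cost_distance(r, source_cells = 1)
  expect_true(all(is.infinite(cd$cwd$values[, 4:5])))
  expect_null(least_cost_path(cd, 14))
  # zero-cost cells traverse for free
  r2 <- uniform_raster(10, 1, 5, cell = 1000)
  cd2 <- cost_distance(r2, source_cells = 1, zero_cells = 1:4)
  expect_equal(cd2$cwd$values[1, 4], 0)
  expect_equal(cd2$cwd$values[1, 5], 0.5 * (0 + 10) * 1000)
  expect_error(cost_distance(r2, integer(0)), "non-empty")
})

test_that("CWD satisfies the triangle inequality through shared surfaces", {
  set.seed(11)
  for (rep in 1:5) {
    res <- matrix(runif(64, 1, 100), 8, 8)
    r <- raster_layer(res, grid_spec(8, 8, 1000))
    cells <- sample(64, 3)
    cd_a <- cost_distance(r, cells[1])
    cd_b <- cost_distance(r, cells[2])
    expect_lte(cd_a$cwd$values[cells[3]],
               cd_a$cwd$values[cells[2]] + cd_b$cwd$values[cells[3]] + 1e-9)
  }
})

# three collinear cores on a thin strip: A at cols 1-2, B at 12-13, C at 23-24
collinear_cores <- function(cell = 500) {
  g <- grid_spec(3, 24, cell)
  m <- matrix(0, 3, 24)
  m[2, c(1, 2, 12, 13, 23, 24)] <- 1
  cores <- extract_cores(raster_layer(m, g), min_area_km2 = 0.4)
  list(cores = cores, resistance = uniform_raster(1, 3, 24, cell))
}

test_that("link building prunes by dispersal distance and drops paths
           through a third core", {
  # two cores 16 km apart on a 1-km grid -> no link at the 15 km rule
  g <- grid_spec(3, 20, 1000)
  m <- matrix(0, 3, 20)
  m[2, c(1, 18)] <- 1
  far <- extract_cores(raster_layer(m, g), min_area_km2 = 0.5)
  net_far <- build_network(far, uniform_raster(1, 3, 20, 1000),
                           max_euclid_km = 15)
  expect_equal(nrow(net_far$edges), 0)
  # the same pair connects at 17 km allowance
  net_ok <- build_network(far, uniform_raster(1, 3, 20, 1000),
                          max_euclid_km = 17)
  expect_equal(nrow(net_ok$edges), 1)
  expect_equal(net_ok$edges$euclid_km, 16)
  # single core -> empty edge list
  single <- extract_cores(raster_layer(matrix(1, 2, 2), grid_spec(2, 2, 1000)),
                          min_area_km2 = 1)
  expect_equal(nrow(build_network(single,
                                  uniform_raster(1, 2, 2, 1000))$edges), 0)
  # collinear A-B-C: A-C dropped because its path crosses B
  cc <- collinear_cores()
  net <- build_network(cc$cores, cc$resistance, max_euclid_km = 15)
  expect_equal(nrow(net$edges), 2)
  pairs <- paste(pmin(net$edges$core_a, net$edges$core_b),
                 pmax(net$edges$core_a, net$edges$core_b))
  # core ids are area-ordered; with equal areas id order follows labels
  # (A=1, B=2, C=3), so the surviving links are A-B and B-C
  expect_setequal(pairs, c("1 2", "2 3"))
  # euclid <= path length on every link
  expect_true(all(net$edges$euclid_km <= net$edges$path_km + 1e-9))
})

test_that("corridor surfaces are the slack-bounded locus of summed CWD", {
  r <- uniform_raster(1, 5, 9, cell = 1000)
  a_cells <- which(matrix(seq_len(45), 5, 9) %% 5 == 3 &
                     col(matrix(0, 5, 9)) == 1)  # cell (3,1)
  b_cells <- which(row(matrix(0, 5, 9)) == 3 & col(matrix(0, 5, 9)) == 9)
  cd_a <- cost_distance(r, a_cells)
  cd_b <- cost_distance(r, b_cells)
  total <- cd_a$cwd$values + cd_b$cwd$values
  lcp <- min(total)
  # cutoff 0: exactly the ties-included least-cost locus
  cs0 <- corridor_surface(cd_a$cwd, cd_b$cwd, 0)
  expect_setequal(cs0$cells, which(total - lcp <= 0))
  expect_equal(cs0$lcp_cost, lcp)
  # small cutoff matches a cellwise scan oracle
  cs <- corridor_surface(cd_a$cwd, cd_b$cwd, 1500)
  expect_setequal(cs$cells, which(total - lcp <= 1500))
  # infinite cutoff: all mutually reachable cells
  expect_length(corridor_surface(cd_a$cwd, cd_b$cwd, Inf)$cells, 45)
  expect_error(corridor_surface(cd_a$cwd, cd_b$cwd, -1), "non-negative")
})

test_that("current flow matches closed forms on elementary circuits", {
  # two cores, one link: the whole unit current crosses it
  n2 <- current_flow(as_network(1:2, data.frame(core_a = 1, core_b = 2,
                                                cwd = 3.7)))
  expect_equal(n2$edges$current, 1)
  expect_equal(n2$nodes$centrality, c(1, 1))
  # two parallel links of equal resistance split the current evenly
  par <- current_flow(as_network(1:2, data.frame(core_a = c(1, 1),
                                                 core_b = c(2, 2),
                                                 cwd = c(2, 2))))
  expect_equal(par$edges$current, c(0.5, 0.5))
  # unequal parallel resistors split inversely to resistance
  par2 <- current_flow(as_network(1:2, data.frame(core_a = c(1, 1),
                                                  core_b = c(2, 2),
                                                  cwd = c(1, 3))))
  expect_equal(par2$edges$current, c(0.75, 0.25))
  # series chain u-w-v: every pair's current crosses each edge it spans
  ser <- current_flow(as_network(1:3, data.frame(core_a = c(1, 2),
                                                 core_b = c(2, 3),
                                                 cwd = c(1, 2))))
  expect_equal(ser$edges$current, c(2, 2))   # pairs (1,2)+(1,3); (2,3)+(1,3)
  expect_equal(ser$nodes$centrality, c(2, 3, 2))  # interior node carries all
  # zero-resistance edges are rejected
  expect_error(current_flow(as_network(1:2, data.frame(core_a = 1, core_b = 2,
                                                       cwd = 0))),
               "positive")
})

test_that("triangle currents match a direct Kirchhoff linear solve", {
  tri <- data.frame(core_a = c(1, 1, 2), core_b = c(2, 3, 3),
                    cwd = c(1, 2, 3))
  got <- current_flow(as_network(1:3, tri))
  oracle <- kirchhoff_oracle(1:3, tri)
  expect_equal(got$edges$current, oracle$link_current, tolerance = 1e-10)
  expect_equal(got$nodes$centrality, oracle$centrality, tolerance = 1e-10)
})

test_that("components are solved independently and isolated cores get
           zero centrality", {
  edges <- data.frame(core_a = c(1, 3), core_b = c(2, 4), cwd = c(1, 1))
  net <- current_flow(as_network(1:5, edges))
  expect_equal(net$nodes$centrality, c(1, 1, 1, 1, 0))
  expect_equal(length(unique(net$components)), 3)
})

test_that("network summary reports degrees, linked fraction and hub size", {
  # star of 5 links on one hub over 6 nodes
  star <- data.frame(core_a = rep(1, 5), core_b = 2:6, cwd = 1,
                     euclid_km = 1:5, path_km = 2:6)
  s <- network_summary(as_network(1:6, star))
  expect_equal(s$n_links, 5)
  expect_equal(s$max_links, 5)
  expect_equal(unname(s$links_per_core["mean"]), 10 / 6)
  expect_equal(s$n_linked, 6)
  expect_equal(s$fraction_linked, 1)
  expect_equal(unname(s$euclid_km["mean"]), 3)
  # empty network
  s0 <- network_summary(as_network(1:3, data.frame(core_a = integer(),
                                                   core_b = integer(),
                                                   cwd = numeric(),
                                                   euclid_km = numeric(),
                                                   path_km = numeric())))
  expect_equal(s0$n_links, 0)
  expect_equal(s0$n_linked, 0)
})

test_that("larger cores anchor more current on a constructed hub
           landscape", {
  # one large hub core ringed by small satellites within dispersal range
  g <- grid_spec(40, 40, 1000)
  m <- matrix(0, 40, 40)
  m[16:25, 16:25] <- 1                      # 100-cell hub
  sat <- list(c(5, 20), c(20, 5), c(35, 20), c(20, 35))
  for (s in sat) m[s[1]:(s[1] + 1), s[2]:(s[2] + 1)] <- 1  # 4-cell satellites
  cores <- extract_cores(raster_layer(m, g), min_area_km2 = 1)
  net <- current_flow(build_network(cores, uniform_raster(1, 40, 40, 1000)))
  tab <- cores$cores
  tab$centrality <- net$nodes$centrality
  fit <- suppressWarnings(   # near-exact fit on the constructed star
    area_centrality_regression(tab, size_thresholds = numeric(0)))
  expect_gt(fit$slope[fit$subset == "all"], 0)
  expect_equal(which.max(tab$centrality),
               which.max(tab$area_km2))
})
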