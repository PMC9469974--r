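test_that("reliability classification is a pure total mapping with the
           documented High/Medium/Low assignments", {
  # independent copy of the criteria table, asserted over the full
  # 5 x 5 x 4 category grid (100 combinations)
  ev <- c(preserved_specimen = "High", machine_observation = "High",
          material_sample = "Medium", human_observation = "Low",
          no_data = "Low")
  src <- c(peer_reviewed = "High", expert_validated = "High",
           museum = "Medium", gbif = "Medium", technical = "Low")
  prec <- c(dept_and_municipality = "High", department = "Medium",
            municipality = "Medium", none = "Low")
  grid <- expand.grid(evidence = names(ev), source = names(src),
                      precision = names(prec), stringsAsFactors = FALSE)
  expect_equal(nrow(grid), 100)
  out <- classify_reliability(grid$evidence, grid$source, grid$precision)
  expect_equal(out$evidence_rel, unname(ev[grid$evidence]))
  expect_equal(out$source_rel, unname(src[grid$source]))
  expect_equal(out$precision_rel, unname(prec[grid$precision]))
  # spot checks mirroring the criteria table
  expect_equal(unlist(classify_reliability("preserved_specimen",
                                           "peer_reviewed",
                                           "dept_and_municipality")),
               c(evidence_rel = "High", source_rel = "High",
                 precision_rel = "High"))
  expect_equal(unlist(classify_reliability("human_observation", "museum",
                                           "department")),
               c(evidence_rel = "Low", source_rel = "Medium",
                 precision_rel = "Medium"))
  expect_error(classify_reliability("photograph_of_track", "museum", "none"),
               "evidence")
})

toy_records <- function() {
  # 8 rows: 2 without coordinates, 2 with a Low criterion, 2 exact
  # duplicates in one 1-km cell, 2 clean records in distinct cells
  data.frame(
    record_id = sprintf("r%02d", 1:8),
    x = c(NA, NA, 500, 1500, 2500, 2500, 3500, 4500),
    y = c(500, NA, 500, 500, 500, 500, 500, 500),
    year = c(2000, 2001, 2002, 2003, 2005, 2004, 2006, 2007),
    evidence = c("preserved_specimen", "preserved_specimen",
                 "human_observation", "preserved_specimen",
                 "preserved_specimen", "preserved_specimen",
                 "machine_observation", "preserved_specimen"),
    source = c("peer_reviewed", "peer_reviewed", "peer_reviewed",
               "technical", "peer_reviewed", "peer_reviewed",
               "expert_validated", "museum"),
    precision = c("dept_and_municipality", "dept_and_municipality",
                  "dept_and_municipality", "dept_and_municipality",
                  "dept_and_municipality", "dept_and_municipality",
                  "department", "municipality")
  )
}

test_that("filter_records applies the four rules in order with a complete
           audit", {
  res <- filter_records(toy_records())
  expect_equal(nrow(res$retained), 3)
  expect_setequal(res$retained$record_id, c("r06", "r07", "r08"))
  tab <- table(res$audit$fate)
  expect_equal(as.integer(tab[c("no_coords", "low_reliability", "duplicate",
                                "grid_redundant", "retained")]),
               c(2L, 2L, 1L, 0L, 3L))
  # duplicate survivor: equal reliability, earlier year wins (r06, 2004)
  expect_true("r06" %in% res$retained$record_id)
  # audit completeness over every input row
  expect_equal(sum(tab), nrow(toy_records()))
  # idempotence: filtering the retained set changes nothing
  again <- filter_records(res$retained[, names(toy_records())])
  expect_equal(again$retained$record_id, res$retained$record_id)
  expect_true(all(again$audit$fate == "retained"))
})

test_that("filter_records handles empty input, identity input and the
           strict variant", {
  empty <- filter_records(toy_records()[0, ])
  expect_equal(nrow(empty$retained), 0)
  expect_equal(nrow(empty$audit), 0)
  clean <- data.frame(
    record_id = c("a", "b", "c"),
    x = c(500, 1500, 2500), y = rep(500, 3), year = 2000:2002,
    evidence = "preserved_specimen", source = "peer_reviewed",
    precision = "dept_and_municipality"
  )
  expect_equal(nrow(filter_records(clean)$retained), 3)
  # strict filter drops anything not all-High
  mixed <- clean
  mixed$source[2] <- "museum"
  expect_equal(nrow(filter_records(mixed, strictness = "strict")$retained), 2)
  expect_equal(nrow(filter_records(mixed, strictness = "moderate")$retained), 3)
})

test_that("grid thinning keeps one survivor per cell and matches a
           brute-force binning oracle", {
  # two points 100 m apart share a 1-km cell
  expect_length(thin_by_grid(c(100, 200), c(100, 100), 1), 1)
  # n points in distinct cells all survive
  expect_length(thin_by_grid(seq(500, 9500, 1000), rep(500, 10), 1), 10)
  expect_error(thin_by_grid(1, 1, 0), "positive")
  # boundary points follow the floor convention; oracle: brute-force
  # binning of 20 random points (some exactly on boundaries)
  set.seed(42)
  x <- c(runif(16, 0, 5000), 1000, 2000, 3000, 3000)
  y <- c(runif(16, 0, 5000), 1000, 2000, 3000, 3000)
  keep <- thin_by_grid(x, y, 1)
  oracle_key <- paste(floor(x / 1000), floor(y / 1000))
  expect_equal(length(keep), length(unique(oracle_key)))
  expect_equal(anyDuplicated(oracle_key[keep]), 0L)
  # first-in-cell survivor by default: earliest index per oracle key
  first <- vapply(split(seq_along(x), oracle_key), min, numeric(1))
  expect_setequal(keep, as.integer(first))
})

test_that("collinearity screening drops the lower-ranked member of each
           correlated pair", {
  set.seed(1)
  n <- 40
  elevation <- sort(runif(n, 0, 4000))
  temperature <- 30 - elevation / 180 + rnorm(n, 0, 1)   # strongly negative
  rain <- runif(n, 500, 3000)                             # independent
  X <- cbind(elevation = elevation, temperature = temperature, rain = rain)
  rho <- cor(X, method = "spearman")
  expect_lt(rho["elevation", "temperature"], -0.7)        # construction check
  res <- screen_collinear_variables(X, c("elevation", "rain", "temperature"))
  expect_setequal(res$kept, c("elevation", "rain"))
  expect_equal(res$dropped$variable, "temperature")
  expect_equal(res$dropped$correlated_with, "elevation")
  # all pairs below threshold -> identity
  set.seed(2)
  Y <- cbind(a = rnorm(50), b = rnorm(50), c = rnorm(50))
  expect_equal(screen_collinear_variables(Y, c("a", "b", "c"))$kept,
               c("a", "b", "c"))
})

test_that("greedy screening equals exhaustive search on a 3-variable chain", {
  # chain: |rho12|, |rho23| >= 0.7 but |rho13| < 0.7
  set.seed(3)
  repeat {
    v2 <- rnorm(60)
    v1 <- v2 + rnorm(60, 0, 0.55)
    v3 <- v2 + rnorm(60, 0, 0.55)
    rho <- cor(cbind(v1, v2, v3), method = "spearman")
    if (abs(rho[1, 2]) >= 0.7 && abs(rho[2, 3]) >= 0.7 &&
        abs(rho[1, 3]) < 0.7) break
  }
  X <- cbind(v1 = v1, v2 = v2, v3 = v3)
  rank <- c("v1", "v2", "v3")
  res <- screen_collinear_variables(X, rank)
  # exhaustive oracle: over all 2^3 subsets, the valid (no pair >= 0.7)
  # subset maximizing retained importance, preferring higher-ranked sets
  subsets <- unlist(lapply(1:3, function(k)
    combn(rank, k, simplify = FALSE)), recursive = FALSE)
  valid <- Filter(function(s) {
    if (length(s) < 2) return(TRUE)
    all(abs(rho[s, s][upper.tri(diag(length(s)))]) < 0.7)
  }, subsets)
  score <- vapply(valid, function(s)
    sum(4 - match(s, rank)), numeric(1))    # importance-weighted size
  best <- valid[[which.max(score)]]
  expect_setequal(res$kept, best)           # {v1, v3}
})

test_that("constant variables are flagged and treated as uncorrelated", {
  X <- cbind(a = rnorm(20), flat = rep(1, 20))
  res <- screen_collinear_variables(X, c("a", "flat"))
  expect_equal(res$constant_flagged, "flat")
  expect_setequal(res$kept, c("a", "flat"))
})
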