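#' Reliability classification of occurrence records
#'
#' Maps the three quality-control criteria of a compiled occurrence dataset
#' — type of evidence, data source and geographic precision — onto ordinal
#' reliability classes (High / Medium / Low):
#'
#' * evidence: preserved specimen, machine observation (camera trap /
#'   photographic record) -> High; material sample -> Medium; human
#'   observation, no data -> Low.
#' * source: peer-reviewed article, expert-validated record -> High;
#'   museum, GBIF -> Medium; technical report -> Low.
#' * precision: department and municipality both resolved -> High; only one
#'   of the two -> Medium; none -> Low.
#'
#' @param evidence,source,precision Character vectors (recycled to common
#'   length) using the category codes above.
#' @return Data.frame with `evidence_rel`, `source_rel`, `precision_rel`.
#' @export
classify_reliability <- function(evidence, source, precision) {
  ev_map <- c(preserved_specimen = "High", machine_observation = "High",
              material_sample = "Medium", human_observation = "Low",
              no_data = "Low")
  src_map <- c(peer_reviewed = "High", expert_validated = "High",
               museum = "Medium", gbif = "Medium", technical = "Low")
  prec_map <- c(dept_and_municipality = "High", department = "Medium",
                municipality = "Medium", none = "Low")
  check <- function(x, map, field) {
    bad <- !(x %in% names(map))
    if (any(bad))
      stop("unknown ", field, " category: ",
           paste(unique(x[bad]), collapse = ", "))
    unname(map[x])
  }
  n <- max(length(evidence), length(source), length(precision))
  data.frame(
    evidence_rel = check(rep_len(evidence, n), ev_map, "evidence"),
    source_rel = check(rep_len(source, n), src_map, "source"),
    precision_rel = check(rep_len(precision, n), prec_map, "precision")
  )
}

# ordering score for the deterministic survivor rule: smaller is better
reliability_rank <- function(rel) {
  v <- c(High = 0L, Medium = 1L, Low = 2L)
  unname(v[rel])
}

#' Thin points to one survivor per grid cell
#'
#' At most one point is retained per `cell_km` x `cell_km` grid cell
#' (anchored at `origin`, floor convention on boundaries). The survivor in
#' each cell is the point with the smallest `priority` value; ties keep the
#' earliest input row. Output preserves input order.
#'
#' @param x,y Projected coordinates in metres.
#' @param cell_km Cell edge in km (> 0).
#' @param origin Grid anchor `c(x, y)` of a cell corner; anchor thinning at
#'   the raster origin so QC and raster stages share cell boundaries.
#' @param priority Optional numeric ranking (smaller wins). Default: first
#'   point in each cell wins.
#' @return Integer indices of the surviving points, in input order.
#' @export
thin_by_grid <- function(x, y, cell_km = 1, origin = c(0, 0),
                         priority = NULL) {
  if (!is.finite(cell_km) || cell_km <= 0) stop("cell_km must be positive")
  n <- length(x)
  if (n == 0) return(integer())
  if (is.null(priority)) priority <- seq_len(n)
  cell <- cell_km * 1000
  key <- paste(floor((x - origin[1]) / cell), floor((y - origin[2]) / cell))
  ord <- order(priority, seq_len(n))
  keep <- ord[!duplicated(key[ord])]
  sort(keep)
}

#' Quality-filter an occurrence-record table
#'
#' Applies, in order, the four rules of the record-cleaning protocol, each
#' logged with a reason code in the audit table:
#' 1. `no_coords` — records lacking coordinates are discarded;
#' 2. `low_reliability` — under the `"moderate"` filter any record with at
#'    least one criterion ranked Low is excluded (the `"strict"` variant
#'    keeps only records ranked High on all three criteria);
#' 3. `duplicate` — exact coordinate duplicates collapse to one record;
#' 4. `grid_redundant` — spatial thinning to one record per `cell_km` grid
#'    cell (see [thin_by_grid()]).
#'
#' The survivor among duplicated / grid-redundant records is the one with
#' the best reliability triple (High > Medium > Low, lexicographic over
#' evidence, source, precision), then the earliest year, then the lowest
#' `record_id`.
#'
#' @param records Data.frame with `record_id`, `x`, `y`, `year`, `evidence`,
#'   `source`, `precision`.
#' @param strictness `"moderate"` (no Low on any criterion) or `"strict"`
#'   (all High).
#' @param cell_km Thinning cell edge in km.
#' @param origin Thinning grid anchor, `c(x, y)`.
#' @return List with `retained` (records plus reliability columns) and
#'   `audit` (`record_id`, `fate` in \{retained, no_coords, low_reliability,
#'   duplicate, grid_redundant\}).
#' @export
filter_records <- function(records, strictness = c("moderate", "strict"),
                           cell_km = 1, origin = c(0, 0)) {
  strictness <- match.arg(strictness)
  fate_levels <- c("retained", "no_coords", "low_reliability", "duplicate",
                   "grid_redundant")
  if (nrow(records) == 0) {
    return(list(
      retained = cbind(records,
                       data.frame(evidence_rel = character(),
                                  source_rel = character(),
                                  precision_rel = character())),
      audit = data.frame(record_id = character(), fate = character())
    ))
  }
  rel <- classify_reliability(records$evidence, records$source,
                              records$precision)
  df <- cbind(records, rel)
  fate <- rep(NA_character_, nrow(df))

  no_coords <- is.na(df$x) | is.na(df$y)
  fate[no_coords] <- "no_coords"

  low <- if (strictness == "moderate") {
    df$evidence_rel == "Low" | df$source_rel == "Low" |
      df$precision_rel == "Low"
  } else {
    !(df$evidence_rel == "High" & df$source_rel == "High" &
        df$precision_rel == "High")
  }
  fate[is.na(fate) & low] <- "low_reliability"

  alive <- which(is.na(fate))
  pri <- order(order(reliability_rank(df$evidence_rel),
                     reliability_rank(df$source_rel),
                     reliability_rank(df$precision_rel),
                     df$year, df$record_id))  # rank: smaller = better survivor
  if (length(alive)) {
    ord <- alive[order(pri[alive])]
    dup_key <- paste(df$x[ord], df$y[ord])
    losers <- ord[duplicated(dup_key)]
    fate[losers] <- "duplicate"
  }

  alive <- which(is.na(fate))
  if (length(alive)) {
    keep <- thin_by_grid(df$x[alive], df$y[alive], cell_km = cell_km,
                         origin = origin, priority = pri[alive])
    fate[setdiff(alive, alive[keep])] <- "grid_redundant"
  }
  fate[is.na(fate)] <- "retained"

  list(
    retained = df[fate == "retained", , drop = FALSE],
    audit = data.frame(record_id = df$record_id,
                       fate = factor(fate, levels = fate_levels))
  )
}

#' Screen collinear environmental variables by Spearman correlation
#'
#' Computes the pairwise Spearman rank correlation matrix (average ranks
#' for ties) and greedily retains variables in order of stated importance:
#' a candidate is dropped when its absolute correlation with any
#' already-retained variable reaches `threshold`. Constant columns, for
#' which the rank correlation is undefined, are flagged and treated as
#' uncorrelated.
#'
#' @param variable_table Numeric matrix or data.frame, observations x
#'   variables, with column names.
#' @param importance_rank Character vector ordering all columns from most
#'   to least important (e.g. by permutation importance).
#' @param threshold Absolute correlation at or above which the
#'   lower-ranked member of a pair is dropped. Default 0.70.
#' @return List: `kept` (character), `dropped` (data.frame `variable`,
#'   `correlated_with`, `rho`), `rho` (full Spearman matrix),
#'   `constant_flagged` (character).
#' @export
screen_collinear_variables <- function(variable_table, importance_rank,
                                       threshold = 0.70) {
  X <- as.matrix(variable_table)
  if (nrow(X) < 3) stop("need at least 3 observations")
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  vars <- colnames(X)
  if (is.null(vars)) stop("variable_table must have column names")
  if (!setequal(importance_rank, vars))
    stop("importance_rank must cover exactly the table's variables")
  rho <- suppressWarnings(stats::cor(X, method = "spearman"))
  constant <- vars[apply(X, 2, function(v) stats::sd(v) == 0)]
  rho_use <- rho
  rho_use[is.na(rho_use)] <- 0        # undefined (constant) => uncorrelated
  kept <- character()
  dropped <- data.frame(variable = character(), correlated_with = character(),
                        rho = numeric())
  for (v in importance_rank) {
    conflict <- kept[abs(rho_use[v, kept]) >= threshold]
    if (length(conflict)) {
      worst <- conflict[which.max(abs(rho_use[v, conflict]))]
      dropped <- rbind(dropped,
                       data.frame(variable = v, correlated_with = worst,
                                  rho = rho[v, worst]))
    } else {
      kept <- c(kept, v)
    }
  }
  list(kept = kept, dropped = dropped, rho = rho, constant_flagged = constant)
}
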