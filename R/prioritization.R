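minmax01 <- function(x) {
  rng <- range(x)
  if (!all(is.finite(rng))) stop("scores contain non-finite values")
  if (diff(rng) == 0) return(rep(1, length(x)))  # degenerate: all best
  (x - rng[1]) / diff(rng)
}

#' Composite conservation score of habitat cores
#'
#' Combines the three prioritization criteria per core: size (log10 area),
#' contribution to connectivity (log10 current-flow centrality) and mean
#' human footprint. Each criterion is min-max normalized to \[0, 1\] before
#' summing so no criterion dominates by unit alone; footprint enters
#' inverted (lower human influence scores higher). The composite score
#' P = z_area + z_centrality + z_footprint_inv lies in \[0, 3\]. An
#' `epsilon` of 1 inside the centrality log sends isolated cores (C = 0) to
#' the bottom of the centrality axis without producing -Inf. With
#' `normalize = FALSE` the raw (log area + log centrality - footprint)
#' sum is returned for sensitivity analysis.
#'
#' @param core_table Data.frame with `core_id`, `area_km2` (> 0),
#'   `centrality` (>= 0) and `mean_footprint` per core.
#' @param epsilon Offset inside the centrality log (default 1).
#' @param normalize Min-max normalize the three components (default TRUE).
#' @return The table with `z_area`, `z_centrality`, `z_footprint_inv` and
#'   `score` appended.
#' @export
composite_score <- function(core_table, epsilon = 1, normalize = TRUE) {
  stopifnot(all(c("core_id", "area_km2", "centrality", "mean_footprint")
                %in% names(core_table)))
  if (nrow(core_table) == 0) {
    core_table$z_area <- core_table$z_centrality <-
      core_table$z_footprint_inv <- core_table$score <- numeric(0)
    return(core_table)
  }
  if (any(core_table$area_km2 <= 0)) stop("core areas must be positive")
  if (any(core_table$centrality < 0)) stop("centrality must be non-negative")
  la <- log10(core_table$area_km2)
  lc <- log10(core_table$centrality + epsilon)
  hf <- core_table$mean_footprint
  if (normalize) {
    core_table$z_area <- minmax01(la)
    core_table$z_centrality <- minmax01(lc)
    # degenerate footprint range counts as best (1), like the other axes
    core_table$z_footprint_inv <- if (diff(range(hf)) == 0)
      rep(1, nrow(core_table)) else 1 - minmax01(hf)
  } else {
    core_table$z_area <- la
    core_table$z_centrality <- lc
    core_table$z_footprint_inv <- -hf
  }
  core_table$score <- core_table$z_area + core_table$z_centrality +
    core_table$z_footprint_inv
  core_table
}

#' Assign ordinal priority categories by equal intervals
#'
#' Splits the observed score range into `k` equal intervals and assigns an
#' ordinal priority from 1 (best existing conditions, highest score) to `k`
#' (most fragmented / most affected, lowest score). Interval upper
#' boundaries belong to the better (lower-numbered neighbouring) category;
#' a degenerate score range puts every core in category 1.
#'
#' @param scored Output of [composite_score()] (needs a `score` column).
#' @param k Number of categories (default 5; must be >= 2).
#' @return The table with an integer `category` column appended.
#' @export
assign_priority <- function(scored, k = 5) {
  if (k < 2) stop("k must be at least 2")
  stopifnot("score" %in% names(scored))
  P <- scored$score
  if (length(P) == 0) {
    scored$category <- integer(0)
    return(scored)
  }
  rng <- range(P)
  if (diff(rng) == 0) {
    scored$category <- rep(1L, length(P))
    return(scored)
  }
  w <- diff(rng) / k
  # 1e-9 guard keeps exact interval boundaries in the better category
  # despite float noise in (P - min) / w
  idx <- ceiling((P - rng[1]) / w - 1e-9)
  scored$category <- as.integer(pmin(k, pmax(1, k + 1 - idx)))
  scored
}

#' Decremental area-centrality regressions
#'
#' Ordinary least squares of current-flow centrality on core area, fitted
#' on all cores and then on nested subsets excluding cores above each size
#' threshold (chained regressions), to locate the core size below which
#' area stops explaining network importance. Fits with fewer than 3 cores
#' or a zero-variance predictor are skipped with a note.
#'
#' @param core_table Data.frame with `area_km2` and `centrality`.
#' @param size_thresholds Decreasing km^2 thresholds; each fit uses cores
#'   with `area_km2 < t`. Default c(2000, 1000, 500, 100).
#' @param log_log Regress log10(C + 1) on log10(A) instead of raw values.
#' @return Data.frame: `subset`, `n`, `slope`, `t_value`, `p_value`,
#'   `adj_r2`, `note`.
#' @export
area_centrality_regression <- function(core_table,
                                       size_thresholds = c(2000, 1000, 500, 100),
                                       log_log = FALSE) {
  fits <- list(all = core_table)
  for (t in size_thresholds)
    fits[[paste0("<", t)]] <- core_table[core_table$area_km2 < t, , drop = FALSE]
  rows <- lapply(names(fits), function(nm) {
    d <- fits[[nm]]
    out <- data.frame(subset = nm, n = nrow(d), slope = NA_real_,
                      t_value = NA_real_, p_value = NA_real_,
                      adj_r2 = NA_real_, note = "")
    if (nrow(d) < 3) {
      out$note <- "skipped: n < 3"
      return(out)
    }
    x <- if (log_log) log10(d$area_km2) else d$area_km2
    y <- if (log_log) log10(d$centrality + 1) else d$centrality
    if (stats::var(x) == 0) {
      out$note <- "skipped: zero variance in predictor"
      return(out)
    }
    fit <- stats::lm(y ~ x)
    sm <- summary(fit)
    out$slope <- sm$coefficients["x", "Estimate"]
    out$t_value <- sm$coefficients["x", "t value"]
    out$p_value <- sm$coefficients["x", "Pr(>|t|)"]
    out$adj_r2 <- sm$adj.r.squared
    out
  })
  do.call(rbind, rows)
}
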