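#' Count perivascular niches in a snapshot
#'
#' A perivascular niche is a blood vessel with at least `min_cells` tumour
#' cells within `radius` distance units (vessel point to cell centre,
#' closed). Counting is per vessel: a tumour cell may contribute to several
#' nearby vessels.
#'
#' @param snapshot Data frame of cell records (one timestep).
#' @param min_cells Minimum tumour cells forming a niche (default 10).
#' @param radius Niche radius in length units (default 5).
#' @return Integer niche count.
#' @export
detect_niches <- function(snapshot, min_cells = 10, radius = 5) {
  v <- snapshot[snapshot$cell_type == "vessel", , drop = FALSE]
  if (nrow(v) == 0) stop("snapshot contains no vessel records")
  tum <- snapshot[snapshot$cell_type == "tumour", , drop = FALSE]
  if (nrow(tum) == 0) return(0L)
  d2 <- outer(v$x, tum$x, "-")^2 + outer(v$y, tum$y, "-")^2
  sum(rowSums(d2 <= radius^2) >= min_cells)
}

#' Binary niche label of a run
#'
#' 1 if the final snapshot (at the series horizon) contains at least one
#' perivascular niche, 0 otherwise. The label depends on the final snapshot
#' only.
#'
#' @param series A `cell_time_series` including its final scheduled
#'   snapshot.
#' @param min_cells,radius Passed to [detect_niches()].
#' @return Integer 0 or 1.
#' @export
label_run <- function(series, min_cells = 10, radius = 5) {
  horizon <- series$params$horizon
  key <- as.character(horizon)
  if (!key %in% names(series$snapshots)) {
    stop(sprintf("series is missing its final snapshot at t = %d", horizon))
  }
  as.integer(detect_niches(series$snapshots[[key]], min_cells, radius) >= 1)
}

#' Benchmark statistics of a snapshot
#'
#' The four non-topological comparison features: tumour cell count,
#' macrophage count, macrophage phenotype ratio M1/M2 and minimum
#' tumour-vessel distance, plus the niche count. The default phenotype
#' ratio is `(1 + #\{p < 0.5\}) / (1 + #\{p >= 0.5\})` (add-one
#' pseudocounts avoid division by zero); `phenotype_ratio_continuous` is the
#' analogous ratio of summed anti- and pro-tumour weights,
#' `(1 + sum(1 - p)) / (1 + sum(p))`. When either the tumour or the vessel
#' set is empty the minimum distance is the domain diagonal sentinel.
#'
#' @param snapshot Data frame of cell records (one timestep).
#' @param domain_size Domain side length used for the distance sentinel.
#' @return One-row data frame with columns `time`, `tumour_count`,
#'   `macrophage_count`, `phenotype_ratio`, `phenotype_ratio_continuous`,
#'   `min_tumour_vessel_distance`, `niche_count`.
#' @export
benchmark_features <- function(snapshot, domain_size = 50) {
  tum <- snapshot[snapshot$cell_type == "tumour", , drop = FALSE]
  mac <- snapshot[snapshot$cell_type == "macrophage", , drop = FALSE]
  v <- snapshot[snapshot$cell_type == "vessel", , drop = FALSE]
  p <- mac$phenotype
  sentinel <- sqrt(2) * domain_size
  min_dist <- if (nrow(tum) == 0 || nrow(v) == 0) sentinel else {
    sqrt(min(outer(tum$x, v$x, "-")^2 + outer(tum$y, v$y, "-")^2))
  }
  data.frame(
    time = if (nrow(snapshot)) snapshot$time[1] else NA_integer_,
    tumour_count = nrow(tum),
    macrophage_count = nrow(mac),
    phenotype_ratio = (1 + sum(p < 0.5)) / (1 + sum(p >= 0.5)),
    phenotype_ratio_continuous = (1 + sum(1 - p)) / (1 + sum(p)),
    min_tumour_vessel_distance = min_dist,
    niche_count = if (nrow(v)) detect_niches(snapshot) else NA_integer_
  )
}
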