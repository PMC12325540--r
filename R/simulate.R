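#' @useDynLib tdaniche, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats dnorm rnorm runif dist sd median coef predict
#' @importFrom utils read.csv head
NULL

vessel_layout <- function(params) {
  centre <- params$domain_size / 2
  r <- 0.36 * params$domain_size
  th <- 2 * pi * (seq_len(params$n_vessels) - 1) / params$n_vessels
  cbind(x = centre + r * cos(th), y = centre + r * sin(th))
}

# hexagonal patch of tumour cells around the domain centre
initial_tumour <- function(params, radius = 2.6, spacing = 1.0) {
  centre <- params$domain_size / 2
  rows <- seq(-3, 3)
  pts <- do.call(rbind, lapply(rows, function(r) {
    yy <- r * spacing * sqrt(3) / 2
    xx <- seq(-4, 4) * spacing + (r %% 2) * spacing / 2
    cbind(xx, yy)
  }))
  pts <- pts[sqrt(rowSums(pts^2)) <= radius, , drop = FALSE]
  cbind(x = centre + pts[, 1], y = centre + pts[, 2])
}

#' Simulate one tumour-macrophage time series
#'
#' Runs the agent-based caricature for `params$horizon` hours on a 1-hour
#' internal tick, recording a snapshot of all cells every
#' `params$snapshot_interval` hours. Vessels are fixed points (ids
#' `1..n_vessels`), the tumour starts as a hexagonal patch at the domain
#' centre, and macrophages appear only at vessels. Cell ids are stable over
#' time and never reused, so consecutive snapshots can be matched by
#' identity.
#'
#' @param params A `simulation_params` object, e.g. from [preset_params()].
#' @return A `cell_time_series`: a list with `snapshots` (a named list of
#'   data frames, one per time `0, 10, ..., horizon`, with columns
#'   `cell_id`, `cell_type`, `x`, `y`, `phenotype`, `time`) and `params`.
#' @export
simulate_run <- function(params) {
  validate_params(params)
  vs <- vessel_layout(params)
  tum <- initial_tumour(params)
  set.seed(params$seed)
  raw <- cpp_simulate(params, vs[, 1], vs[, 2], tum[, 1], tum[, 2])
  df <- data.frame(
    cell_id = raw$cell_id,
    cell_type = c("tumour", "macrophage")[raw$type + 1L],
    x = raw$x, y = raw$y,
    phenotype = raw$phenotype,
    time = raw$time,
    stringsAsFactors = FALSE
  )
  times <- seq(0L, params$horizon, by = params$snapshot_interval)
  vrec <- data.frame(
    cell_id = seq_len(params$n_vessels),
    cell_type = "vessel",
    x = vs[, 1], y = vs[, 2],
    phenotype = NA_real_,
    time = 0L,
    stringsAsFactors = FALSE
  )
  snapshots <- lapply(times, function(t) {
    s <- df[df$time == t, , drop = FALSE]
    v <- vrec
    v$time <- t
    out <- rbind(v, s)
    rownames(out) <- NULL
    out
  })
  names(snapshots) <- as.character(times)
  new_cell_time_series(snapshots, params)
}

new_cell_time_series <- function(snapshots, params) {
  structure(list(snapshots = snapshots, params = params),
            class = "cell_time_series")
}

#' @export
print.cell_time_series <- function(x, ...) {
  tn <- as.integer(names(x$snapshots))
  last <- x$snapshots[[length(x$snapshots)]]
  cat(sprintf(
    "cell_time_series: %d snapshots (t = %d..%d h), final counts: %d tumour, %d macrophage, %d vessel\n",
    length(x$snapshots), min(tn), max(tn),
    sum(last$cell_type == "tumour"), sum(last$cell_type == "macrophage"),
    sum(last$cell_type == "vessel")
  ))
  invisible(x)
}

#' Extract one snapshot from a time series
#'
#' @param series A `cell_time_series`.
#' @param time Snapshot hour; must be one of the recorded times.
#' @return Data frame of cell records at that hour.
#' @export
snapshot_at <- function(series, time) {
  key <- as.character(time)
  if (!key %in% names(series$snapshots)) {
    stop(sprintf("no snapshot at time %s", format(time)))
  }
  series$snapshots[[key]]
}

#' Coordinates of one cell type at one time
#'
#' @inheritParams snapshot_at
#' @param cell_type `"tumour"`, `"macrophage"` or `"vessel"`.
#' @return Two-column matrix of coordinates with cell ids as rownames.
#' @export
points_at <- function(series, time, cell_type) {
  s <- snapshot_at(series, time)
  s <- s[s$cell_type == cell_type, , drop = FALSE]
  m <- cbind(x = s$x, y = s$y)
  rownames(m) <- s$cell_id
  m
}

#' Generate a labelled cohort across the three regimes
#'
#' Produces `n_per_regime` runs of each regime with distinct seeds derived
#' deterministically from `base_seed`.
#'
#' @param n_per_regime Runs per regime (>= 1).
#' @param base_seed Integer base seed.
#' @return A list with `series` (list of `cell_time_series`, length
#'   `3 * n_per_regime`) and `regime` (character vector of regime names).
#' @export
generate_cohort <- function(n_per_regime, base_seed = 0L) {
  stopifnot(n_per_regime >= 1)
  regimes <- c("equilibrium", "elimination", "escape")
  series <- list()
  regime <- character(0)
  for (ri in seq_along(regimes)) {
    for (k in seq_len(n_per_regime)) {
      seed <- (as.integer(base_seed) * 1009L + ri * 131071L + k * 7919L) %% 2147483647L
      series[[length(series) + 1L]] <-
        simulate_run(preset_params(regimes[ri], seed))
      regime <- c(regime, regimes[ri])
    }
  }
  list(series = series, regime = regime)
}
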