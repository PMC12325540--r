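# Hand-built cell_time_series objects for filtration / zigzag / niche tests.

make_series <- function(snap_list, interval = 10, domain_size = 50) {
  times <- (seq_along(snap_list) - 1L) * interval
  snaps <- lapply(seq_along(snap_list), function(i) {
    df <- snap_list[[i]]
    df$time <- times[i]
    df
  })
  names(snaps) <- as.character(times)
  structure(list(snapshots = snaps,
                 params = list(horizon = max(times),
                               snapshot_interval = interval,
                               domain_size = domain_size)),
            class = "cell_time_series")
}

mac_snapshot <- function(ids, x, y) {
  data.frame(cell_id = ids, cell_type = "macrophage", x = x, y = y,
             phenotype = 0, time = 0L)
}

# random dynamic toy run: cells appear/disappear and random-walk; used for
# zigzag invariants
random_toy_series <- function(n_cells, k, seed, step = 1.5, eps = 2) {
  set.seed(seed)
  present <- matrix(runif(n_cells * k) < 0.8, n_cells, k)
  x <- matrix(0, n_cells, k); y <- matrix(0, n_cells, k)
  x[, 1] <- runif(n_cells, 0, 15); y[, 1] <- runif(n_cells, 0, 15)
  for (t in 2:k) {
    x[, t] <- x[, t - 1] + runif(n_cells, -step, step)
    y[, t] <- y[, t - 1] + runif(n_cells, -step, step)
  }
  snaps <- lapply(seq_len(k), function(t) {
    ix <- which(present[, t])
    if (!length(ix)) ix <- 1L  # keep every snapshot nonempty
    mac_snapshot(ix, x[ix, t], y[ix, t])
  })
  make_series(snaps)
}
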