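new_zigzag_intervals <- function(start, end, multiplicity, length_out) {
  df <- data.frame(start = as.integer(start), end = as.integer(end),
                   multiplicity = as.integer(multiplicity))
  if (nrow(df)) {
    agg <- stats::aggregate(multiplicity ~ start + end, data = df, FUN = sum)
    df <- agg[order(agg$start, agg$end), , drop = FALSE]
    rownames(df) <- NULL
  }
  structure(list(intervals = df, length = as.integer(length_out)),
            class = "zigzag_intervals")
}

#' @export
print.zigzag_intervals <- function(x, ...) {
  cat(sprintf("zigzag_intervals: %d intervals over indices 0..%d\n",
              sum(x$intervals$multiplicity), x$length - 1L))
  invisible(x)
}

#' Dimension-0 zigzag persistence of a sequence of complexes
#'
#' Computes the interval decomposition of the dimension-0 zigzag module
#' `H0(K_0) <- H0(I_0) -> H0(K_1) <- ...` of a [build_zigzag_sequence()]
#' output, where each intersection complex includes into its two
#' neighbouring snapshot complexes. Intervals are reported as
#' `(start, end, multiplicity)` over the 0-based sequence indices; an
#' interval records a cluster of cells that exists, as a connected
#' component, at every index it spans.
#'
#' The computation works on the component graph of the sequence: one node
#' per connected component of each complex, with an edge whenever an
#' intersection component includes into a snapshot component. Bars are then
#' the essential interval of each graph component, merge-tree branches of
#' the index function swept upward and downward (elder rule), and one bar
#' per independent cycle, with multiplicities obtained from a first-Betti
#' inclusion-exclusion over index ranges. The per-index multiplicities
#' always sum to the component count of the complex at that index.
#'
#' @param sequence A `zigzag_sequence`.
#' @return A `zigzag_intervals` object.
#' @export
zigzag_ph0 <- function(sequence) {
  stopifnot(inherits(sequence, "zigzag_sequence"))
  complexes <- sequence$complexes
  L <- length(complexes)
  if (L == 0) return(new_zigzag_intervals(integer(0), integer(0), integer(0), 0L))

  # connected components of each complex
  comp <- vector("list", L)    # per complex: component label per vertex
  ncomp <- integer(L)
  for (i in seq_len(L)) {
    fc <- complexes[[i]]
    comp[[i]] <- if (fc$n_points) cpp_components(fc$n_points, fc$edges) else integer(0)
    ncomp[i] <- if (fc$n_points) max(comp[[i]]) else 0L
  }

  # global node ids for (level, component); levels are 0-based
  offset <- c(0L, cumsum(ncomp))
  node_of <- function(i, c) offset[i] + c
  n_nodes <- offset[L + 1L]
  node_level <- rep(seq_len(L) - 1L, times = ncomp)

  # graph edges: intersection component -> containing snapshot component
  ea <- integer(0); eb <- integer(0)
  if (L > 1) {
    for (i in seq(2L, L, by = 2L)) {          # odd 0-based = even R index
      I <- complexes[[i]]
      if (I$n_points == 0) next
      rep_vertex <- match(seq_len(ncomp[i]), comp[[i]])  # one vertex per comp
      rep_lab <- I$labels[rep_vertex]
      for (side in c(-1L, 1L)) {
        K <- complexes[[i + side]]
        ck <- comp[[i + side]][match(rep_lab, K$labels)]
        ea <- c(ea, node_of(i, seq_len(ncomp[i])))
        eb <- c(eb, node_of(i + side, ck))
      }
    }
  }

  starts <- integer(0); ends <- integer(0)

  uf_new <- function(n) seq_len(n)
  uf_find <- function(parent, i) {
    while (parent[i] != i) i <- parent[i]
    i
  }

  # essential bars: one per component of the whole graph, spanning its range
  if (n_nodes > 0) {
    parent <- uf_new(n_nodes)
    for (k in seq_along(ea)) {
      ra <- uf_find(parent, ea[k]); rb <- uf_find(parent, eb[k])
      if (ra != rb) parent[ra] <- rb
    }
    root <- vapply(seq_len(n_nodes), function(i) uf_find(parent, i), integer(1))
    for (r in unique(root)) {
      lv <- node_level[root == r]
      starts <- c(starts, min(lv)); ends <- c(ends, max(lv))
    }
  }

  # merge-tree sweeps: upward (births at min levels, deaths at merges) and
  # downward (the mirror image)
  sweep_bars <- function(up = TRUE) {
    parent <- uf_new(n_nodes)
    extreme <- node_level            # birth level (up) / top level (down)
    lvl_seq <- if (up) sort(unique(node_level)) else rev(sort(unique(node_level)))
    s <- integer(0); e <- integer(0)
    if (length(ea) == 0) return(list(s = s, e = e))
    elo <- pmin(node_level[ea] + 0L, node_level[eb])
    ehi <- pmax(node_level[ea] + 0L, node_level[eb])
    for (lv in lvl_seq) {
      ek <- if (up) which(ehi == lv) else which(elo == lv)
      for (k in ek) {
        ra <- uf_find(parent, ea[k]); rb <- uf_find(parent, eb[k])
        if (ra == rb) next
        if (up) {
          younger <- if (extreme[ra] > extreme[rb]) ra else rb
          elder <- if (younger == ra) rb else ra
          if (extreme[younger] <= lv - 1L) {
            s <- c(s, extreme[younger]); e <- c(e, lv - 1L)
          }
        } else {
          younger <- if (extreme[ra] < extreme[rb]) ra else rb
          elder <- if (younger == ra) rb else ra
          if (extreme[younger] >= lv + 1L) {
            s <- c(s, lv + 1L); e <- c(e, extreme[younger])
          }
        }
        parent[younger] <- elder
        extreme[elder] <- if (up) min(extreme[elder], extreme[younger]) else
          max(extreme[elder], extreme[younger])
      }
    }
    list(s = s, e = e)
  }
  upb <- sweep_bars(TRUE)
  dnb <- sweep_bars(FALSE)
  starts <- c(starts, upb$s, dnb$s)
  ends <- c(ends, upb$e, dnb$e)

  # cycle bars via first-Betti inclusion-exclusion over index ranges:
  # a cycle closed below at y and above at x spans the open range (y, x)
  if (length(ea)) {
    elo <- pmin(node_level[ea], node_level[eb])
    ehi <- pmax(node_level[ea], node_level[eb])
    beta1 <- function(y, x) {
      keep <- which(elo >= y & ehi <= x)
      nodes <- which(node_level >= y & node_level <= x)
      if (!length(nodes)) return(0L)
      idx <- integer(n_nodes); idx[nodes] <- seq_along(nodes)
      parent <- uf_new(length(nodes))
      ncomps <- length(nodes)
      for (k in keep) {
        ra <- uf_find(parent, idx[ea[k]]); rb <- uf_find(parent, idx[eb[k]])
        if (ra != rb) { parent[ra] <- rb; ncomps <- ncomps - 1L }
      }
      length(keep) - length(nodes) + ncomps
    }
    N <- matrix(0L, L, L)   # N[y+1, x+1]
    for (y in 0:(L - 1L)) for (x in y:(L - 1L)) N[y + 1L, x + 1L] <- beta1(y, x)
    for (y in 0:(L - 3L)) {
      for (x in (y + 2L):(L - 1L)) {
        m <- N[y + 1L, x + 1L] - N[y + 2L, x + 1L] -
          (if (x >= y + 1L) N[y + 1L, x] else 0L) + N[y + 2L, x]
        if (m > 0) {
          starts <- c(starts, rep(y + 1L, m)); ends <- c(ends, rep(x - 1L, m))
        }
      }
    }
  }

  new_zigzag_intervals(starts, ends, rep(1L, length(starts)), L)
}

#' Per-index feature multiplicity of a zigzag barcode
#'
#' Sums the multiplicities of all intervals containing each sequence index;
#' by the structure theorem this equals the number of connected components
#' of the complex at that index.
#'
#' @param intervals A `zigzag_intervals` object.
#' @return Integer vector indexed by sequence position (0-based positions
#'   `0..length-1`).
#' @export
zigzag_multiplicity <- function(intervals) {
  L <- intervals$length
  out <- integer(L)
  df <- intervals$intervals
  for (k in seq_len(nrow(df))) {
    ix <- seq(df$start[k], df$end[k]) + 1L
    out[ix] <- out[ix] + df$multiplicity[k]
  }
  out
}
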