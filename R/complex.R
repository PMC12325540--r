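new_filtered_complex <- function(n_points, vertex_values, edges, edge_values,
                                 triangles, triangle_values, max_dim,
                                 kind = "vr", labels = NULL, eps = NA_real_,
                                 basepoint = NULL, radius = NA_real_) {
  structure(list(
    n_points = n_points,
    labels = if (is.null(labels)) seq_len(n_points) else labels,
    vertex_values = vertex_values,
    edges = edges, edge_values = edge_values,
    triangles = triangles, triangle_values = triangle_values,
    max_dim = max_dim, kind = kind, eps = eps,
    basepoint = basepoint, radius = radius
  ), class = "filtered_complex")
}

#' @export
print.filtered_complex <- function(x, ...) {
  cat(sprintf(
    "filtered_complex (%s): %d vertices, %d edges, %d triangles\n",
    x$kind, x$n_points, nrow(x$edges), nrow(x$triangles)
  ))
  invisible(x)
}

as_point_matrix <- function(points) {
  if (is.null(points) || length(points) == 0) {
    return(matrix(numeric(0), ncol = 2))
  }
  points <- as.matrix(points)
  if (ncol(points) != 2) stop("'points' must have two columns")
  storage.mode(points) <- "double"
  points
}

#' Vietoris-Rips filtration of a planar point cloud
#'
#' Builds the filtered complex with a vertex (value 0) per point, an edge per
#' pair at distance `<= max_eps` valued at that distance (closed balls, so an
#' edge appears exactly at `d(x, y)`), and, when `max_dim >= 2`, a triangle
#' per mutually linked triple valued at its longest edge. Simplices are in
#' filtration order, ties broken lexicographically by vertex tuple.
#'
#' @param points Two-column coordinate matrix (possibly empty).
#' @param max_dim Maximum simplex dimension, 0-2.
#' @param max_eps Largest edge length retained.
#' @param labels Optional stable vertex labels (e.g. cell ids).
#' @return A `filtered_complex`.
#' @export
build_vr_filtration <- function(points, max_dim = 2, max_eps, labels = NULL) {
  stopifnot(max_eps > 0, max_dim %in% 0:2)
  points <- as_point_matrix(points)
  n <- nrow(points)
  if (n == 0 || max_dim == 0) {
    sk <- list(edges = matrix(integer(0), ncol = 2), edge_values = numeric(0),
               triangles = matrix(integer(0), ncol = 3),
               triangle_values = numeric(0))
  } else {
    sk <- cpp_vr_skeleton(points[, 1], points[, 2], max_eps, max_dim)
  }
  new_filtered_complex(
    n_points = n, vertex_values = rep(0, n),
    edges = sk$edges, edge_values = sk$edge_values,
    triangles = sk$triangles, triangle_values = sk$triangle_values,
    max_dim = max_dim, kind = "vr", labels = labels, eps = max_eps
  )
}

#' Fixed-radius (static) Vietoris-Rips complex
#'
#' The Vietoris-Rips complex thresholded at `eps` with every filtration value
#' set to 0; the building block for intersection complexes and zigzag
#' sequences.
#'
#' @inheritParams build_vr_filtration
#' @param eps Linkage radius.
#' @return A `filtered_complex` with kind `"fixed"`.
#' @export
build_fixed_complex <- function(points, eps, max_dim = 2, labels = NULL) {
  fc <- build_vr_filtration(points, max_dim = max_dim, max_eps = eps,
                            labels = labels)
  fc$vertex_values <- rep(0, fc$n_points)
  fc$edge_values <- rep(0, nrow(fc$edges))
  fc$triangle_values <- rep(0, nrow(fc$triangles))
  fc$kind <- "fixed"
  fc$eps <- eps
  fc
}

#' Radial filtration about a basepoint
#'
#' Fixes the Vietoris-Rips complex at linkage radius `eps` and refilters it
#' by distance from the basepoint `mu`: a simplex enters at
#' `w = max over its vertices of (R - ||x - mu||)`, so the outermost points
#' appear first and the filtration runs `w = 0..R`. Encodes boundary
#' tortuosity and outgrowths of the cloud.
#'
#' @inheritParams build_fixed_complex
#' @param mu Basepoint (length-2 numeric), by default the domain centre.
#' @param R Maximum radius; every point must satisfy `||x - mu|| < R`.
#' @return A `filtered_complex` with kind `"radial"`.
#' @export
build_radial_filtration <- function(points, eps, mu = c(25, 25), R = 35,
                                    labels = NULL) {
  points <- as_point_matrix(points)
  rad <- sqrt((points[, 1] - mu[1])^2 + (points[, 2] - mu[2])^2)
  if (any(rad >= R)) {
    stop(sprintf("point at radial distance %.3f >= R = %.3f from the basepoint",
                 max(rad), R))
  }
  fc <- build_fixed_complex(points, eps, max_dim = 2, labels = labels)
  vv <- R - rad
  ev <- if (nrow(fc$edges)) pmax(vv[fc$edges[, 1]], vv[fc$edges[, 2]]) else numeric(0)
  tv <- if (nrow(fc$triangles)) {
    pmax(vv[fc$triangles[, 1]], vv[fc$triangles[, 2]], vv[fc$triangles[, 3]])
  } else numeric(0)
  eo <- order(ev, fc$edges[, 1], fc$edges[, 2])
  to <- order(tv, fc$triangles[, 1], fc$triangles[, 2], fc$triangles[, 3])
  new_filtered_complex(
    n_points = fc$n_points, vertex_values = vv,
    edges = fc$edges[eo, , drop = FALSE], edge_values = ev[eo],
    triangles = fc$triangles[to, , drop = FALSE], triangle_values = tv[to],
    max_dim = 2, kind = "radial", labels = labels, eps = eps,
    basepoint = mu, radius = R
  )
}

simplex_keys <- function(m, labels) {
  if (nrow(m) == 0) return(character(0))
  lab <- matrix(labels[m], nrow = nrow(m))
  lab <- t(apply(lab, 1, sort))
  apply(lab, 1, paste, collapse = "|")
}

#' Intersection of two fixed-radius complexes
#'
#' Returns the complex containing exactly the simplices present, by vertex
#' label tuple, in both inputs. Both complexes must share the same linkage
#' radius; vertices are matched by their stable labels (cell ids).
#'
#' @param K1,K2 Fixed complexes from [build_fixed_complex()].
#' @return A `filtered_complex` with kind `"fixed"`.
#' @export
build_intersection_complex <- function(K1, K2) {
  if (!isTRUE(all.equal(K1$eps, K2$eps))) {
    stop("complexes were built at different linkage radii")
  }
  lab <- intersect(K1$labels, K2$labels)
  lab <- lab[order(match(lab, K1$labels))]
  idx1 <- match(lab, K1$labels)
  ek <- intersect(simplex_keys(K1$edges, K1$labels),
                  simplex_keys(K2$edges, K2$labels))
  tk <- intersect(simplex_keys(K1$triangles, K1$labels),
                  simplex_keys(K2$triangles, K2$labels))
  remap <- match(K1$labels, lab)  # old index -> new index (NA if dropped)
  keep_e <- simplex_keys(K1$edges, K1$labels) %in% ek
  keep_t <- simplex_keys(K1$triangles, K1$labels) %in% tk
  edges <- matrix(remap[K1$edges[keep_e, , drop = FALSE]], ncol = 2)
  triangles <- matrix(remap[K1$triangles[keep_t, , drop = FALSE]], ncol = 3)
  new_filtered_complex(
    n_points = length(lab), vertex_values = rep(0, length(lab)),
    edges = edges, edge_values = rep(0, nrow(edges)),
    triangles = triangles, triangle_values = rep(0, nrow(triangles)),
    max_dim = max(K1$max_dim, K2$max_dim), kind = "fixed",
    labels = lab, eps = K1$eps
  )
}

#' Zigzag sequence of snapshot and intersection complexes
#'
#' For snapshot hours `t_1 < ... < t_k`, builds the alternating sequence
#' `K(t_1), K(t_1) ∩ K(t_2), K(t_2), ..., K(t_k)` of length `2k - 1`
#' over the shared cell-id vertex universe: even indices (0-based) are
#' fixed-radius complexes of the chosen cell type, odd indices the
#' intersections of their neighbours. For the default 10-snapshot window the
#' sequence has length 19.
#'
#' @param series A `cell_time_series`.
#' @param cell_type Cell type to track (default `"macrophage"`).
#' @param eps Linkage radius (default 2, the macrophage clustering scale).
#' @param times Snapshot hours; all must be present in `series`.
#' @param max_dim Maximum simplex dimension kept (1 suffices for
#'   dimension-0 zigzag persistence).
#' @return A `zigzag_sequence`: list with `complexes`, `epsilon`, `times`.
#' @export
build_zigzag_sequence <- function(series, cell_type = "macrophage", eps = 2,
                                  times, max_dim = 1) {
  missing_t <- setdiff(as.character(times), names(series$snapshots))
  if (length(missing_t)) {
    stop(sprintf("missing timestep(s): %s", paste(missing_t, collapse = ", ")))
  }
  snaps <- lapply(times, function(t) {
    pts <- points_at(series, t, cell_type)
    build_fixed_complex(pts, eps, max_dim = max_dim,
                        labels = as.integer(rownames(pts)))
  })
  k <- length(snaps)
  complexes <- vector("list", max(2 * k - 1, 0))
  for (i in seq_len(k)) complexes[[2 * i - 1]] <- snaps[[i]]
  if (k > 1) {
    for (i in seq_len(k - 1)) {
      complexes[[2 * i]] <- build_intersection_complex(snaps[[i]], snaps[[i + 1]])
    }
  }
  structure(list(complexes = complexes, epsilon = eps, times = times),
            class = "zigzag_sequence")
}

#' @export
print.zigzag_sequence <- function(x, ...) {
  cat(sprintf("zigzag_sequence: %d complexes (k = %d snapshots), eps = %g\n",
              length(x$complexes), length(x$times), x$epsilon))
  invisible(x)
}

#' Match cells between two snapshots by minimal squared displacement
#'
#' Finds the matching between two unlabeled point sets that minimises the
#' total squared displacement, where unmatched points may pair with the
#' vessel set (with arbitrary multiplicity) to model macrophages entering or
#' leaving the vasculature. Solved as an assignment problem with vessel
#' slots replicated; an approximation of identity tracking for data without
#' stable cell ids.
#'
#' @param points_t,points_t2 Two-column coordinate matrices.
#' @param vessel_points Two-column matrix of vessel locations (may be empty).
#' @return A list with `pairs` (rows `(i, j)` of matched indices), `to_vessel`
#'   (indices of `points_t` matched to a vessel), `from_vessel` (indices of
#'   `points_t2` matched to a vessel) and `cost` (total squared displacement).
#' @export
match_cells_by_transport <- function(points_t, points_t2, vessel_points) {
  p1 <- as_point_matrix(points_t)
  p2 <- as_point_matrix(points_t2)
  vv <- as_point_matrix(vessel_points)
  n1 <- nrow(p1); n2 <- nrow(p2)
  empty <- list(pairs = matrix(integer(0), ncol = 2,
                               dimnames = list(NULL, c("i", "j"))),
                to_vessel = integer(0), from_vessel = integer(0), cost = 0)
  if (n1 + n2 == 0) return(empty)
  sq <- function(a, b) {
    outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
  }
  if (nrow(vv) == 0) {
    if (n1 != n2) {
      stop("point sets of different size require a nonempty vessel set")
    }
    assign <- hungarian_assign(sq(p1, p2))
    pairs <- cbind(i = seq_len(n1), j = assign)
    return(list(pairs = pairs, to_vessel = integer(0),
                from_vessel = integer(0),
                cost = sum(sq(p1, p2)[pairs])))
  }
  # nearest-vessel squared distances (a point matched to "a vessel" always
  # takes its nearest one, since vessel multiplicity is unconstrained)
  nv1 <- if (n1) apply(sq(p1, vv), 1, min) else numeric(0)
  nv2 <- if (n2) apply(sq(p2, vv), 1, min) else numeric(0)
  big <- n1 + n2
  cost <- matrix(0, big, big)
  if (n1 && n2) cost[seq_len(n1), seq_len(n2)] <- sq(p1, p2)
  if (n1) cost[seq_len(n1), n2 + seq_len(n1)] <- nv1  # recycled by column
  if (n2) cost[n1 + seq_len(n2), seq_len(n2)] <-
      matrix(nv2, n2, n2, byrow = TRUE)
  assign <- hungarian_assign(cost)
  ii <- seq_len(n1)
  real <- which(assign[ii] <= n2)
  pairs <- cbind(i = ii[real], j = assign[real])
  from_vessel <- sort(assign[n1 + seq_len(n2)][assign[n1 + seq_len(n2)] <= n2])
  list(pairs = pairs,
       to_vessel = ii[assign[ii] > n2],
       from_vessel = from_vessel,
       cost = sum(cost[cbind(seq_len(big), assign)]))
}

# O(n^3) Hungarian algorithm (shortest augmenting path with dual
# potentials); returns the column assigned to each row.
hungarian_assign <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  # indices shifted by +1: slot 1 is the dummy row/column 0
  u <- numeric(n + 1)
  v <- numeric(n + 1)
  p <- integer(n + 1)    # p[j+1] = row currently assigned to column j
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      free <- which(!used[-1L])              # candidate columns j
      cur <- cost[i0, free] - u[i0 + 1L] - v[free + 1L]
      upd <- cur < minv[free + 1L]
      minv[free[upd] + 1L] <- cur[upd]
      way[free[upd] + 1L] <- j0
      k <- which.min(minv[free + 1L])
      j1 <- free[k]
      delta <- minv[j1 + 1L]
      usedix <- which(used)
      u[p[usedix] + 1L] <- u[p[usedix] + 1L] + delta
      v[usedix] <- v[usedix] - delta
      minv[-usedix] <- minv[-usedix] - delta
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  ans <- integer(n)
  for (j in seq_len(n)) if (p[j + 1L] > 0L) ans[p[j + 1L]] <- j
  ans
}
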