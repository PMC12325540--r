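# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths: single-linkage via stats::hclust, full
# boundary-matrix reduction in plain R, GF(2) limit/colimit ranks for zigzag
# interval multiplicities, closed-form Gaussian integrals, and exhaustive
# enumeration for the transport matching.

# sorted single-linkage merge heights == sorted finite VR dimension-0 deaths
sl_merge_heights <- function(points) {
  if (nrow(points) < 2) return(numeric(0))
  sort(stats::hclust(stats::dist(points), method = "single")$height)
}

# Full persistence by reduction of the complete boundary matrix (all
# dimensions), small inputs only. Returns data frames of (birth, death) per
# homology dimension, death = Inf for unpaired creators.
bf_persistence <- function(fc) {
  simp <- list(); val <- numeric(0); dm <- integer(0)
  for (v in seq_len(fc$n_points)) {
    simp[[length(simp) + 1L]] <- v
    val <- c(val, fc$vertex_values[v]); dm <- c(dm, 0L)
  }
  for (k in seq_len(nrow(fc$edges))) {
    simp[[length(simp) + 1L]] <- sort(fc$edges[k, ])
    val <- c(val, fc$edge_values[k]); dm <- c(dm, 1L)
  }
  for (k in seq_len(nrow(fc$triangles))) {
    simp[[length(simp) + 1L]] <- sort(fc$triangles[k, ])
    val <- c(val, fc$triangle_values[k]); dm <- c(dm, 2L)
  }
  n <- length(simp)
  if (n == 0) {
    e <- data.frame(birth = numeric(0), death = numeric(0))
    return(list(h0 = e, h1 = e))
  }
  k1 <- vapply(simp, function(s) s[1], numeric(1))
  k2 <- vapply(simp, function(s) if (length(s) > 1) s[2] else -1, numeric(1))
  k3 <- vapply(simp, function(s) if (length(s) > 2) s[3] else -1, numeric(1))
  ord <- order(val, dm, k1, k2, k3)
  pos <- integer(n); pos[ord] <- seq_len(n)
  key <- vapply(simp, function(s) paste(s, collapse = "-"), character(1))
  idx <- stats::setNames(pos, key)

  boundary <- function(i) {   # i = filtration position
    s <- simp[[ord[i]]]
    if (length(s) == 1) return(integer(0))
    faces <- lapply(seq_along(s), function(d) s[-d])
    sort(unname(idx[vapply(faces, paste, character(1), collapse = "-")]))
  }
  low2col <- integer(n)      # 0 = none
  cols <- vector("list", n)
  pair_of <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    col <- boundary(i)
    while (length(col)) {
      p <- col[length(col)]
      if (low2col[p] == 0L) break
      other <- cols[[low2col[p]]]
      col <- sort(c(setdiff(col, other), setdiff(other, col)))
    }
    if (length(col)) {
      p <- col[length(col)]
      low2col[p] <- i
      cols[[i]] <- col
      pair_of[p] <- i
    }
  }
  out <- function(d) {
    creators <- which(vapply(seq_len(n), function(i) {
      dm[ord[i]] == d && is.null(cols[[i]])
    }, logical(1)))
    birth <- val[ord[creators]]
    death <- ifelse(is.na(pair_of[creators]), Inf, val[ord[pair_of[creators]]])
    data.frame(birth = birth, death = death)
  }
  list(h0 = out(0L), h1 = out(1L))
}

# ---- GF(2) linear algebra --------------------------------------------------

gf2_rref <- function(A) {
  if (is.null(dim(A))) A <- matrix(A, nrow = 1)
  A <- A %% 2
  m <- nrow(A); n <- ncol(A)
  pivots <- integer(0)
  r <- 0L
  for (col in seq_len(n)) {
    if (r == m) break
    pr <- which(A[(r + 1L):m, col] == 1)
    if (!length(pr)) next
    pr <- pr[1] + r
    if (pr != r + 1L) A[c(r + 1L, pr), ] <- A[c(pr, r + 1L), ]
    r <- r + 1L
    hit <- which(A[, col] == 1)
    hit <- hit[hit != r]
    if (length(hit)) A[hit, ] <- (A[hit, , drop = FALSE] +
                                    matrix(A[r, ], length(hit), n, byrow = TRUE)) %% 2
    pivots <- c(pivots, col)
  }
  list(R = A, rank = r, pivots = pivots)
}

gf2_rank <- function(A) {
  if (length(A) == 0 || nrow(A) == 0 || ncol(A) == 0) return(0L)
  gf2_rref(A)$rank
}

gf2_nullspace <- function(A, nvar) {
  if (length(A) == 0 || nrow(A) == 0) return(diag(1, nvar))
  rr <- gf2_rref(A)
  free <- setdiff(seq_len(nvar), rr$pivots)
  if (!length(free)) return(matrix(0, nvar, 0))
  basis <- matrix(0, nvar, length(free))
  for (j in seq_along(free)) {
    v <- numeric(nvar); v[free[j]] <- 1
    for (i in seq_along(rr$pivots)) {
      v[rr$pivots[i]] <- rr$R[i, free[j]] %% 2
    }
    basis[, j] <- v
  }
  basis
}

# ---- zigzag interval multiplicities by generalized rank --------------------

# independent component labelling (igraph)
oracle_components <- function(fc) {
  if (fc$n_points == 0) return(integer(0))
  g <- igraph::make_empty_graph(n = fc$n_points, directed = FALSE)
  if (nrow(fc$edges)) g <- igraph::add_edges(g, t(fc$edges))
  as.integer(igraph::components(g)$membership)
}

# Interval decomposition multiplicities of the dimension-0 zigzag module,
# from the generalized-rank inclusion-exclusion: r(i, j) is the rank of the
# canonical map lim -> colim of the diagram restricted to [i, j].
zz_oracle <- function(sequence) {
  cx <- sequence$complexes
  L <- length(cx)
  comp <- lapply(cx, oracle_components)
  dims <- vapply(comp, function(z) if (length(z)) max(z) else 0L, integer(1))
  # arrows: odd 0-based index o maps into o - 1 and o + 1
  arrows <- list()
  if (L > 1) {
    for (i in seq(2L, L, by = 2L)) {
      if (cx[[i]]$n_points == 0) { # empty source still constrains nothing
        arrows <- c(arrows, list(list(from = i, to = i - 1L,
                                      M = matrix(0, dims[i - 1L], 0)),
                                 list(from = i, to = i + 1L,
                                      M = matrix(0, dims[i + 1L], 0))))
        next
      }
      repv <- match(seq_len(dims[i]), comp[[i]])
      lab <- cx[[i]]$labels[repv]
      for (side in c(-1L, 1L)) {
        t_ <- i + side
        ct <- comp[[t_]][match(lab, cx[[t_]]$labels)]
        M <- matrix(0, dims[t_], dims[i])
        M[cbind(ct, seq_len(dims[i]))] <- 1
        arrows <- c(arrows, list(list(from = i, to = t_, M = M)))
      }
    }
  }
  block_off <- function(win) c(0L, cumsum(dims[win]))
  r_fun <- function(i, j) {
    win <- i:j
    N <- sum(dims[win])
    if (N == 0 || dims[i] == 0) return(0L)
    off <- block_off(win)
    pos <- function(ix) which(win == ix)
    # constraints: f v_from = v_to for every arrow inside the window
    crows <- list()
    rels <- list()
    for (a in arrows) {
      if (a$from < i || a$from > j || a$to < i || a$to > j) next
      nt <- dims[a$to]
      if (nt == 0) { if (ncol(a$M) == 0) next }
      C <- matrix(0, nt, N)
      fo <- off[pos(a$from)]; to <- off[pos(a$to)]
      if (ncol(a$M)) C[, fo + seq_len(ncol(a$M))] <- a$M
      if (nt) C[, to + seq_len(nt)] <- (C[, to + seq_len(nt), drop = FALSE] +
                                          diag(1, nt)) %% 2
      crows[[length(crows) + 1L]] <- C
      # colimit relations: e(from, c) + M[, c] e(to, .)
      for (cc in seq_len(ncol(a$M))) {
        v <- numeric(N)
        v[fo + cc] <- 1
        v[to + seq_len(nt)] <- (v[to + seq_len(nt)] + a$M[, cc]) %% 2
        rels[[length(rels) + 1L]] <- v
      }
    }
    C <- if (length(crows)) do.call(rbind, crows) else matrix(0, 0, N)
    Nb <- gf2_nullspace(C, N)
    if (ncol(Nb) == 0) return(0L)
    # project limit elements to their block at index i, map into the colimit
    P <- matrix(0, N, ncol(Nb))
    sel <- off[pos(i)] + seq_len(dims[i])
    P[sel, ] <- Nb[sel, , drop = FALSE]
    R <- if (length(rels)) do.call(cbind, rels) else matrix(0, N, 0)
    gf2_rank(cbind(P, R)) - gf2_rank(R)
  }
  rr <- function(i, j) {
    if (i < 0 || j > L - 1L || i > j) return(0L)
    r_fun(i + 1L, j + 1L)
  }
  out <- data.frame(start = integer(0), end = integer(0),
                    multiplicity = integer(0))
  for (s in 0:(L - 1L)) {
    for (e in s:(L - 1L)) {
      m <- rr(s, e) - rr(s - 1L, e) - rr(s, e + 1L) + rr(s - 1L, e + 1L)
      if (m > 0) out <- rbind(out, data.frame(start = s, end = e,
                                              multiplicity = m))
    }
  }
  out
}

# ---- misc oracles ----------------------------------------------------------

# exact mass of a persistence-weighted Gaussian inside the image window
gauss_mass_window <- function(b, p, w, spec) {
  w * (stats::pnorm(spec$birth_range[2], b, spec$sigma) -
         stats::pnorm(spec$birth_range[1], b, spec$sigma)) *
    (stats::pnorm(spec$pers_range[2], p, spec$sigma) -
       stats::pnorm(spec$pers_range[1], p, spec$sigma))
}

# exhaustive minimum-cost matching with vessel slots, tiny inputs only
bf_match_cost <- function(p1, p2, vv) {
  n1 <- nrow(p1); n2 <- nrow(p2)
  sq <- function(a, b) sum((a - b)^2)
  nv <- function(pt) {
    if (nrow(vv) == 0) return(Inf)
    min(apply(vv, 1, function(v) sq(pt, v)))
  }
  best <- Inf
  # choose an injection from a subset of p1 into p2; rest go to vessels
  subs1 <- unlist(lapply(0:n1, function(k) combn(n1, k, simplify = FALSE)),
                  recursive = FALSE)
  for (s1 in subs1) {
    k <- length(s1)
    if (k > n2) next
    targets <- if (k == 0) list(integer(0)) else
      unlist(lapply(combn(n2, k, simplify = FALSE), function(s2) {
        lapply(if (k) asplit(gtools_permutations(k), 1) else list(integer(0)),
               function(p) s2[p])
      }), recursive = FALSE)
    for (t1 in targets) {
      cost <- 0
      if (k) for (q in seq_len(k)) cost <- cost + sq(p1[s1[q], ], p2[t1[q], ])
      un1 <- setdiff(seq_len(n1), s1)
      un2 <- setdiff(seq_len(n2), t1)
      if (length(un1)) cost <- cost + sum(vapply(un1, function(i) nv(p1[i, ]), numeric(1)))
      if (length(un2)) cost <- cost + sum(vapply(un2, function(j) nv(p2[j, ]), numeric(1)))
      best <- min(best, cost)
    }
  }
  best
}

gtools_permutations <- function(k) {
  if (k == 1) return(matrix(1))
  sub <- gtools_permutations(k - 1)
  do.call(rbind, lapply(seq_len(k), function(i) {
    cbind(i, matrix(c(seq_len(k)[-i])[sub], nrow(sub)))
  }))
}
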