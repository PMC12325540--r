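test_that("Vietoris-Rips skeleton matches the closed-ball definition", {
  fc <- build_vr_filtration(rbind(c(0, 0), c(1, 0), c(0, 1)), 2, 2)
  expect_equal(fc$n_points, 3)
  expect_equal(sort(fc$edge_values), c(1, 1, sqrt(2)))
  expect_equal(nrow(fc$triangles), 1)
  expect_equal(fc$triangle_values, sqrt(2))

  single <- build_vr_filtration(matrix(c(3, 4), 1), 2, 2)
  expect_equal(single$n_points, 1)
  expect_equal(nrow(single$edges), 0)

  far <- build_vr_filtration(rbind(c(0, 0), c(3, 0)), 2, 2)
  expect_equal(far$n_points, 2)
  expect_equal(nrow(far$edges), 0)

  empty <- build_vr_filtration(matrix(numeric(0), 0, 2), 2, 1)
  expect_equal(empty$n_points, 0)

  # an edge at exactly max_eps is kept (closed balls)
  at <- build_vr_filtration(rbind(c(0, 0), c(2, 0)), 1, 2)
  expect_equal(nrow(at$edges), 1)
})

test_that("filtration order is by value with lexicographic ties", {
  set.seed(7)
  pts <- matrix(runif(24, 0, 3), ncol = 2)
  fc <- build_vr_filtration(pts, 2, 3)
  expect_true(!is.unsorted(fc$edge_values))
  expect_true(!is.unsorted(fc$triangle_values))
  # simplex values dominate face values
  for (k in seq_len(nrow(fc$triangles))) {
    tri <- fc$triangles[k, ]
    for (pair in list(tri[1:2], tri[c(1, 3)], tri[2:3])) {
      ix <- which(fc$edges[, 1] == pair[1] & fc$edges[, 2] == pair[2])
      expect_true(fc$edge_values[ix] <= fc$triangle_values[k] + 1e-12)
    }
  }
})

test_that("radial filtration values are R minus radial distance, max over vertices", {
  mu <- c(25, 25)
  iso <- rbind(c(25, 55), c(25, 45), c(25, 35))   # radial distances 30, 20, 10
  rf <- build_radial_filtration(iso, eps = 1, mu = mu, R = 35)
  expect_equal(sort(rf$vertex_values), c(5, 15, 25))
  expect_equal(nrow(rf$edges), 0)

  duo <- rbind(c(25, 35), c(25.5, 35))            # both at radial distance ~10
  rf2 <- build_radial_filtration(duo, eps = 1, mu = mu, R = 35)
  expect_equal(nrow(rf2$edges), 1)
  expect_equal(rf2$edge_values, max(rf2$vertex_values))

  at_mu <- build_radial_filtration(rbind(mu, c(25, 30)), eps = 1, mu = mu, R = 35)
  expect_equal(max(at_mu$vertex_values), 35)

  expect_error(build_radial_filtration(rbind(c(25, 61)), eps = 1, mu = mu, R = 35),
               "radial distance")
})

test_that("fixed complex equals the thresholded VR complex with zeroed values", {
  set.seed(11)
  pts <- matrix(runif(30, 0, 5), ncol = 2)
  eps <- 1.4
  vr <- build_vr_filtration(pts, 2, eps)
  fx <- build_fixed_complex(pts, eps, 2)
  key <- function(m) apply(m, 1, paste, collapse = "|")
  expect_setequal(key(vr$edges), key(fx$edges))
  expect_setequal(key(vr$triangles), key(fx$triangles))
  expect_true(all(fx$edge_values == 0))
  expect_true(all(fx$vertex_values == 0))

  chain <- build_fixed_complex(rbind(c(0, 0), c(1, 0), c(2, 0)), 1.2, 2)
  expect_equal(nrow(chain$edges), 2)   # a-b, b-c but d(a, c) > eps
  expect_equal(nrow(chain$triangles), 0)

  tri <- build_fixed_complex(rbind(c(0, 0), c(1, 0), c(0.5, 0.8)), 1.2, 2)
  expect_equal(nrow(tri$triangles), 1)

  expect_equal(build_fixed_complex(matrix(numeric(0), 0, 2), 1, 2)$n_points, 0)
})

test_that("intersection complexes keep simplices present in both inputs", {
  K1 <- build_fixed_complex(rbind(c(0, 0), c(1, 0), c(5, 5)), 1.5, 2,
                            labels = c(10L, 20L, 30L))
  # same cells, a and b moved apart, c gone
  K2 <- build_fixed_complex(rbind(c(0, 0), c(3, 0)), 1.5, 2,
                            labels = c(10L, 20L))
  I <- build_intersection_complex(K1, K2)
  expect_setequal(I$labels, c(10L, 20L))
  expect_equal(nrow(I$edges), 0)

  # idempotence
  II <- build_intersection_complex(K1, K1)
  expect_equal(II$n_points, K1$n_points)
  expect_equal(nrow(II$edges), nrow(K1$edges))
  expect_equal(nrow(II$triangles), nrow(K1$triangles))

  # commutativity and monotonicity on random instances
  set.seed(3)
  for (rep in 1:5) {
    lab <- sample(50, 8)
    A <- build_fixed_complex(matrix(runif(16, 0, 4), ncol = 2), 1.5, 2, labels = lab)
    B <- build_fixed_complex(matrix(runif(16, 0, 4), ncol = 2), 1.5, 2,
                             labels = sample(lab, 6))
    AB <- build_intersection_complex(A, B)
    BA <- build_intersection_complex(B, A)
    keye <- function(K) sort(apply(matrix(K$labels[K$edges], ncol = 2), 1,
                                   function(r) paste(sort(r), collapse = "|")))
    expect_equal(keye(AB), keye(BA))
    expect_true(all(keye(AB) %in% keye(A)))
    expect_true(all(sort(AB$labels) %in% sort(A$labels)))
  }

  expect_error(build_intersection_complex(
    K1, build_fixed_complex(rbind(c(0, 0)), 2.0, 2, labels = 10L)),
    "different linkage radii")
})

test_that("zigzag sequences alternate snapshots and intersections", {
  set.seed(5)
  snaps <- lapply(1:10, function(t) mac_snapshot(1:12, runif(12, 0, 10), runif(12, 0, 10)))
  s <- make_series(snaps)
  zs <- build_zigzag_sequence(s, "macrophage", eps = 2, times = seq(0, 90, 10))
  expect_length(zs$complexes, 19)

  one <- build_zigzag_sequence(s, "macrophage", eps = 2, times = 0)
  expect_length(one$complexes, 1)

  # static points: all five complexes identical
  stat <- make_series(rep(list(mac_snapshot(1:5, 1:5, rep(0, 5))), 3))
  z3 <- build_zigzag_sequence(stat, "macrophage", eps = 1.2, times = c(0, 10, 20))
  expect_length(z3$complexes, 5)
  for (cx in z3$complexes) {
    expect_equal(cx$n_points, 5)
    expect_equal(nrow(cx$edges), 4)
  }

  expect_error(build_zigzag_sequence(s, "macrophage", 2, times = c(0, 15)),
               "missing timestep")
})

test_that("face closure holds for every constructed complex", {
  set.seed(13)
  for (builder in list(
    function(p) build_vr_filtration(p, 2, 2),
    function(p) build_fixed_complex(p, 1.5, 2),
    function(p) build_radial_filtration(p + 20, 1.5, mu = c(22, 22), R = 35)
  )) {
    p <- matrix(runif(20, 0, 4), ncol = 2)
    fc <- builder(p)
    ek <- apply(fc$edges, 1, paste, collapse = "|")
    for (k in seq_len(nrow(fc$triangles))) {
      tri <- fc$triangles[k, ]
      faces <- c(paste(tri[1], tri[2], sep = "|"),
                 paste(tri[1], tri[3], sep = "|"),
                 paste(tri[2], tri[3], sep = "|"))
      expect_true(all(faces %in% ek))
    }
    expect_true(all(fc$edges[, 1] < fc$edges[, 2]))
    if (nrow(fc$triangles)) {
      expect_true(all(fc$triangles[, 1] < fc$triangles[, 2] &
                        fc$triangles[, 2] < fc$triangles[, 3]))
    }
  }
})

test_that("transport matching minimises total squared displacement", {
  novess <- matrix(numeric(0), 0, 2)
  pts <- rbind(c(1, 1), c(4, 2), c(2, 5))
  ident <- match_cells_by_transport(pts, pts, novess)
  expect_equal(ident$pairs[, "j"], 1:3)
  expect_equal(ident$cost, 0)

  moved <- match_cells_by_transport(rbind(c(0, 0)), rbind(c(0.3, 0.4)), novess)
  expect_equal(moved$cost, 0.25)

  # macrophage re-entering a vessel is matched to the nearest vessel
  vv <- rbind(c(10, 0))
  m <- match_cells_by_transport(rbind(c(0, 0), c(9, 0)), rbind(c(0.5, 0)), vv)
  expect_equal(m$to_vessel, 2L)
  expect_equal(unname(m$pairs[, "j"]), 1L)

  # agreement with exhaustive enumeration on random tiny instances
  set.seed(21)
  for (rep in 1:8) {
    n1 <- sample(1:4, 1); n2 <- sample(1:4, 1)
    p1 <- matrix(runif(2 * n1, 0, 6), ncol = 2)
    p2 <- matrix(runif(2 * n2, 0, 6), ncol = 2)
    vv <- matrix(runif(4, 0, 6), ncol = 2)
    got <- match_cells_by_transport(p1, p2, vv)$cost
    expect_equal(got, bf_match_cost(p1, p2, vv), tolerance = 1e-9)
  }
})
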