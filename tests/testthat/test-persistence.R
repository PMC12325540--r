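test_that("dimension-0 barcodes follow the elder rule", {
  duo <- build_vr_filtration(rbind(c(0, 0), c(1, 0)), 1, 2)
  d <- ph0(duo)$pairs
  expect_equal(nrow(d), 2)
  expect_setequal(d$death, c(1, Inf))
  expect_true(all(d$birth == 0))

  col <- build_vr_filtration(cbind(c(0, 1, 3), 0), 1, 5)
  d <- ph0(col)$pairs
  expect_equal(sort(d$death[is.finite(d$death)]), c(1, 2))
  expect_equal(sum(!is.finite(d$death)), 1)

  iso <- build_radial_filtration(rbind(c(25, 55), c(25, 45), c(25, 35)),
                                 eps = 1, mu = c(25, 25), R = 35)
  d <- ph0(iso)$pairs
  expect_equal(sort(d$birth), c(5, 15, 25))
  expect_true(all(!is.finite(d$death)))
})

test_that("finite VR deaths equal single-linkage merge heights", {
  set.seed(42)
  for (rep in 1:25) {
    n <- sample(5:40, 1)
    pts <- matrix(runif(2 * n, 0, 50), ncol = 2)
    d <- ph0(build_vr_filtration(pts, 1, 100))$pairs
    expect_equal(sum(!is.finite(d$death)), 1)
    expect_equal(sort(d$death[is.finite(d$death)]), sl_merge_heights(pts),
                 tolerance = 1e-9)
  }
})

test_that("dimension-1 barcodes are exact on worked shapes", {
  sq <- ph1(build_vr_filtration(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)), 2, 2))$pairs
  expect_equal(nrow(sq), 1)
  expect_equal(c(sq$birth, sq$death), c(1, sqrt(2)), tolerance = 1e-12)

  hexa <- cbind(cos(2 * pi * (0:5) / 6), sin(2 * pi * (0:5) / 6))
  hx <- ph1(build_vr_filtration(hexa, 2, 2.5))$pairs
  expect_equal(nrow(hx), 1)
  expect_equal(c(hx$birth, hx$death), c(1, sqrt(3)), tolerance = 1e-12)

  tri <- ph1(build_vr_filtration(rbind(c(0, 0), c(1, 0), c(0, 1)), 2, 2))$pairs
  expect_equal(nrow(tri), 0)
})

test_that("both engines agree with full boundary-matrix reduction", {
  set.seed(99)
  for (rep in 1:10) {
    n <- sample(6:15, 1)
    pts <- matrix(runif(2 * n, 0, 4), ncol = 2)
    fc <- build_vr_filtration(pts, 2, 3)
    bf <- bf_persistence(fc)
    d0 <- ph0(fc)$pairs
    expect_equal(sort(d0$death[is.finite(d0$death)]),
                 sort(bf$h0$death[is.finite(bf$h0$death)]), tolerance = 1e-9)
    expect_equal(sum(!is.finite(d0$death)), sum(!is.finite(bf$h0$death)))
    d1 <- ph1(fc)$pairs
    bf1 <- bf$h1[bf$h1$death > bf$h1$birth, , drop = FALSE]
    expect_equal(nrow(d1), nrow(bf1))
    if (nrow(d1)) {
      o1 <- order(d1$birth, d1$death); o2 <- order(bf1$birth, bf1$death)
      expect_equal(d1$birth[o1], bf1$birth[o2], tolerance = 1e-9)
      expect_equal(d1$death[o1], bf1$death[o2], tolerance = 1e-9)
    }
  }
})

test_that("Euler characteristic matches alive Betti numbers along the filtration", {
  set.seed(17)
  for (rep in 1:6) {
    n <- sample(6:10, 1)
    pts <- matrix(runif(2 * n, 0, 3), ncol = 2)
    fc <- build_vr_filtration(pts, 2, 3)
    bf <- bf_persistence(fc)
    d0 <- ph0(fc)$pairs
    d1 <- ph1(fc)$pairs
    for (c in c(0.3, 0.8, 1.5, 2.4, 3)) {
      V <- sum(fc$vertex_values <= c)
      E <- sum(fc$edge_values <= c)
      TT <- sum(fc$triangle_values <= c)
      b0 <- sum(d0$birth <= c & d0$death > c)
      b1 <- sum(d1$birth <= c & d1$death > c)
      # dimension-2 classes from an independent GF(2) rank computation
      keep_t <- which(fc$triangle_values <= c)
      b2 <- 0L
      if (length(keep_t)) {
        ekey <- apply(fc$edges, 1, paste, collapse = "|")
        B <- matrix(0, E, length(keep_t))
        for (q in seq_along(keep_t)) {
          tri <- fc$triangles[keep_t[q], ]
          fk <- c(paste(tri[1], tri[2], sep = "|"), paste(tri[1], tri[3], sep = "|"),
                  paste(tri[2], tri[3], sep = "|"))
          B[match(fk, ekey), q] <- 1
        }
        b2 <- length(keep_t) - gf2_rank(B)
      }
      expect_equal(V - E + TT, b0 - b1 + b2)
    }
  }
})

test_that("small perturbations move finite deaths by at most twice the jitter", {
  set.seed(31)
  pts <- matrix(runif(40, 0, 50), ncol = 2)
  gap <- min(dist(pts))
  delta <- gap / 100
  base <- sort(ph0(build_vr_filtration(pts, 1, 100))$pairs$death)
  for (rep in 1:5) {
    jit <- pts + matrix(runif(40, -delta / sqrt(2), delta / sqrt(2)), ncol = 2)
    moved <- sort(ph0(build_vr_filtration(jit, 1, 100))$pairs$death)
    fin <- is.finite(base)
    expect_true(all(abs(moved[fin] - base[fin]) <= 2 * delta + 1e-12))
  }
})
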