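mk_diag <- function(birth, death, dim = 0L, kind = "vr", radius = NA_real_) {
  tdaniche:::new_persistence_diagram(birth, death, rep(dim, length(birth)),
                                     kind = kind, radius = radius)
}

test_that("images are linear in the diagram and zero for empty input", {
  spec <- pi_spec(c(0, 5), c(0, 5), c(20, 20), sigma = 0.25)
  expect_true(all(diagram_to_image(mk_diag(numeric(0), numeric(0)), spec)$grid == 0))

  one <- diagram_to_image(mk_diag(1, 3), spec)
  two <- diagram_to_image(mk_diag(c(1, 1), c(3, 3)), spec)
  expect_equal(two$grid, 2 * one$grid)
  expect_true(all(one$grid >= 0))

  # zero-persistence records contribute exactly nothing
  z <- diagram_to_image(mk_diag(c(1, 2), c(3, 2)), spec)
  expect_equal(z$grid, one$grid)

  expect_error(diagram_to_image(mk_diag(0, Inf), spec), "infinite")
})

test_that("single-record mass matches the closed-form Gaussian integral", {
  # fine pixels relative to sigma so midpoint evaluation approximates the
  # integral closely
  spec <- pi_spec(c(0, 10), c(0, 10), c(50, 50), sigma = 1)
  px_area <- (10 / 50)^2
  for (rec in list(c(2, 5), c(0, 3), c(8.7, 1.2))) {
    img <- diagram_to_image(mk_diag(rec[1], rec[1] + rec[2]), spec)
    expect_equal(sum(img$grid) * px_area,
                 gauss_mass_window(rec[1], rec[2], rec[2], spec),
                 tolerance = 0.01)
  }
})

test_that("one-pixel record translation shifts the mass pattern by one pixel", {
  spec <- pi_spec(c(0, 10), c(0, 10), c(20, 20), sigma = 0.5)
  px <- 0.5
  a <- diagram_to_image(mk_diag(3, 3 + 4), spec)$grid
  b <- diagram_to_image(mk_diag(3 + px, 3 + px + 4), spec)$grid
  expect_equal(b[, -1], a[, -20], tolerance = 1e-12)  # birth axis shift
})

test_that("radial images place finite mass at (radial distance, persistence)", {
  spec <- radial_image_spec()
  d <- mk_diag(25, 31, kind = "radial", radius = 35)   # w-birth 25, w-death 31
  img <- radial_to_image(d, spec)
  xc <- tdaniche:::pixel_centres(0, 35, 35)
  yc <- tdaniche:::pixel_centres(0, 8, 8)
  # mass centroid sits at (R - w_birth, persistence) = (10, 6)
  expect_equal(sum(img$grid %*% xc) / sum(img$grid), 10, tolerance = 0.2)
  expect_equal(sum(yc %*% img$grid) / sum(img$grid), 6, tolerance = 0.2)
  expect_equal(length(img$infinite_profile), 35)
  expect_true(all(img$infinite_profile == 0))
})

test_that("infinite radial features become a 1-D profile with one mode per bar", {
  spec <- radial_image_spec()
  d <- mk_diag(c(5.3, 24.6), c(Inf, Inf), kind = "radial", radius = 35)
  img <- radial_to_image(d, spec)
  expect_true(all(img$grid == 0))
  pr <- img$infinite_profile
  # one contiguous region of profile mass per infinite bar
  runs <- rle(pr > 0.2)
  expect_equal(sum(runs$values), 2)
  xc <- tdaniche:::pixel_centres(0, 35, 35)
  expect_equal(sum(pr * xc) / sum(pr), mean(c(35 - 5.3, 35 - 24.6)),
               tolerance = 0.5)

  dup <- radial_to_image(mk_diag(c(20, 20), c(Inf, Inf), kind = "radial",
                                 radius = 35), spec)
  single <- radial_to_image(mk_diag(20, Inf, kind = "radial", radius = 35), spec)
  expect_equal(dup$infinite_profile, 2 * single$infinite_profile)
})

test_that("vineyard images stack slots and enforce the infinity convention", {
  spec <- vineyard_image_spec(k = 1, pers_hi = 10)
  # k = 1 reduces to a diagram image with birth axis at slot 1
  v <- vineyard_image(list(mk_diag(c(0, 0), c(2, Inf))), spec)
  ref <- diagram_to_image(mk_diag(1, 1 + 2), spec)  # record at (slot 1, pers 2)
  expect_equal(v$grid, ref$grid)

  spec10 <- vineyard_image_spec(k = 10, pers_hi = 10)
  empty <- vineyard_image(rep(list(mk_diag(0, Inf)), 10), spec10)
  expect_true(all(empty$grid == 0))

  # identical diagrams in every slot: interior time-slot marginals agree
  same <- rep(list(mk_diag(rep(0, 3), c(1, 2, Inf))), 10)
  img <- vineyard_image(same, spec10)
  colmass <- colSums(img$grid)
  expect_equal(colmass[4], colmass[7], tolerance = 1e-9)
  expect_equal(colmass[3], colmass[8], tolerance = 1e-9)

  expect_error(vineyard_image(list(mk_diag(c(0, 0), c(Inf, Inf))),
                              vineyard_image_spec(1)), "infinite")
})

test_that("zigzag images weight intervals by their index lifetime", {
  spec <- zigzag_image_spec(19)
  zi <- tdaniche:::new_zigzag_intervals(0L, 18L, 1L, 19L)
  img <- zigzag_image(zi, spec)
  peak <- which(img$grid == max(img$grid), arr.ind = TRUE)
  # kernel at (0, 19): first column, top persistence row (pixel centres at
  # integer coordinates)
  expect_equal(unname(peak[, "col"]), 1)
  expect_equal(unname(peak[, "row"]), 19)

  dbl <- tdaniche:::new_zigzag_intervals(0L, 18L, 2L, 19L)
  expect_equal(zigzag_image(dbl, spec)$grid, 2 * img$grid)

  ones <- tdaniche:::new_zigzag_intervals(0:18, 0:18, rep(1L, 19), 19L)
  img1 <- zigzag_image(ones, spec)
  rowmass <- rowSums(img1$grid)
  expect_equal(which.max(rowmass), 1L)   # lifetime-1 row dominates
})
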