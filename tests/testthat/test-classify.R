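# small synthetic cohort shared across classify tests
local_cohort <- local({
  coh <- NULL
  function() {
    if (is.null(coh)) coh <<- generate_cohort(4, 11)
    coh
  }
})

test_that("featurise produces matched rows, labels and specs", {
  coh <- local_cohort()
  fm <- featurise(coh$series, "vr0_T", 350)
  expect_s3_class(fm, "feature_matrix")
  expect_equal(nrow(fm$features), 12)
  expect_equal(ncol(fm$features), 400)
  expect_equal(fm$labels, vapply(coh$series, label_run, integer(1)))

  rad <- featurise(coh$series, "rad0_T", 350)
  expect_equal(ncol(rad$features), 35 * 8 + 35)

  zz <- featurise(coh$series, "zz0_M", 250)
  expect_equal(ncol(zz$features), 19 * 19)

  ratio <- featurise(coh$series, "bench_ratio", 350)
  expect_equal(ncol(ratio$features), 1)

  expect_error(featurise(coh$series, "not_a_tag", 350))
})

test_that("dynamic tags use the ten snapshots before the analysis time", {
  # a series holding only hours 150..240 plus the labelling snapshot: the
  # zigzag and vineyard windows for t = 250 must succeed, t = 260 must fail
  set.seed(2)
  snaps <- lapply(0:50, function(i) {
    if (i %in% c(15:24, 50)) {
      mac_snapshot(1:8, runif(8, 0, 20), runif(8, 0, 20))
    } else NULL
  })
  s <- make_series(snaps[!vapply(snaps, is.null, logical(1))])
  # rename times to the schedule we kept
  names(s$snapshots) <- as.character(c(seq(150, 240, 10), 500))
  for (i in seq_along(s$snapshots)) {
    s$snapshots[[i]]$time <- as.integer(names(s$snapshots)[i])
  }
  s$params$horizon <- 500L
  # vessels needed for labelling
  s$snapshots[["500"]] <- rbind(
    data.frame(cell_id = 100L, cell_type = "vessel", x = 25, y = 25,
               phenotype = NA_real_, time = 500L),
    s$snapshots[["500"]])
  lst <- list(s, s, s, s)
  fm <- featurise(lst, "zz0_M", 250)
  expect_equal(nrow(fm$features), 4)
  expect_error(featurise(lst, "zz0_M", 260), "missing timestep")
  fmv <- featurise(lst, "vin0_M", 250)
  expect_equal(ncol(fmv$features), 10 * 20)
  expect_error(featurise(lst, "vin0_M", 260), "no snapshot")
})

test_that("cross-validated accuracy behaves at the signal extremes", {
  set.seed(1)
  n <- 40
  labels <- rep(0:1, each = n / 2)

  # no signal: identical features for every run
  flat <- feature_matrix(matrix(1, n, 3) + 0, labels, "vr0_M", 100)
  rep_flat <- fit_logreg_cv(flat, seed = 1, repeats = 3)
  expect_lt(abs(rep_flat$mean_accuracy - 0.5), 0.15)

  # perfectly separable single informative column
  x <- cbind(labels + rnorm(n, 0, 0.01), rnorm(n), rnorm(n))
  sep <- feature_matrix(x, labels, "vr0_M", 100)
  rep_sep <- fit_logreg_cv(sep, seed = 1, repeats = 3)
  expect_gte(rep_sep$mean_accuracy, 0.95)

  # permuted labels destroy the signal
  perm <- feature_matrix(x, sample(labels), "vr0_M", 100)
  rep_perm <- fit_logreg_cv(perm, seed = 1, repeats = 3)
  expect_lt(rep_perm$mean_accuracy, 0.75)

  expect_error(fit_logreg_cv(feature_matrix(x, rep(0L, n), "vr0_M", 100)),
               "single class")
})

test_that("fits are deterministic given the seed", {
  coh <- local_cohort()
  fm <- featurise(coh$series, "bench_distance", 500)
  a <- fit_logreg_cv(fm, seed = 5)
  b <- fit_logreg_cv(fm, seed = 5)
  expect_identical(a$fold_accuracy, b$fold_accuracy)
  expect_identical(a$coefficients, b$coefficients)
})

test_that("accuracy tables cover every tag-time pair", {
  coh <- local_cohort()
  tab <- accuracy_vs_time(coh$series, tags = c("bench_ratio", "bench_distance"),
                          times = c(250, 500), seed = 3)
  expect_equal(nrow(tab), 4)
  expect_true(all(tab$mean_accuracy >= 0 & tab$mean_accuracy <= 1))
  expect_length(attr(tab, "reports"), 4)

  tab2 <- accuracy_vs_time(coh$series, tags = c("bench_ratio", "bench_distance"),
                           times = c(250, 500), seed = 3)
  expect_identical(tab$mean_accuracy, tab2$mean_accuracy)
})

test_that("coefficient maps restore image geometry", {
  coh <- local_cohort()
  fm <- featurise(coh$series, "vr0_M", 350)
  rep_ <- fit_logreg_cv(fm, seed = 2, repeats = 2)
  cm <- coefficient_map(rep_)
  expect_equal(dim(cm$grid), c(20, 20))
  expect_null(cm$profile)
  expect_equal(c(cm$grid), rep_$coefficients)

  rad <- featurise(coh$series, "rad0_T", 350)
  rrep <- fit_logreg_cv(rad, seed = 2, repeats = 2)
  rcm <- coefficient_map(rrep)
  expect_equal(dim(rcm$grid), c(8, 35))
  expect_length(rcm$profile, 35)

  rep0 <- rep_
  rep0$coefficients <- rep(0, 400)
  expect_true(all(coefficient_map(rep0)$grid == 0))

  rep_bad <- rep_
  rep_bad$coefficients <- rep(0, 17)
  expect_error(coefficient_map(rep_bad), "length")
})
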