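#' Pipeline configuration defaults
#'
#' Collects the tunable constants of the featurisation pipeline: linkage
#' radii (tumour 0.7, the optimal tumour connection radius; macrophage 2,
#' the coarser macrophage clustering scale), the radial basepoint and
#' maximum radius, the Vietoris-Rips truncation radii, the image
#' geometries, the 10-snapshot dynamic window and the analysis times.
#'
#' @return A named list; pass (possibly modified) to [featurise()] and
#'   [accuracy_vs_time()].
#' @export
default_config <- function() {
  list(
    eps_tumour = 0.7,
    eps_macrophage = 2,
    basepoint = c(25, 25),
    R = 35,
    vr_max_eps_tumour = 6,
    vr_max_eps_macrophage = 10.5,
    vr_spec_tumour = vr_image_spec(5),
    vr_spec_macrophage = vr_image_spec(10),
    radial_spec = radial_image_spec(),
    profile_length = 35L,
    vineyard_spec = vineyard_image_spec(10, 10),
    zigzag_spec = zigzag_image_spec(19),
    window_snapshots = 10L,
    times = c(250, 300, 350, 400, 450, 500)
  )
}

feature_tags <- function() {
  c("vr0_T", "vr1_T", "vr0_M", "vr1_M", "rad0_T", "vin0_M", "zz0_M",
    "bench_tumour_count", "bench_mac_count", "bench_ratio", "bench_distance")
}

#' Feature-matrix container
#'
#' One row per run (a flattened persistence image or a scalar benchmark),
#' with 0/1 niche labels and the shared image spec.
#'
#' @param features Numeric matrix, one row per run.
#' @param labels Integer 0/1 vector, one per run.
#' @param feature_tag Feature tag string.
#' @param time Analysis hour.
#' @param spec The shared [pi_spec()] (image features), or `NULL`.
#' @param n_dropped_infinite Count of truncated-filtration features dropped
#'   while building the rows.
#' @return A `feature_matrix` object.
#' @export
feature_matrix <- function(features, labels, feature_tag, time, spec = NULL,
                           n_dropped_infinite = 0L) {
  features <- as.matrix(features)
  labels <- as.integer(labels)
  stopifnot(nrow(features) == length(labels), all(labels %in% c(0L, 1L)))
  structure(list(features = features, labels = labels,
                 feature_tag = feature_tag, time = time, spec = spec,
                 n_dropped_infinite = as.integer(n_dropped_infinite)),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf(
    "feature_matrix '%s' at t = %s: %d runs x %d features (%d positive labels, %d truncated features dropped)\n",
    x$feature_tag, format(x$time), nrow(x$features), ncol(x$features),
    sum(x$labels), x$n_dropped_infinite))
  invisible(x)
}

strip_infinite <- function(diagram) {
  n_inf <- nrow(infinite_pairs(diagram))
  diagram$pairs <- finite_pairs(diagram)
  list(diagram = diagram, n_dropped = n_inf)
}

#' Featurise a list of runs at one analysis time
#'
#' Builds the feature matrix of one feature tag for every run. Static tags
#' (`vr0_T`, `vr1_T`, `vr0_M`, `vr1_M`, `rad0_T`, `bench_*`) use only the
#' snapshot at `time`; dynamic tags (`vin0_M`, `zz0_M`) use the 10-snapshot
#' window `time - 100, time - 90, ..., time - 10`. Vietoris-Rips features
#' still alive at the truncation radius are dropped and counted (for
#' dimension-0 these are the components present at full scale, whose count
#' carries no multi-scale information); radial infinite features are
#' instead kept as the appended 1-D profile. Labels come from
#' [label_run()] on each series.
#'
#' @param series_list List of `cell_time_series`.
#' @param feature_tag One of `vr0_T`, `vr1_T`, `vr0_M`, `vr1_M`, `rad0_T`,
#'   `vin0_M`, `zz0_M`, `bench_tumour_count`, `bench_mac_count`,
#'   `bench_ratio`, `bench_distance`.
#' @param time Analysis hour.
#' @param config See [default_config()].
#' @return A [feature_matrix()].
#' @export
featurise <- function(series_list, feature_tag, time,
                      config = default_config()) {
  feature_tag <- match.arg(feature_tag, feature_tags())
  labels <- vapply(series_list, label_run, integer(1))
  dropped <- 0L
  spec <- NULL

  image_row <- function(img) c(c(img$grid), img$infinite_profile)

  if (startsWith(feature_tag, "bench_")) {
    col <- switch(feature_tag,
      bench_tumour_count = "tumour_count",
      bench_mac_count = "macrophage_count",
      bench_ratio = "phenotype_ratio",
      bench_distance = "min_tumour_vessel_distance")
    rows <- vapply(series_list, function(s) {
      benchmark_features(snapshot_at(s, time), s$params$domain_size)[[col]]
    }, numeric(1))
    return(feature_matrix(matrix(rows, ncol = 1,
                                 dimnames = list(NULL, col)),
                          labels, feature_tag, time))
  }

  if (feature_tag %in% c("vr0_T", "vr1_T", "vr0_M", "vr1_M")) {
    tumour <- endsWith(feature_tag, "_T")
    dim1 <- feature_tag %in% c("vr1_T", "vr1_M")
    ctype <- if (tumour) "tumour" else "macrophage"
    max_eps <- if (tumour) config$vr_max_eps_tumour else config$vr_max_eps_macrophage
    spec <- if (tumour) config$vr_spec_tumour else config$vr_spec_macrophage
    rows <- lapply(series_list, function(s) {
      pts <- points_at(s, time, ctype)
      fc <- build_vr_filtration(pts, max_dim = if (dim1) 2 else 1,
                                max_eps = max_eps)
      dg <- if (dim1) ph1(fc) else ph0(fc)
      st <- strip_infinite(dg)
      dropped <<- dropped + st$n_dropped
      image_row(diagram_to_image(st$diagram, spec))
    })
  } else if (feature_tag == "rad0_T") {
    spec <- config$radial_spec
    rows <- lapply(series_list, function(s) {
      pts <- points_at(s, time, "tumour")
      # cells clamped at the domain boundary can exceed the basepoint radius;
      # they are outside the radial window and are dropped (and counted)
      rad <- sqrt((pts[, 1] - config$basepoint[1])^2 +
                    (pts[, 2] - config$basepoint[2])^2)
      dropped <<- dropped + sum(rad >= config$R)
      pts <- pts[rad < config$R, , drop = FALSE]
      fc <- build_radial_filtration(pts, eps = config$eps_tumour,
                                    mu = config$basepoint, R = config$R)
      image_row(radial_to_image(ph0(fc), spec, config$profile_length))
    })
  } else if (feature_tag == "vin0_M") {
    k <- config$window_snapshots
    window <- time - rev(seq_len(k)) * 10
    spec <- config$vineyard_spec
    rows <- lapply(series_list, function(s) {
      diagrams <- lapply(window, function(t) {
        fc <- build_vr_filtration(points_at(s, t, "macrophage"), max_dim = 1,
                                  max_eps = config$vr_max_eps_macrophage)
        st <- strip_infinite(ph0(fc))
        dropped <<- dropped + st$n_dropped
        st$diagram
      })
      image_row(vineyard_image(diagrams, spec))
    })
  } else if (feature_tag == "zz0_M") {
    k <- config$window_snapshots
    window <- time - rev(seq_len(k)) * 10
    spec <- config$zigzag_spec
    rows <- lapply(series_list, function(s) {
      zs <- build_zigzag_sequence(s, "macrophage", eps = config$eps_macrophage,
                                  times = window)
      image_row(zigzag_image(zigzag_ph0(zs), spec))
    })
  }

  feature_matrix(do.call(rbind, rows), labels, feature_tag, time, spec,
                 n_dropped_infinite = dropped)
}

stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    ix <- which(labels == cl)
    fold[ix] <- sample(rep(seq_len(k), length.out = length(ix)))
  }
  fold
}

#' Cross-validated L2 logistic regression on a feature matrix
#'
#' Ridge-penalised logistic regression (glmnet, alpha = 0) evaluated by
#' `repeats` independent seeded repeats of stratified `folds`-fold
#' cross-validation; the reported accuracy is the mean held-out accuracy
#' over all repeat x fold evaluations. The regularisation strength is
#' selected by inner cross-validation on a logarithmic lambda grid within
#' each training set. Features are not standardised, so coefficients stay
#' in image units. Coefficients come from a final inner-CV fit on all data.
#'
#' @param fm A [feature_matrix()] with at least two examples per class.
#' @param seed Integer seed controlling all fold assignments.
#' @param folds,repeats Cross-validation geometry (default stratified
#'   5-fold repeated 10 times).
#' @return A `classifier_report`: mean_accuracy, accuracy_sd (over folds),
#'   fold_accuracy, baseline (majority fraction), coefficients, intercept,
#'   lambda, folds, repeats, feature_tag, time, spec.
#' @export
fit_logreg_cv <- function(fm, seed = 0L, folds = 5L, repeats = 10L) {
  stopifnot(inherits(fm, "feature_matrix"))
  x <- fm$features
  y <- fm$labels
  if (length(unique(y)) < 2) stop("labels contain a single class")
  if (min(table(y)) < 2) stop("need at least two examples per class")
  baseline <- max(table(y)) / length(y)
  lambda_grid <- 10^seq(2, -4, length.out = 25)
  varying <- apply(x, 2, function(col) stats::var(col) > 0)

  set.seed(as.integer(seed))
  fit_one <- function(xtr, ytr) {
    if (length(unique(ytr)) < 2 || !any(varying)) return(NULL)
    if (ncol(xtr) == 1) {
      # scalar benchmark: unpenalised logistic regression
      df <- data.frame(y = ytr, f = xtr[, 1])
      return(structure(suppressWarnings(stats::glm(y ~ f, df, family = stats::binomial())),
                       class = c("bench_glm", "glm", "lm")))
    }
    foldid <- stratified_folds(ytr, min(5L, min(table(ytr))))
    # small inner folds trigger a benign class-size warning from glmnet
    suppressWarnings(
      glmnet::cv.glmnet(xtr, ytr, family = "binomial", alpha = 0,
                        lambda = lambda_grid, foldid = foldid,
                        standardize = FALSE)
    )
  }
  predict_class <- function(fit, xte) {
    if (inherits(fit, "bench_glm")) {
      pr <- stats::predict.glm(fit, newdata = data.frame(f = xte[, 1]),
                               type = "response")
      as.integer(pr >= 0.5)
    } else {
      as.integer(predict(fit, xte, s = "lambda.min", type = "class"))
    }
  }
  acc <- numeric(0)
  for (r in seq_len(repeats)) {
    fold <- stratified_folds(y, folds)
    for (f in seq_len(folds)) {
      test <- fold == f
      cv <- fit_one(x[!test, , drop = FALSE], y[!test])
      pred <- if (is.null(cv)) {
        rep(as.integer(names(which.max(table(y[!test])))), sum(test))
      } else {
        predict_class(cv, x[test, , drop = FALSE])
      }
      acc <- c(acc, mean(pred == y[test]))
    }
  }
  final <- fit_one(x, y)
  if (is.null(final)) {
    coefs <- rep(0, ncol(x)); intercept <- 0; lambda <- NA_real_
  } else if (inherits(final, "bench_glm")) {
    cf <- stats::coef(final)
    intercept <- unname(cf[1]); coefs <- unname(cf[2]); lambda <- 0
  } else {
    cf <- as.numeric(coef(final, s = "lambda.min"))
    intercept <- cf[1]
    coefs <- cf[-1]
    lambda <- final$lambda.min
  }
  structure(list(
    mean_accuracy = mean(acc), accuracy_sd = sd(acc), fold_accuracy = acc,
    baseline = baseline, coefficients = coefs, intercept = intercept,
    lambda = lambda, folds = folds, repeats = repeats,
    feature_tag = fm$feature_tag, time = fm$time, spec = fm$spec
  ), class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf(
    "classifier_report '%s' at t = %s: accuracy %.3f (sd %.3f, baseline %.3f) over %d x %d-fold CV\n",
    x$feature_tag, format(x$time), x$mean_accuracy, x$accuracy_sd,
    x$baseline, x$repeats, x$folds))
  invisible(x)
}

#' Accuracy of every feature tag across analysis times
#'
#' Runs [featurise()] then [fit_logreg_cv()] for each (tag, time)
#' combination and collects a long-format table. The per-combination
#' `classifier_report`s (for coefficient maps) are attached as the
#' `"reports"` attribute, named `"tag@time"`.
#'
#' @param series_list List of `cell_time_series`.
#' @param tags Feature tags (default all seven topological + four
#'   benchmarks).
#' @param times Analysis hours.
#' @param config See [default_config()].
#' @param seed Seed passed to every fit.
#' @return Data frame with columns `feature_tag`, `time`, `mean_accuracy`,
#'   `accuracy_sd`, `baseline`, `folds`, `repeats`.
#' @export
accuracy_vs_time <- function(series_list, tags = feature_tags(),
                             times = default_config()$times,
                             config = default_config(), seed = 0L) {
  rows <- list()
  reports <- list()
  for (tag in tags) {
    for (t in times) {
      fm <- featurise(series_list, tag, t, config)
      rep_ <- fit_logreg_cv(fm, seed = seed)
      reports[[sprintf("%s@%d", tag, t)]] <- rep_
      rows[[length(rows) + 1L]] <- data.frame(
        feature_tag = tag, time = t, mean_accuracy = rep_$mean_accuracy,
        accuracy_sd = rep_$accuracy_sd, baseline = rep_$baseline,
        folds = rep_$folds, repeats = rep_$repeats
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "reports") <- reports
  out
}

#' Reshape classifier coefficients to image geometry
#'
#' Inverts the row-flattening of [featurise()]: image coefficients return
#' as a signed (ny x nx) grid; for radial features the trailing profile
#' coefficients are split off as a signed 1-D vector.
#'
#' @param report A `classifier_report` from an image-based feature tag.
#' @param image_spec The [pi_spec()] used to build the features (defaults
#'   to the one stored in the report).
#' @return List with `grid` (ny x nx matrix) and `profile` (vector or
#'   `NULL`).
#' @export
coefficient_map <- function(report, image_spec = report$spec) {
  if (is.null(image_spec)) stop("report does not carry an image spec")
  nx <- image_spec$resolution[1]; ny <- image_spec$resolution[2]
  cf <- report$coefficients
  extra <- length(cf) - nx * ny
  if (extra < 0) stop("coefficient length does not match the image geometry")
  grid <- matrix(cf[seq_len(nx * ny)], ny, nx)
  profile <- if (extra > 0) cf[nx * ny + seq_len(extra)] else NULL
  list(grid = grid, profile = profile)
}

#' Plot an accuracy-versus-time table
#'
#' @param table Output of [accuracy_vs_time()].
#' @return A ggplot object.
#' @export
plot_accuracy_vs_time <- function(table) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  topological <- !startsWith(table$feature_tag, "bench_")
  table$class <- ifelse(topological, "topological", "benchmark")
  ggplot2::ggplot(table, ggplot2::aes(x = time, y = mean_accuracy,
                                      colour = feature_tag,
                                      linetype = class)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "analysis time (h)", y = "CV accuracy") +
    ggplot2::ylim(0, 1)
}
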