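#' Persistence-image specification
#'
#' Axis windows, pixel resolution and Gaussian kernel width shared by all
#' persistence-image constructors. Images from different runs are comparable
#' (and may enter one feature matrix) only under identical specs.
#'
#' @param birth_range Length-2 numeric, x-axis window (birth, radial birth
#'   distance, time slot or sequence index depending on the vectorisation).
#' @param pers_range Length-2 numeric, y-axis (persistence) window.
#' @param resolution Integer `(nx, ny)` pixel counts.
#' @param sigma Kernel standard deviation, in axis units.
#' @param weight Weighting tag; only `"linear_persistence"` is defined: each
#'   record contributes its persistence times a unit-mass isotropic Gaussian.
#' @return A `pi_spec` object.
#' @export
pi_spec <- function(birth_range, pers_range, resolution, sigma,
                    weight = "linear_persistence") {
  stopifnot(length(birth_range) == 2, birth_range[2] > birth_range[1],
            length(pers_range) == 2, pers_range[2] > pers_range[1],
            length(resolution) == 2, all(resolution >= 1),
            sigma > 0)
  weight <- match.arg(weight, "linear_persistence")
  structure(list(birth_range = as.numeric(birth_range),
                 pers_range = as.numeric(pers_range),
                 resolution = as.integer(resolution),
                 sigma = as.numeric(sigma), weight = weight),
            class = "pi_spec")
}

#' @export
print.pi_spec <- function(x, ...) {
  cat(sprintf("pi_spec: %dx%d pixels, birth [%g, %g], persistence [%g, %g], sigma %g\n",
              x$resolution[1], x$resolution[2], x$birth_range[1], x$birth_range[2],
              x$pers_range[1], x$pers_range[2], x$sigma))
  invisible(x)
}

pixel_centres <- function(lo, hi, n) {
  w <- (hi - lo) / n
  lo + w * (seq_len(n) - 0.5)
}

new_persistence_image <- function(grid, spec, infinite_profile = NULL) {
  structure(list(grid = grid, spec = spec,
                 infinite_profile = infinite_profile),
            class = "persistence_image")
}

#' @export
print.persistence_image <- function(x, ...) {
  cat(sprintf("persistence_image: %dx%d grid, total mass %.4g%s\n",
              nrow(x$grid), ncol(x$grid), sum(x$grid),
              if (is.null(x$infinite_profile)) "" else
                sprintf(", infinite profile length %d", length(x$infinite_profile))))
  invisible(x)
}

# Sum of persistence-weighted isotropic Gaussians evaluated at pixel
# centres. `xs`, `ys`, `w` give kernel centres and weights. The grid is
# (ny x nx), row i = i-th persistence bin (ascending), column j = j-th
# birth-axis bin.
kernel_grid <- function(xs, ys, w, spec) {
  nx <- spec$resolution[1]; ny <- spec$resolution[2]
  grid <- matrix(0, ny, nx)
  if (length(xs) == 0) return(grid)
  xc <- pixel_centres(spec$birth_range[1], spec$birth_range[2], nx)
  yc <- pixel_centres(spec$pers_range[1], spec$pers_range[2], ny)
  for (k in seq_along(xs)) {
    if (w[k] == 0) next
    gx <- dnorm(xc, mean = xs[k], sd = spec$sigma)
    gy <- dnorm(yc, mean = ys[k], sd = spec$sigma)
    grid <- grid + w[k] * tcrossprod(gy, gx)
  }
  grid
}

#' Persistence image of a diagram
#'
#' Maps each finite record `(b, d)` to birth-persistence coordinates
#' `(b, d - b)` and accumulates, for every record, its persistence times an
#' isotropic Gaussian kernel of width `sigma` evaluated at pixel centres.
#' Infinite records must be removed (or routed to [radial_to_image()] /
#' dropped per the vineyard convention) by the caller.
#'
#' @param diagram A `persistence_diagram` with finite records only.
#' @param spec A [pi_spec()].
#' @return A `persistence_image`.
#' @export
diagram_to_image <- function(diagram, spec) {
  stopifnot(inherits(diagram, "persistence_diagram"), inherits(spec, "pi_spec"))
  if (nrow(infinite_pairs(diagram)) > 0) {
    stop("diagram contains infinite records; remove or route them first")
  }
  p <- diagram$pairs
  new_persistence_image(kernel_grid(p$birth, p$death - p$birth,
                                    p$death - p$birth, spec), spec)
}

#' Two-part persistence image of a radial filtration
#'
#' Finite dimension-0 records are plotted at x = radial birth distance
#' `R - w_birth` (distance of the feature's outermost cell from the
#' basepoint) and y = persistence `w_death - w_birth`, weighted linearly by
#' persistence. Infinite records - the connected components of the
#' underlying fixed-radius complex - are vectorised separately as a 1-D
#' profile over the same radial-distance axis, summing unit-mass 1-D
#' Gaussians of the same `sigma` centred at each component's birth distance.
#'
#' @param diagram A `persistence_diagram` from a radial filtration (it
#'   carries the basepoint radius `R`).
#' @param spec A [pi_spec()]; the default is the 35 x 8 unit-pixel window.
#' @param profile_length Number of bins of the infinite-feature profile over
#'   `birth_range`.
#' @return A `persistence_image` with an `infinite_profile` vector.
#' @export
radial_to_image <- function(diagram, spec = radial_image_spec(),
                            profile_length = 35) {
  stopifnot(inherits(diagram, "persistence_diagram"))
  if (diagram$kind != "radial" || !is.finite(diagram$radius)) {
    stop("'diagram' must come from a radial filtration")
  }
  R <- diagram$radius
  fin <- finite_pairs(diagram)
  grid <- kernel_grid(R - fin$birth, fin$death - fin$birth,
                      fin$death - fin$birth, spec)
  inf <- infinite_pairs(diagram)
  xc <- pixel_centres(spec$birth_range[1], spec$birth_range[2], profile_length)
  profile <- rep(0, profile_length)
  for (b in inf$birth) profile <- profile + dnorm(xc, mean = R - b, sd = spec$sigma)
  new_persistence_image(grid, spec, infinite_profile = profile)
}

#' Vineyard persistence image from stacked dimension-0 diagrams
#'
#' Stacks `k` consecutive-snapshot Vietoris-Rips dimension-0 diagrams along
#' a time axis: the record set of the diagram in slot `j` (1-based)
#' contributes Gaussians at `(j, death)` weighted by the death radius, a
#' piecewise approximation of the vines traced by cluster features over
#' time. Exactly one infinite record per slot (the everlasting component)
#' is discarded; any further infinite record signals a truncated filtration
#' and raises an error.
#'
#' @param diagrams List of `k` dimension-0 `persistence_diagram`s, ordered
#'   by snapshot time.
#' @param spec A [pi_spec()]; x axis in slot units (slot `j` at x = j).
#' @return A `persistence_image`.
#' @export
vineyard_image <- function(diagrams, spec) {
  xs <- numeric(0); ys <- numeric(0)
  for (j in seq_along(diagrams)) {
    d <- diagrams[[j]]
    stopifnot(inherits(d, "persistence_diagram"))
    n_inf <- nrow(infinite_pairs(d))
    if (n_inf > 1) {
      stop(sprintf("slot %d has %d infinite records; expected at most one",
                   j, n_inf))
    }
    fin <- finite_pairs(d)
    xs <- c(xs, rep(j, nrow(fin)))
    ys <- c(ys, fin$death - fin$birth)
  }
  new_persistence_image(kernel_grid(xs, ys, ys, spec), spec)
}

#' Persistence image of a zigzag barcode
#'
#' Each interval `(s, e, m)` over sequence indices contributes `m` Gaussians
#' at `(s, e - s + 1)` - birth index against lifetime in indices - weighted
#' by the lifetime.
#'
#' @param intervals A `zigzag_intervals` object.
#' @param spec A [pi_spec()]; both axes in sequence-index units.
#' @return A `persistence_image`.
#' @export
zigzag_image <- function(intervals, spec = zigzag_image_spec()) {
  stopifnot(inherits(intervals, "zigzag_intervals"))
  df <- intervals$intervals
  len <- df$end - df$start + 1
  xs <- rep(df$start, df$multiplicity)
  ys <- rep(len, df$multiplicity)
  new_persistence_image(kernel_grid(xs, ys, ys, spec), spec)
}

# ---- default image geometries ---------------------------------------------

#' Default image specs for each vectorisation
#'
#' The defaults fix comparable geometries for the feature tags: 20 x 20
#' pixels over `[0, 5]` (tumour) or `[0, 10]` (macrophage) birth/persistence
#' windows with sigma half a pixel; a 35 x 8 unit-pixel window with a
#' length-35 profile for the radial variant; slot/index axes at one unit per
#' step for the time-dependent variants.
#'
#' @param window Upper end of both axes.
#' @param k Number of vineyard slots.
#' @param pers_hi Upper persistence window of the vineyard image.
#' @param len Zigzag sequence length.
#' @return A [pi_spec()].
#' @export
vr_image_spec <- function(window = 5) {
  px <- window / 20
  pi_spec(c(0, window), c(0, window), c(20L, 20L), sigma = px / 2)
}

#' @rdname vr_image_spec
#' @export
radial_image_spec <- function() {
  pi_spec(c(0, 35), c(0, 8), c(35L, 8L), sigma = 0.5)
}

#' @rdname vr_image_spec
#' @export
vineyard_image_spec <- function(k = 10, pers_hi = 10) {
  pi_spec(c(0.5, k + 0.5), c(0, pers_hi), c(as.integer(k), 20L), sigma = 0.5)
}

#' @rdname vr_image_spec
#' @export
zigzag_image_spec <- function(len = 19) {
  pi_spec(c(-0.5, len - 0.5), c(0.5, len + 0.5), c(as.integer(len), as.integer(len)),
          sigma = 0.5)
}
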