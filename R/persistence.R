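new_persistence_diagram <- function(birth, death, dimension, kind = "vr",
                                    radius = NA_real_) {
  structure(list(
    pairs = data.frame(birth = as.numeric(birth), death = as.numeric(death),
                       dimension = as.integer(dimension)),
    kind = kind, radius = radius
  ), class = "persistence_diagram")
}

#' @export
print.persistence_diagram <- function(x, ...) {
  nf <- sum(is.finite(x$pairs$death))
  cat(sprintf("persistence_diagram (%s): %d features (%d finite, %d infinite)\n",
              x$kind, nrow(x$pairs), nf, nrow(x$pairs) - nf))
  invisible(x)
}

#' Dimension-0 persistent homology
#'
#' Computes the dimension-0 barcode of a filtered complex by a union-find
#' sweep over the edges in filtration order. Births are the vertex
#' filtration values (all 0 for Vietoris-Rips; the radial entry value for
#' radial filtrations); when two components merge the younger one dies at
#' the edge value (elder rule, ties broken so the component containing the
#' smallest vertex index survives). Components alive at the end of the
#' filtration are reported with infinite death, so the number of bars equals
#' the number of points.
#'
#' @param filtration A `filtered_complex`.
#' @return A `persistence_diagram` with one dimension-0 record per point.
#' @export
ph0 <- function(filtration) {
  stopifnot(inherits(filtration, "filtered_complex"))
  bars <- cpp_ph0(filtration$vertex_values, filtration$edges,
                  filtration$edge_values)
  new_persistence_diagram(bars[, 1], bars[, 2],
                          rep(0L, nrow(bars)),
                          kind = filtration$kind,
                          radius = filtration$radius)
}

#' Dimension-1 persistent homology
#'
#' Standard boundary-matrix reduction over the field with two elements, in
#' filtration order: each triangle column (its three boundary edges) is
#' reduced against previously reduced columns; a surviving pivot edge pairs
#' that edge's birth with the triangle's value. Cycle-creating edges never
#' paired by a triangle yield infinite bars.
#'
#' @param filtration A `filtered_complex` built with `max_dim = 2`.
#' @return A `persistence_diagram` of dimension-1 records.
#' @export
ph1 <- function(filtration) {
  stopifnot(inherits(filtration, "filtered_complex"))
  bars <- cpp_ph1(filtration$n_points, filtration$edges,
                  filtration$edge_values, filtration$triangles,
                  filtration$triangle_values)
  # zero-persistence pairs are artefacts of simultaneous simplex entry
  bars <- bars[bars[, 2] > bars[, 1], , drop = FALSE]
  new_persistence_diagram(bars[, 1], bars[, 2],
                          rep(1L, nrow(bars)),
                          kind = filtration$kind,
                          radius = filtration$radius)
}

finite_pairs <- function(diagram) {
  diagram$pairs[is.finite(diagram$pairs$death), , drop = FALSE]
}

infinite_pairs <- function(diagram) {
  diagram$pairs[!is.finite(diagram$pairs$death), , drop = FALSE]
}
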