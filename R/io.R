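num17 <- function(x) {
  out <- formatC(x, digits = 17, format = "g")
  out[is.na(x)] <- ""
  out
}

#' Write / read cell tables
#'
#' Cell tables are CSV files with header
#' `cell_id,cell_type,x,y,phenotype,time`, one row per cell per timestep,
#' phenotype empty for non-macrophages. Numbers are serialised with 17
#' significant digits so coordinates round-trip exactly; the writer is
#' deterministic byte-for-byte. `write_cell_table()` optionally writes a
#' JSON sidecar `<path>.json` holding the simulation parameters (and regime
#' name, if given).
#'
#' @param series A `cell_time_series`.
#' @param path Output CSV path.
#' @param sidecar Write the JSON metadata sidecar?
#' @param regime Optional regime name stored in the sidecar.
#' @return `write_cell_table()`: the path, invisibly. `read_cell_table()`:
#'   a `cell_time_series`.
#' @export
write_cell_table <- function(series, path, sidecar = FALSE, regime = NULL) {
  rows <- do.call(rbind, series$snapshots)
  lines <- c("cell_id,cell_type,x,y,phenotype,time",
             paste(rows$cell_id, rows$cell_type, num17(rows$x), num17(rows$y),
                   num17(rows$phenotype), rows$time, sep = ","))
  writeLines(lines, path)
  if (sidecar) {
    meta <- list(params = unclass(series$params))
    if (!is.null(regime)) meta$regime <- regime
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_cell_table
#' @param params Optional `simulation_params` to attach; when `NULL`, a
#'   minimal parameter list is inferred from the table (horizon, snapshot
#'   interval, vessel count; domain size defaults to 50).
#' @export
read_cell_table <- function(path, params = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- read.csv(path, colClasses = "character", stringsAsFactors = FALSE)
  needed <- c("cell_id", "cell_type", "x", "y", "phenotype", "time")
  miss <- setdiff(needed, names(df))
  if (length(miss)) {
    stop(sprintf("missing column(s): %s", paste(miss, collapse = ", ")))
  }
  if (nrow(df) == 0) stop("no records")
  num_or_stop <- function(col) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & nzchar(df[[col]]))
    if (length(bad)) {
      stop(sprintf("non-numeric '%s' value in row %d", col, bad[1]))
    }
    v
  }
  x <- num_or_stop("x"); y <- num_or_stop("y")
  phen <- num_or_stop("phenotype")
  time <- num_or_stop("time")
  id <- num_or_stop("cell_id")
  if (anyNA(x) || anyNA(y) || anyNA(time) || anyNA(id)) {
    stop(sprintf("empty coordinate, id or time in row %d",
                 which(is.na(x) | is.na(y) | is.na(time) | is.na(id))[1]))
  }
  ok_type <- df$cell_type %in% c("tumour", "macrophage", "vessel")
  if (!all(ok_type)) {
    stop(sprintf("unknown cell_type '%s' in row %d",
                 df$cell_type[!ok_type][1], which(!ok_type)[1]))
  }
  dup <- duplicated(paste(id, time))
  if (any(dup)) {
    stop(sprintf("duplicate (cell_id, time) in row %d", which(dup)[1]))
  }
  bad_ph <- which(!is.na(phen) & df$cell_type != "macrophage")
  if (length(bad_ph)) {
    stop(sprintf("phenotype given for %s cell in row %d",
                 df$cell_type[bad_ph[1]], bad_ph[1]))
  }
  miss_ph <- which(is.na(phen) & df$cell_type == "macrophage")
  if (length(miss_ph)) {
    stop(sprintf("macrophage without phenotype in row %d", miss_ph[1]))
  }
  type_per_id <- tapply(df$cell_type, id, function(v) length(unique(v)))
  if (any(type_per_id > 1)) {
    stop(sprintf("cell_id %s changes cell_type over time",
                 names(type_per_id)[type_per_id > 1][1]))
  }
  times <- sort(unique(time))
  snaps <- lapply(times, function(t) {
    ix <- which(time == t)
    ix <- ix[order(id[ix])]
    out <- data.frame(cell_id = as.integer(id[ix]), cell_type = df$cell_type[ix],
                      x = x[ix], y = y[ix], phenotype = phen[ix],
                      time = as.integer(t), stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
  })
  names(snaps) <- as.character(as.integer(times))
  if (is.null(params)) {
    params <- list(
      domain_size = 50,
      horizon = as.integer(max(times)),
      snapshot_interval = as.integer(if (length(times) > 1) min(diff(times)) else max(times)),
      n_vessels = sum(df$cell_type[time == times[1]] == "vessel"),
      seed = NA_integer_
    )
  }
  new_cell_time_series(snaps, params)
}

#' Write / read persistence diagrams as JSON
#'
#' The format is an object per homology dimension,
#' `{"dimension": d, "pairs": [[birth, death, multiplicity], ...]}` with
#' infinite deaths serialised as the literal string `"inf"`; a diagram
#' spanning several dimensions is written as an array of such objects. The
#' filtration kind and (for radial diagrams) the basepoint radius are kept
#' alongside so that a read diagram can be vectorised directly. Identical
#' records are aggregated by multiplicity; round trips preserve the
#' diagram as a multiset.
#'
#' @param diagram A `persistence_diagram`.
#' @param path JSON path.
#' @return `write_diagram()`: the path, invisibly; `read_diagram()`: a
#'   `persistence_diagram`.
#' @export
write_diagram <- function(diagram, path) {
  stopifnot(inherits(diagram, "persistence_diagram"))
  # numbers are emitted at 17 significant digits so values round-trip exactly
  blocks <- vapply(sort(unique(diagram$pairs$dimension)), function(d) {
    p <- diagram$pairs[diagram$pairs$dimension == d, , drop = FALSE]
    key <- paste(num17(p$birth), num17(p$death))
    agg <- table(key)
    first <- p[match(names(agg), key), , drop = FALSE]
    ord <- order(first$birth, first$death)
    pairs <- vapply(ord, function(i) {
      dth <- if (is.finite(first$death[i])) num17(first$death[i]) else "\"inf\""
      sprintf("[%s,%s,%d]", num17(first$birth[i]), dth, as.integer(agg[i]))
    }, character(1))
    sprintf("{\"dimension\":%d,\"pairs\":[%s]}", d,
            paste(pairs, collapse = ","))
  }, character(1))
  rad <- if (is.finite(diagram$radius)) num17(diagram$radius) else "null"
  writeLines(sprintf("{\"kind\":\"%s\",\"radius\":%s,\"diagrams\":[%s]}",
                     diagram$kind, rad, paste(blocks, collapse = ",")),
             path)
  invisible(path)
}

#' @rdname write_diagram
#' @export
read_diagram <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  body <- jsonlite::read_json(path)
  if (is.null(body$diagrams)) stop("not a diagram file: missing 'diagrams'")
  birth <- numeric(0); death <- numeric(0); dimension <- integer(0)
  for (blk in body$diagrams) {
    d <- blk$dimension
    for (k in seq_along(blk$pairs)) {
      pr <- blk$pairs[[k]]
      if (length(pr) != 3 || !is.numeric(pr[[1]])) {
        stop(sprintf("malformed pair %d in dimension-%s block", k, format(d)))
      }
      dth <- if (identical(pr[[2]], "inf")) Inf else {
        if (!is.numeric(pr[[2]])) {
          stop(sprintf("malformed death in pair %d of dimension-%s block",
                       k, format(d)))
        }
        pr[[2]]
      }
      m <- pr[[3]]
      birth <- c(birth, rep(pr[[1]], m))
      death <- c(death, rep(dth, m))
      dimension <- c(dimension, rep(as.integer(d), m))
    }
  }
  new_persistence_diagram(birth, death, dimension,
                          kind = if (is.null(body$kind)) "vr" else body$kind,
                          radius = if (is.null(body$radius)) NA_real_ else body$radius)
}

#' Write / read persistence images as JSON
#'
#' Serialises the grid (row-nested), the axis metadata and, for the radial
#' variant, the appended infinite-feature profile. Numbers keep full
#' precision so values round-trip exactly.
#'
#' @param image A `persistence_image`.
#' @param path JSON path.
#' @return `write_image()`: the path, invisibly; `read_image()`: a
#'   `persistence_image`.
#' @export
write_image <- function(image, path) {
  stopifnot(inherits(image, "persistence_image"))
  arr <- function(v) paste0("[", paste(num17(v), collapse = ","), "]")
  rows <- apply(image$grid, 1, arr)
  fields <- c(
    sprintf("\"birth_range\":%s", arr(image$spec$birth_range)),
    sprintf("\"pers_range\":%s", arr(image$spec$pers_range)),
    sprintf("\"resolution\":[%d,%d]", image$spec$resolution[1],
            image$spec$resolution[2]),
    sprintf("\"sigma\":%s", num17(image$spec$sigma)),
    sprintf("\"weight\":\"%s\"", image$spec$weight),
    sprintf("\"grid\":[%s]", paste(rows, collapse = ","))
  )
  if (!is.null(image$infinite_profile)) {
    fields <- c(fields, sprintf("\"infinite_profile\":%s",
                                arr(image$infinite_profile)))
  }
  writeLines(paste0("{", paste(fields, collapse = ","), "}"), path)
  invisible(path)
}

#' @rdname write_image
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  body <- jsonlite::fromJSON(path)
  spec <- pi_spec(body$birth_range, body$pers_range, body$resolution,
                  body$sigma, body$weight)
  grid <- body$grid
  if (is.null(dim(grid))) grid <- matrix(grid, nrow = 1)
  storage.mode(grid) <- "double"
  if (nrow(grid) != spec$resolution[2] || ncol(grid) != spec$resolution[1]) {
    stop(sprintf("grid is %dx%d but resolution metadata says %dx%d",
                 nrow(grid), ncol(grid), spec$resolution[2], spec$resolution[1]))
  }
  profile <- body$infinite_profile
  if (!is.null(profile)) profile <- as.numeric(profile)
  new_persistence_image(grid, spec, infinite_profile = profile)
}
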