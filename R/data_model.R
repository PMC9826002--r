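#' Construct a cluster dataset
#'
#' A cluster dataset holds the raw observational unit of a multi-dose
#' coverage survey: one row per survey cluster with its planar coordinates,
#' the number of children sampled \code{n}, the numbers vaccinated with at
#' least one, at least two and all three doses (\code{y1 >= y2 >= y3}), and
#' any covariates used for prediction. Counts may be fractional, which
#' arises naturally for simulated data built from exact expected counts and
#' for ratio-based pseudo counts.
#'
#' @param df data frame with columns \code{cluster_id, x, y, n, y1, y2, y3}
#'   followed by covariate columns.
#' @param covariate_names character vector naming the covariate columns;
#'   defaults to every column not among the reserved ones.
#' @param integer_counts if \code{TRUE}, require \code{n, y1, y2, y3} to be
#'   whole numbers.
#' @return an object of class \code{cluster_dataset} (a validated data
#'   frame with a \code{covariate_names} attribute).
#' @export
cluster_dataset <- function(df, covariate_names = NULL, integer_counts = FALSE) {
  req <- c("cluster_id", "x", "y", "n", "y1", "y2", "y3")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0L) {
    stop("cluster table is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (is.null(covariate_names)) {
    covariate_names <- setdiff(names(df), req)
  }
  missing_cov <- setdiff(covariate_names, names(df))
  if (length(missing_cov) > 0L) {
    stop("cluster table is missing covariate column(s): ",
         paste(missing_cov, collapse = ", "))
  }
  df <- as.data.frame(df)[, c(req, covariate_names), drop = FALSE]
  df$cluster_id <- as.character(df$cluster_id)
  if (anyDuplicated(df$cluster_id)) {
    stop("cluster_id values are not unique")
  }
  if (!all(is.finite(df$x)) || !all(is.finite(df$y))) {
    stop("cluster coordinates must be finite")
  }
  for (cv in covariate_names) {
    if (!is.numeric(df[[cv]]) || anyNA(df[[cv]])) {
      stop("covariate '", cv, "' must be numeric with no missing values")
    }
  }
  bad <- which(!(df$n >= df$y1 & df$y1 >= df$y2 & df$y2 >= df$y3 & df$y3 >= 0))
  if (length(bad) > 0L) {
    stop("monotone count invariant n >= y1 >= y2 >= y3 >= 0 violated for cluster(s): ",
         paste(df$cluster_id[bad], collapse = ", "))
  }
  if (integer_counts) {
    cnt <- as.matrix(df[, c("n", "y1", "y2", "y3")])
    if (any(abs(cnt - round(cnt)) > 1e-9)) {
      stop("integer_counts = TRUE but fractional counts present")
    }
  }
  structure(df, covariate_names = covariate_names, class = c("cluster_dataset", "data.frame"))
}

#' Names of the covariate columns of a dataset
#' @param x a \code{cluster_dataset} or \code{indicator_dataset}
#' @return character vector
#' @export
covariate_names <- function(x) attr(x, "covariate_names")

#' Read a cluster table from delimited text
#'
#' Expects a UTF-8 header row with columns
#' \code{cluster_id,x,y,n,y1,y2,y3,<covariates...>} and validates the
#' monotone count invariant on read.
#'
#' @param path file path
#' @param covariate_names covariate columns to retain; default all extra
#'   columns.
#' @param sep field separator (default comma)
#' @inheritParams cluster_dataset
#' @return a \code{cluster_dataset}
#' @export
read_cluster_table <- function(path, covariate_names = NULL, sep = ",",
                               integer_counts = FALSE) {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  cluster_dataset(df, covariate_names = covariate_names,
                  integer_counts = integer_counts)
}

#' Write a cluster dataset as delimited text
#' @param ds a \code{cluster_dataset}
#' @param path destination file
#' @param sep field separator
#' @export
write_cluster_table <- function(ds, path, sep = ",") {
  utils::write.table(as.data.frame(ds), path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Drop clusters below a minimum sample size
#'
#' Survey clusters where only one child was sampled carry almost no
#' information about a proportion and are excluded before modelling.
#'
#' @param ds a \code{cluster_dataset}
#' @param min_n minimum number of children sampled (default 2)
#' @return the filtered \code{cluster_dataset}; retained rows are unchanged
#' @export
filter_clusters <- function(ds, min_n = 2) {
  stopifnot(inherits(ds, "cluster_dataset"))
  keep <- ds$n >= min_n
  removed <- sum(!keep)
  if (removed > 0L) {
    message("filter_clusters: removed ", removed, " cluster(s) with n < ", min_n)
  }
  if (!any(keep)) {
    stop("no clusters with n >= ", min_n, ": nothing left to model")
  }
  out <- as.data.frame(ds)[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, covariate_names = covariate_names(ds),
            class = c("cluster_dataset", "data.frame"),
            n_removed = removed)
}

#' Construct a prediction grid
#'
#' @param df data frame with columns \code{cell_id, x, y, population}
#'   followed by covariate columns. Population is a count of children (or a
#'   proxy age group) per cell, used for population-weighted aggregation.
#' @param covariate_names covariate columns; default all extra columns
#' @return an object of class \code{prediction_grid}
#' @export
prediction_grid <- function(df, covariate_names = NULL) {
  req <- c("cell_id", "x", "y", "population")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0L) {
    stop("grid table is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (is.null(covariate_names)) covariate_names <- setdiff(names(df), req)
  df <- as.data.frame(df)[, c(req, covariate_names), drop = FALSE]
  df$cell_id <- as.character(df$cell_id)
  if (anyDuplicated(df$cell_id)) stop("cell_id values are not unique")
  if (any(df$population < 0) || anyNA(df$population)) {
    stop("population must be nonnegative and non-missing")
  }
  for (cv in covariate_names) {
    if (!is.numeric(df[[cv]]) || anyNA(df[[cv]])) {
      stop("covariate '", cv, "' must be numeric with no missing values")
    }
  }
  structure(df, covariate_names = covariate_names,
            class = c("prediction_grid", "data.frame"))
}

#' Read a prediction grid table
#' @param path delimited text file with header
#'   \code{cell_id,x,y,population,<covariates...>}
#' @param sep field separator
#' @inheritParams prediction_grid
#' @export
read_grid_table <- function(path, covariate_names = NULL, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  prediction_grid(df, covariate_names = covariate_names)
}

## ---- admin polygons (GeoJSON) ----

#' Read admin units from a GeoJSON FeatureCollection
#'
#' Each feature must carry \code{unit_id} and \code{level} properties and a
#' Polygon or MultiPolygon geometry in the same planar coordinate system as
#' the grid.
#'
#' @param path GeoJSON file
#' @return list of admin units, each a list with \code{unit_id},
#'   \code{level}, \code{rings} (list of coordinate matrices; outer rings
#'   and holes treated by the even-odd rule) and \code{member_cells}
#'   (filled by \code{\link{assign_cells_to_units}})
#' @export
read_admin_geojson <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(gj$type) || gj$type != "FeatureCollection") {
    stop("admin file is not a GeoJSON FeatureCollection")
  }
  lapply(gj$features, function(ft) {
    props <- ft$properties
    if (is.null(props$unit_id) || is.null(props$level)) {
      stop("every admin feature needs unit_id and level properties")
    }
    geom <- ft$geometry
    rings <- switch(geom$type,
      Polygon = lapply(geom$coordinates, geojson_ring),
      MultiPolygon = unlist(lapply(geom$coordinates, function(poly) {
        lapply(poly, geojson_ring)
      }), recursive = FALSE),
      stop("unsupported geometry type: ", geom$type)
    )
    list(unit_id = as.character(props$unit_id), level = as.character(props$level),
         rings = rings, member_cells = character(0))
  })
}

geojson_ring <- function(coords) {
  m <- do.call(rbind, lapply(coords, function(pt) c(pt[[1]], pt[[2]])))
  storage.mode(m) <- "double"
  m
}

#' Write admin units to GeoJSON
#' @param units list of admin units (as from \code{\link{read_admin_geojson}})
#' @param path destination file
#' @export
write_admin_geojson <- function(units, path) {
  features <- lapply(units, function(u) {
    coords <- lapply(u$rings, function(r) {
      lapply(seq_len(nrow(r)), function(i) c(r[i, 1], r[i, 2]))
    })
    list(type = "Feature",
         properties = list(unit_id = u$unit_id, level = u$level),
         geometry = list(type = "Polygon", coordinates = coords))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Even-odd (ray casting) point-in-polygon test against one ring.
# Points exactly on an edge count as inside (boundary-inclusive on the
# horizontal ray crossings; adequate for centroid assignment).
point_in_ring <- function(px, py, ring) {
  n <- nrow(ring)
  xs <- ring[, 1]; ys <- ring[, 2]
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((ys[i] > py) != (ys[j] > py)) &
      (px < (xs[j] - xs[i]) * (py - ys[i]) / (ys[j] - ys[i]) + xs[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

point_in_unit <- function(px, py, unit) {
  inside <- rep(FALSE, length(px))
  for (ring in unit$rings) {
    inside <- xor(inside, point_in_ring(px, py, ring))
  }
  inside
}

#' Assign grid cells to admin units by centroid
#'
#' Each grid cell is assigned to the unit (per level) whose polygon
#' contains the cell centroid; within a level the first containing unit
#' wins, so assignment is a function. Cells outside all polygons of a level
#' are flagged and excluded from aggregation at that level.
#'
#' @param grid a \code{prediction_grid}
#' @param units list of admin units
#' @return the units, with \code{member_cells} filled; attribute
#'   \code{unassigned} lists cell ids outside all polygons, per level
#' @export
assign_cells_to_units <- function(grid, units) {
  stopifnot(inherits(grid, "prediction_grid"))
  levels <- unique(vapply(units, `[[`, "", "level"))
  unassigned <- list()
  taken <- list()
  for (lv in levels) taken[[lv]] <- rep(FALSE, nrow(grid))
  for (k in seq_along(units)) {
    u <- units[[k]]
    inside <- point_in_unit(grid$x, grid$y, u) & !taken[[u$level]]
    taken[[u$level]] <- taken[[u$level]] | inside
    units[[k]]$member_cells <- grid$cell_id[inside]
    if (!any(inside)) {
      warning("admin unit '", u$unit_id, "' (level ", u$level,
              ") contains no grid cells")
    }
  }
  for (lv in levels) {
    out <- grid$cell_id[!taken[[lv]]]
    if (length(out) > 0L) {
      warning(length(out), " grid cell(s) fall outside all level-", lv,
              " polygons and are excluded from aggregation")
    }
    unassigned[[lv]] <- out
  }
  structure(units, unassigned = unassigned)
}

#' Read grid and admin inputs together
#'
#' @param grid_path delimited-text grid table
#' @param admin_path GeoJSON FeatureCollection of admin polygons
#' @param covariate_names optional covariate columns for the grid
#' @return list with \code{grid} (a \code{prediction_grid}) and
#'   \code{units} (admin units with \code{member_cells} filled)
#' @export
read_grid_and_admin <- function(grid_path, admin_path, covariate_names = NULL) {
  grid <- read_grid_table(grid_path, covariate_names = covariate_names)
  units <- read_admin_geojson(admin_path)
  # crude CRS sanity check: polygon bounding boxes must overlap the grid
  bb <- range(c(sapply(units, function(u) range(sapply(u$rings, function(r) r[, 1])))))
  if (max(grid$x) < bb[1] || min(grid$x) > bb[2]) {
    stop("grid and admin coordinates do not overlap; check coordinate systems")
  }
  units <- assign_cells_to_units(grid, units)
  list(grid = grid, units = units)
}

## ---- output writing ----

#' Write surface and admin summaries to an output directory
#'
#' Grid summaries are written as delimited text (one row per cell, one
#' column per statistic); admin summaries likewise, keyed by unit id. A
#' manifest listing every file with an md5 checksum is returned and
#' written alongside.
#'
#' @param surfaces named list of data frames with a \code{cell_id} column
#' @param summaries named list of data frames with a \code{unit_id} column
#' @param out_dir output directory (created if needed)
#' @return data frame manifest (file, md5)
#' @export
write_outputs <- function(surfaces = list(), summaries = list(), out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  }
  files <- character(0)
  for (nm in names(surfaces)) {
    f <- file.path(out_dir, paste0("surface_", nm, ".csv"))
    utils::write.table(surfaces[[nm]], f, sep = ",", row.names = FALSE, quote = FALSE)
    files <- c(files, f)
  }
  for (nm in names(summaries)) {
    f <- file.path(out_dir, paste0("admin_", nm, ".csv"))
    utils::write.table(summaries[[nm]], f, sep = ",", row.names = FALSE, quote = FALSE)
    files <- c(files, f)
  }
  manifest <- data.frame(file = basename(files),
                         md5 = if (length(files)) unname(tools::md5sum(files)) else character(0),
                         stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(out_dir, "MANIFEST.txt"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  manifest
}
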