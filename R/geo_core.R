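# Earth radius (km) used for all spherical area computations.
.R_EARTH_KM <- 6371

#' Define a regular geographic grid
#'
#' A `grid_spec` describes a regular longitude/latitude grid in WGS84
#' geographic coordinates, registered by cell edges. Row 1 is the
#' northernmost row; cells are half-open `[edge, edge + resolution)` in
#' longitude and, mirrored from the top, in latitude, so a point exactly on
#' an interior cell boundary belongs to the higher-index cell.
#'
#' @param lon_min,lon_max,lat_min,lat_max Extent in decimal degrees.
#' @param resolution Cell size in degrees. Default `5/60` (5 arc-minutes,
#'   roughly 9.2 km at the equator).
#' @return An object of class `grid_spec` with fields `lon_min`, `lon_max`,
#'   `lat_min`, `lat_max`, `resolution`, `n_rows`, `n_cols`.
#' @examples
#' g <- grid_spec(90, 140, -11, 15)
#' c(g$n_rows, g$n_cols)
#' @export
grid_spec <- function(lon_min, lon_max, lat_min, lat_max, resolution = 5 / 60) {
  stopifnot(lon_max > lon_min, lat_max > lat_min, resolution > 0)
  nc <- (lon_max - lon_min) / resolution
  nr <- (lat_max - lat_min) / resolution
  if (abs(nc - round(nc)) > 1e-9 || abs(nr - round(nr)) > 1e-9) {
    stop("grid extent is not an integer multiple of the resolution")
  }
  structure(
    list(
      lon_min = lon_min, lon_max = lon_max,
      lat_min = lat_min, lat_max = lat_max,
      resolution = resolution,
      n_rows = as.integer(round(nr)), n_cols = as.integer(round(nc))
    ),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf(
    "grid_spec: %g..%g E, %g..%g N, res %.6g deg (%d rows x %d cols)\n",
    x$lon_min, x$lon_max, x$lat_min, x$lat_max, x$resolution,
    x$n_rows, x$n_cols
  ))
  invisible(x)
}

grids_equal <- function(a, b) {
  isTRUE(all.equal(unclass(a)[1:5], unclass(b)[1:5], tolerance = 1e-12)) &&
    a$n_rows == b$n_rows && a$n_cols == b$n_cols
}

#' Area of one grid cell
#'
#' Spherical-cap area of every cell in row `row`:
#' \eqn{A = R^2 \Delta\lambda (\sin\varphi_t - \sin\varphi_b)} with
#' \eqn{R = 6371} km and the cell-edge latitudes \eqn{\varphi_t, \varphi_b}.
#' All cells in one row share the same area.
#'
#' @param grid A [grid_spec()].
#' @param row Row index (1 = northernmost row).
#' @return Cell area in km^2.
#' @examples
#' g <- grid_spec(0, 1, -0.5, 0.5, 5 / 60)
#' cell_area(g, 6) # cell row touching the equator, ~85.9 km^2
#' @export
cell_area <- function(grid, row) {
  stopifnot(inherits(grid, "grid_spec"))
  if (any(row < 1L | row > grid$n_rows)) {
    stop("row index out of range [1, ", grid$n_rows, "]")
  }
  res_rad <- grid$resolution * pi / 180
  phi_top <- (grid$lat_max - (row - 1) * grid$resolution) * pi / 180
  phi_bot <- phi_top - grid$resolution * pi / 180
  .R_EARTH_KM^2 * res_rad * (sin(phi_top) - sin(phi_bot))
}

#' Per-row cell areas for a whole grid
#'
#' @param grid A [grid_spec()].
#' @return Numeric vector of length `n_rows`, cell area in km^2 per row.
#' @export
cell_areas_by_row <- function(grid) {
  cell_area(grid, seq_len(grid$n_rows))
}

#' Matrix of cell areas (rows x cols), km^2
#' @param grid A [grid_spec()].
#' @return `n_rows` x `n_cols` matrix.
#' @export
cell_area_matrix <- function(grid) {
  matrix(cell_areas_by_row(grid), nrow = grid$n_rows, ncol = grid$n_cols)
}

#' Locate the grid cell containing a point
#'
#' Cell-edge registration with half-open cells: a point exactly on an
#' interior boundary is assigned to the higher-index (east / south) cell.
#' Points with `lon == lon_max` or `lat == lat_min` fall outside the
#' half-open extent.
#'
#' @param grid A [grid_spec()].
#' @param lon,lat Point coordinates in degrees (vectorised).
#' @return A data.frame with integer columns `row`, `col`.
#' @export
point_to_cell <- function(grid, lon, lat) {
  stopifnot(inherits(grid, "grid_spec"), length(lon) == length(lat))
  bad <- lon < grid$lon_min | lon >= grid$lon_max |
    lat <= grid$lat_min | lat > grid$lat_max
  if (any(bad)) {
    stop(sprintf(
      "%d point(s) outside the half-open grid extent (first: lon=%g lat=%g)",
      sum(bad), lon[which(bad)[1]], lat[which(bad)[1]]
    ))
  }
  col <- as.integer(floor((lon - grid$lon_min) / grid$resolution)) + 1L
  row <- as.integer(floor((grid$lat_max - lat) / grid$resolution)) + 1L
  # guard FP round-off for points microscopically below a boundary
  col <- pmin(col, grid$n_cols)
  row <- pmin(row, grid$n_rows)
  data.frame(row = row, col = col)
}

#' Coordinates of cell centers
#'
#' @param grid A [grid_spec()].
#' @param row,col Cell indices (vectorised).
#' @return data.frame with columns `lon`, `lat`.
#' @export
cell_center <- function(grid, row, col) {
  stopifnot(inherits(grid, "grid_spec"))
  data.frame(
    lon = grid$lon_min + (col - 0.5) * grid$resolution,
    lat = grid$lat_max - (row - 0.5) * grid$resolution
  )
}

#' Construct a raster layer on a grid
#'
#' A `layer` couples a [grid_spec()] with a matrix of per-cell values and a
#' logical mask (`TRUE` = valid sea cell). Values on masked-out cells are
#' stored as `NA`.
#'
#' @param grid A [grid_spec()].
#' @param values Numeric matrix `n_rows x n_cols`.
#' @param mask Logical matrix of the same shape; default: non-NA values.
#' @param name Layer name.
#' @param units Unit string (free text).
#' @return An object of class `layer`.
#' @export
layer <- function(grid, values, mask = NULL, name = "layer", units = "") {
  stopifnot(inherits(grid, "grid_spec"), is.matrix(values))
  if (nrow(values) != grid$n_rows || ncol(values) != grid$n_cols) {
    stop("values shape does not match grid (", grid$n_rows, "x", grid$n_cols, ")")
  }
  if (is.null(mask)) mask <- !is.na(values)
  stopifnot(is.matrix(mask), identical(dim(mask), dim(values)))
  values[!mask] <- NA_real_
  if (any(is.na(values[mask]))) stop("NA values on mask-true cells in layer '", name, "'")
  structure(
    list(grid = grid, values = values, mask = mask, name = name, units = units),
    class = "layer"
  )
}

#' @export
print.layer <- function(x, ...) {
  cat(sprintf(
    "layer '%s'%s: %d x %d, %d valid cells, range [%.4g, %.4g]\n",
    x$name, if (nzchar(x$units)) paste0(" [", x$units, "]") else "",
    x$grid$n_rows, x$grid$n_cols, sum(x$mask),
    suppressWarnings(min(x$values, na.rm = TRUE)),
    suppressWarnings(max(x$values, na.rm = TRUE))
  ))
  invisible(x)
}

#' Bundle layers sharing one grid and mask into a predictor stack
#'
#' @param layers Named or unnamed list of [layer()] objects; names default to
#'   the layers' own names. Layer names must be unique; all layers must share
#'   an identical grid and mask.
#' @param scenario_tag Free-text scenario label, e.g. `"current"` or
#'   `"2100s_RCP8.5"`.
#' @return An object of class `predictor_stack`.
#' @export
predictor_stack <- function(layers, scenario_tag = "current") {
  stopifnot(is.list(layers), length(layers) >= 1)
  nms <- vapply(layers, function(l) l$name, character(1))
  if (anyDuplicated(nms)) stop("duplicate layer names: ", paste(nms[duplicated(nms)], collapse = ", "))
  names(layers) <- nms
  g <- layers[[1]]$grid
  m <- layers[[1]]$mask
  for (l in layers[-1]) {
    if (!grids_equal(l$grid, g)) stop("layer '", l$name, "' is on a different grid")
    if (!identical(l$mask, m)) stop("layer '", l$name, "' has a different mask")
  }
  structure(
    list(layers = layers, grid = g, mask = m, scenario_tag = scenario_tag),
    class = "predictor_stack"
  )
}

#' @export
print.predictor_stack <- function(x, ...) {
  cat(sprintf(
    "predictor_stack [%s]: %d layers on %d x %d grid (%d sea cells)\n  %s\n",
    x$scenario_tag, length(x$layers), x$grid$n_rows, x$grid$n_cols,
    sum(x$mask), paste(names(x$layers), collapse = ", ")
  ))
  invisible(x)
}

#' Read / write a single-band raster as an ESRI ASCII grid
#'
#' Plain-text georeferenced raster interchange: header rows `ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value` followed by the value
#' matrix north row first. Values are written with full `%.17g` precision so
#' a write/read round trip reproduces valid-cell values bit-exactly.
#'
#' @param path File path (conventionally `.asc`).
#' @param name,units Metadata for the returned layer; `name` defaults to the
#'   file name without extension.
#' @return `read_ascii_raster`: a [layer()]. `write_ascii_raster`: `path`,
#'   invisibly.
#' @export
read_ascii_raster <- function(path, name = NULL, units = "") {
  con <- file(path, "r")
  on.exit(close(con))
  hdr <- character(6)
  for (i in 1:6) hdr[i] <- readLines(con, n = 1)
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  keys <- tolower(kv[, 1])
  vals <- as.numeric(kv[, 2])
  names(vals) <- keys
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize", "nodata_value")
  if (!all(need %in% keys)) stop("malformed ASCII grid header in ", path)
  nc <- as.integer(vals[["ncols"]]); nr <- as.integer(vals[["nrows"]])
  res <- vals[["cellsize"]]; nodata <- vals[["nodata_value"]]
  vv <- scan(con, what = double(), quiet = TRUE)
  if (length(vv) != nr * nc) stop("ASCII grid body has wrong length in ", path)
  m <- matrix(vv, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  g <- grid_spec(
    lon_min = vals[["xllcorner"]], lon_max = vals[["xllcorner"]] + nc * res,
    lat_min = vals[["yllcorner"]], lat_max = vals[["yllcorner"]] + nr * res,
    resolution = res
  )
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  layer(g, m, name = name, units = units)
}

#' @param lyr A [layer()] to write.
#' @param nodata Nodata sentinel written for masked cells.
#' @rdname read_ascii_raster
#' @export
write_ascii_raster <- function(lyr, path, nodata = -9999) {
  stopifnot(inherits(lyr, "layer"))
  g <- lyr$grid
  if (any(abs(lyr$values - nodata) < 1e-12, na.rm = TRUE)) {
    stop("layer contains the nodata sentinel ", nodata, " as a data value")
  }
  hdr <- c(
    sprintf("ncols %d", g$n_cols),
    sprintf("nrows %d", g$n_rows),
    sprintf("xllcorner %.12f", g$lon_min),
    sprintf("yllcorner %.12f", g$lat_min),
    sprintf("cellsize %.12f", g$resolution),
    sprintf("NODATA_value %g", nodata)
  )
  v <- lyr$values
  v[!lyr$mask] <- nodata
  body <- apply(v, 1, function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write / read a predictor stack as a directory of ASCII grids
#'
#' One `.asc` file per layer plus a `stack.yml` manifest recording layer
#' order, names, units and the scenario tag.
#'
#' @param stack A [predictor_stack()].
#' @param dir Directory path.
#' @return `read_stack`: a [predictor_stack()]. `write_stack`: `dir`,
#'   invisibly.
#' @export
write_stack <- function(stack, dir) {
  stopifnot(inherits(stack, "predictor_stack"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    scenario_tag = stack$scenario_tag,
    layers = lapply(stack$layers, function(l) {
      list(name = l$name, units = l$units, file = paste0(l$name, ".asc"))
    })
  )
  for (l in stack$layers) write_ascii_raster(l, file.path(dir, paste0(l$name, ".asc")))
  yaml::write_yaml(manifest, file.path(dir, "stack.yml"))
  invisible(dir)
}

#' @rdname write_stack
#' @export
read_stack <- function(dir) {
  manifest <- yaml::read_yaml(file.path(dir, "stack.yml"))
  layers <- lapply(manifest$layers, function(m) {
    f <- file.path(dir, m$file)
    if (!file.exists(f)) stop("missing raster for layer '", m$name, "': ", f)
    read_ascii_raster(f, name = m$name, units = m$units)
  })
  predictor_stack(layers, scenario_tag = manifest$scenario_tag)
}
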