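# Plain lon/lat vector geometry: GeoJSON I/O, point-in-polygon, and the
# population boundary polyline. Polygons are data.frames of (lon, lat)
# vertices (closed implicitly); a polygon set is a list of them.

#' Test points against a polygon (even-odd ray casting)
#'
#' Boundary handling follows the half-open convention of the crossing test;
#' use it only where boundary-exact points are not meaningful.
#'
#' @param lon,lat Point coordinates (vectorised).
#' @param poly data.frame with columns `lon`, `lat` (vertices in order; the
#'   closing edge is implicit).
#' @return Logical vector.
#' @export
point_in_polygon <- function(lon, lat, poly) {
  stopifnot(all(c("lon", "lat") %in% names(poly)), nrow(poly) >= 3)
  px <- poly$lon
  py <- poly$lat
  n <- length(px)
  jx <- c(px[n], px[-n])
  jy <- c(py[n], py[-n])
  inside <- rep(FALSE, length(lon))
  for (k in seq_len(n)) {
    xi <- px[k]; yi <- py[k]; xj <- jx[k]; yj <- jy[k]
    crosses <- ((yi > lat) != (yj > lat)) &
      (lon < (xj - xi) * (lat - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
  }
  inside
}

#' Test points against a set of polygons
#'
#' @param polys List of polygons (see [point_in_polygon()]).
#' @inheritParams point_in_polygon
#' @return Logical vector: `TRUE` where a point is inside at least one
#'   polygon.
#' @export
point_in_any_polygon <- function(lon, lat, polys) {
  inside <- rep(FALSE, length(lon))
  for (p in polys) inside <- inside | point_in_polygon(lon, lat, p)
  inside
}

#' Create a north-south population boundary polyline
#'
#' The boundary separating the two populations is a polyline ordered from
#' south to north that spans the full latitude range of the study window;
#' everything west of it (smaller longitude at equal latitude) is one
#' population's side. The default traces the Makassar Strait / Indonesian
#' Throughflow corridor used to split an Eastern Indian Ocean-South China
#' Sea (EIOS) population from a Western Pacific-Indonesia (WPI) population.
#'
#' @param vertices data.frame with columns `lon`, `lat`, strictly increasing
#'   in `lat`.
#' @return Object of class `boundary_line`.
#' @export
boundary_line <- function(vertices = data.frame(
                            lon = c(118.5, 117.5, 116.5),
                            lat = c(-11, 0, 15)
                          )) {
  stopifnot(all(c("lon", "lat") %in% names(vertices)), nrow(vertices) >= 2)
  if (any(diff(vertices$lat) <= 0)) stop("boundary vertices must increase strictly in latitude")
  structure(list(vertices = vertices), class = "boundary_line")
}

#' Longitude of a boundary at given latitudes
#'
#' Linear interpolation along the polyline; latitudes beyond the vertex
#' range use the nearest segment's endpoint longitude.
#'
#' @param boundary A [boundary_line()].
#' @param lat Latitudes (vectorised).
#' @return Numeric vector of longitudes.
#' @export
boundary_lon_at <- function(boundary, lat) {
  stopifnot(inherits(boundary, "boundary_line"))
  v <- boundary$vertices
  stats::approx(v$lat, v$lon, xout = lat, rule = 2)$y
}

#' Which side of the boundary is a point on?
#'
#' @inheritParams boundary_lon_at
#' @param lon Longitudes (vectorised, same length as `lat`).
#' @return Character vector, `"west"` or `"east"`; points exactly on the
#'   boundary count as `"west"` by convention.
#' @export
boundary_side <- function(boundary, lon, lat) {
  b <- boundary_lon_at(boundary, lat)
  ifelse(lon <= b, "west", "east")
}

#' Read and write polygons as GeoJSON
#'
#' Supports FeatureCollections of Polygon / MultiPolygon features (outer
#' rings only; holes are not used by this pipeline) and, for boundaries,
#' a single LineString feature.
#'
#' @param path File path.
#' @return `read_geojson_polygons`: list of polygons (data.frames of
#'   `lon`,`lat`), with feature `id`s as names when present.
#' @export
read_geojson_polygons <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  feats <- if (identical(gj$type, "FeatureCollection")) gj$features else list(gj)
  out <- list()
  for (f in feats) {
    geom <- if (identical(f$type, "Feature")) f$geometry else f
    id <- if (!is.null(f$properties$id)) as.character(f$properties$id) else NULL
    rings <- switch(geom$type,
      Polygon = list(geom$coordinates[[1]]),
      MultiPolygon = lapply(geom$coordinates, function(p) p[[1]]),
      stop("unsupported geometry type: ", geom$type)
    )
    for (r in rings) {
      xy <- do.call(rbind, lapply(r, function(pt) c(pt[[1]], pt[[2]])))
      poly <- data.frame(lon = xy[, 1], lat = xy[, 2])
      # drop the explicit closing vertex if present
      n <- nrow(poly)
      if (n > 3 && poly$lon[1] == poly$lon[n] && poly$lat[1] == poly$lat[n]) {
        poly <- poly[-n, ]
      }
      out[[length(out) + 1L]] <- poly
      if (!is.null(id)) names(out)[length(out)] <- id
    }
  }
  out
}

#' @param polys List of polygons (data.frames of `lon`, `lat`).
#' @rdname read_geojson_polygons
#' @export
write_geojson_polygons <- function(polys, path) {
  feats <- lapply(seq_along(polys), function(i) {
    p <- polys[[i]]
    ring <- lapply(seq_len(nrow(p)), function(k) c(p$lon[k], p$lat[k]))
    ring[[length(ring) + 1L]] <- ring[[1]]
    id <- if (!is.null(names(polys)) && nzchar(names(polys)[i])) names(polys)[i] else paste0("poly_", i)
    list(
      type = "Feature",
      properties = list(id = id),
      geometry = list(type = "Polygon", coordinates = list(ring))
    )
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = feats),
    path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname read_geojson_polygons
#' @param boundary A [boundary_line()] (for `write_geojson_boundary`).
#' @export
write_geojson_boundary <- function(boundary, path) {
  stopifnot(inherits(boundary, "boundary_line"))
  v <- boundary$vertices
  coords <- lapply(seq_len(nrow(v)), function(k) c(v$lon[k], v$lat[k]))
  jsonlite::write_json(
    list(
      type = "Feature",
      properties = list(id = "population_boundary"),
      geometry = list(type = "LineString", coordinates = coords)
    ),
    path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname read_geojson_polygons
#' @export
read_geojson_boundary <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  geom <- if (identical(gj$type, "Feature")) gj$geometry else gj
  if (!identical(geom$type, "LineString")) stop("boundary file must contain a LineString")
  xy <- do.call(rbind, lapply(geom$coordinates, function(pt) c(pt[[1]], pt[[2]])))
  v <- data.frame(lon = xy[, 1], lat = xy[, 2])
  if (v$lat[1] > v$lat[nrow(v)]) v <- v[rev(seq_len(nrow(v))), ]
  rownames(v) <- NULL
  boundary_line(v)
}
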