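# Marine-protected-area gap analysis: rasterise MPA polygons onto the
# working grid, compute cell-area-weighted protection statistics of the
# suitable range, and classify the loss class into priority conservation
# areas (PCAs, unprotected) and conservation areas pending optimisation
# (POCAs, inside existing MPAs).

#' Rasterise MPA polygons onto a grid
#'
#' A cell is protected iff its center lies inside at least one polygon
#' (cell-center rule, no partial-coverage weighting). Degenerate polygons
#' (fewer than 3 vertices) raise an error naming the polygon.
#'
#' @param mpas List of polygons (data.frames with `lon`, `lat`), e.g. from
#'   [simulate_mpas()] or [read_geojson_polygons()].
#' @param grid A [grid_spec()].
#' @return Logical matrix `n_rows x n_cols` (`TRUE` = protected).
#' @export
rasterize_mpas <- function(mpas, grid) {
  stopifnot(inherits(grid, "grid_spec"))
  out <- matrix(FALSE, grid$n_rows, grid$n_cols)
  if (length(mpas) == 0) return(out)
  ctr_lon <- grid$lon_min + (seq_len(grid$n_cols) - 0.5) * grid$resolution
  ctr_lat <- grid$lat_max - (seq_len(grid$n_rows) - 0.5) * grid$resolution
  lon <- as.numeric(matrix(ctr_lon, grid$n_rows, grid$n_cols, byrow = TRUE))
  lat <- as.numeric(matrix(ctr_lat, grid$n_rows, grid$n_cols))
  for (i in seq_along(mpas)) {
    p <- mpas[[i]]
    if (nrow(p) < 3) {
      id <- if (!is.null(names(mpas)) && nzchar(names(mpas)[i])) names(mpas)[i] else i
      stop("invalid polygon '", id, "': fewer than 3 vertices")
    }
    out <- out | matrix(point_in_polygon(lon, lat, p), grid$n_rows, grid$n_cols)
  }
  out
}

#' Protection statistics of a binary suitability map
#'
#' `predicted_area` is the cell-area-weighted area (km^2) of suitable
#' cells; `protected_area` the area of suitable cells inside MPAs;
#' `percent_protected = 100 * protected / predicted`.
#'
#' @param binary A binary suitability [layer()].
#' @param mpa_mask Logical matrix from [rasterize_mpas()].
#' @param scenario Label recorded in the output row.
#' @return One-row data.frame: `scenario`, `predicted_area_km2`,
#'   `protected_area_km2`, `percent_protected`.
#' @export
protection_stats <- function(binary, mpa_mask, scenario = "current") {
  stopifnot(inherits(binary, "layer"), is.matrix(mpa_mask))
  if (!identical(dim(mpa_mask), dim(binary$values))) stop("MPA mask shape does not match grid")
  areas <- cell_area_matrix(binary$grid)
  suit <- binary$mask & !is.na(binary$values) & binary$values == 1
  predicted <- sum(areas[suit])
  if (predicted == 0) stop("zero predicted suitable area: percent protected undefined")
  protected <- sum(areas[suit & mpa_mask])
  data.frame(
    scenario = scenario,
    predicted_area_km2 = predicted,
    protected_area_km2 = protected,
    percent_protected = 100 * protected / predicted,
    stringsAsFactors = FALSE
  )
}

#' Percent protected from printed area figures
#'
#' The ratio form of [protection_stats()] for externally supplied area
#' totals: `100 * protected / predicted`.
#'
#' @param predicted_km2,protected_km2 Areas in km^2 (`protected <=
#'   predicted`).
#' @return Percentage.
#' @export
percent_protected <- function(predicted_km2, protected_km2) {
  stopifnot(predicted_km2 > 0, protected_km2 >= 0, protected_km2 <= predicted_km2)
  100 * protected_km2 / predicted_km2
}

#' Classify the projected loss class for conservation planning
#'
#' Cells suitable now but unsuitable in the future are split by protection
#' status: outside existing MPAs they are Priority Conservation Areas
#' (PCAs, candidates for new protection); inside MPAs they are
#' Conservation Areas Pending Optimisation (POCAs, where protection should
#' be adapted). The two masks are disjoint and together equal the loss
#' class of [change_map()].
#'
#' @param current_bin,future_bin Binary [layer()]s on one grid/mask.
#' @param mpa_mask Logical matrix from [rasterize_mpas()].
#' @return List with logical matrices `pca` and `poca`.
#' @export
classify_conservation <- function(current_bin, future_bin, mpa_mask) {
  stopifnot(inherits(current_bin, "layer"), inherits(future_bin, "layer"))
  if (!grids_equal(current_bin$grid, future_bin$grid)) stop("grids differ")
  if (!identical(current_bin$mask, future_bin$mask)) stop("masks differ")
  if (!identical(dim(mpa_mask), dim(current_bin$values))) stop("MPA mask shape does not match grid")
  m <- current_bin$mask
  loss <- m & current_bin$values == 1 & future_bin$values == 0
  loss[is.na(loss)] <- FALSE
  list(pca = loss & !mpa_mask, poca = loss & mpa_mask)
}
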