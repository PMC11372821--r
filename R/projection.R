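# Projection of fitted ensembles onto predictor stacks, maxTSS
# binarisation, change maps between current and future binary maps, and
# cell-area-weighted range-change percentages.

#' Project an ensemble onto a predictor stack
#'
#' Per-cell ensemble suitability over all valid (sea) cells; masked cells
#' stay masked. The stack must provide every variable the ensemble was
#' trained on.
#'
#' @param ensemble A [build_ensemble()] result.
#' @param stack A [predictor_stack()].
#' @return A [layer()] named `"suitability"` with values in `[0, 1]` and
#'   attribute `scenario_tag`.
#' @export
predict_map <- function(ensemble, stack) {
  stopifnot(inherits(ensemble, "sdm_ensemble"), inherits(stack, "predictor_stack"))
  need <- ensemble$members[[1]]$vars
  miss <- setdiff(need, names(stack$layers))
  if (length(miss)) stop("stack is missing layer(s): ", paste(miss, collapse = ", "))
  env <- stack_env_matrix(stack)
  p <- predict_ensemble(ensemble, env)
  vals <- matrix(NA_real_, stack$grid$n_rows, stack$grid$n_cols)
  vals[stack$mask] <- p
  out <- layer(stack$grid, vals, mask = stack$mask, name = "suitability", units = "")
  attr(out, "scenario_tag") <- stack$scenario_tag
  out
}

#' The maxTSS binarisation threshold of an ensemble
#'
#' Threshold that maximises TSS of the ensemble's full-table predictions
#' against the observed 0/1 response; reused unchanged for all future
#' scenarios of the same model.
#'
#' @param ensemble A [build_ensemble()] result.
#' @param env Full training predictor matrix.
#' @param response Full 0/1 response.
#' @return Scalar threshold in `[0, 1]`.
#' @export
ensemble_threshold <- function(ensemble, env, response) {
  evaluate_predictions(predict_ensemble(ensemble, env), response)$threshold
}

#' Binarise a continuous suitability map
#'
#' Cells with suitability `>= tau` become 1 ("prediction existence"), the
#' rest 0. `tau` is clamped into `[0, 1]`.
#'
#' @param map A suitability [layer()].
#' @param tau Threshold.
#' @return A [layer()] with values in `{0, 1}` and attribute `threshold`.
#' @export
binarize <- function(map, tau) {
  stopifnot(inherits(map, "layer"))
  tau <- min(max(tau, 0), 1)
  vals <- ifelse(map$values >= tau, 1, 0)
  vals[!map$mask] <- NA_real_
  out <- layer(map$grid, vals, mask = map$mask, name = paste0(map$name, "_binary"))
  attr(out, "threshold") <- tau
  attr(out, "scenario_tag") <- attr(map, "scenario_tag")
  out
}

.CHANGE_LEVELS <- c(loss = 1, stable = 2, gain = 3, unsuitable = 0)

#' Change map between current and future binary suitability
#'
#' Per-cell category from the (current, future) pair: (1,0) loss, (1,1)
#' stable, (0,1) gain, (0,0) unsuitable.
#'
#' @param current,future Binary [layer()]s on the same grid and mask.
#' @return A [layer()] with integer codes (`unsuitable` 0, `loss` 1,
#'   `stable` 2, `gain` 3) and attribute `legend`.
#' @export
change_map <- function(current, future) {
  stopifnot(inherits(current, "layer"), inherits(future, "layer"))
  if (!grids_equal(current$grid, future$grid)) stop("binary maps are on different grids")
  if (!identical(current$mask, future$mask)) stop("binary maps have different masks")
  cur <- current$values
  fut <- future$values
  vals <- matrix(NA_real_, nrow(cur), ncol(cur))
  m <- current$mask
  vals[m] <- ifelse(cur[m] == 1 & fut[m] == 0, .CHANGE_LEVELS[["loss"]],
    ifelse(cur[m] == 1 & fut[m] == 1, .CHANGE_LEVELS[["stable"]],
      ifelse(cur[m] == 0 & fut[m] == 1, .CHANGE_LEVELS[["gain"]],
        .CHANGE_LEVELS[["unsuitable"]]
      )
    )
  )
  out <- layer(current$grid, vals, mask = m, name = "change")
  attr(out, "legend") <- .CHANGE_LEVELS
  out
}

#' Cell-area-weighted area of a set of cells, km^2
#'
#' @param lyr A [layer()].
#' @param predicate Function mapping cell values to logical (default:
#'   value == 1).
#' @return Total area in km^2 of valid cells where the predicate holds.
#' @export
layer_area_km2 <- function(lyr, predicate = function(v) v == 1) {
  areas <- cell_area_matrix(lyr$grid)
  sel <- lyr$mask & !is.na(lyr$values) & predicate(lyr$values)
  sum(areas[sel])
}

#' Areas of the four change categories, km^2
#'
#' @param chg A [change_map()] result.
#' @return Named numeric vector with `loss`, `stable`, `gain`,
#'   `unsuitable` areas in km^2.
#' @export
change_areas <- function(chg) {
  vapply(names(.CHANGE_LEVELS), function(nm) {
    layer_area_km2(chg, predicate = function(v) v == .CHANGE_LEVELS[[nm]])
  }, numeric(1))
}

#' Percentage range change
#'
#' `range_change_pct` is the scalar form,
#' `100 * (A_future - A_current) / A_current` (negative = contraction),
#' for externally supplied area totals; `range_change` computes it between
#' two binary maps with cell-area-weighted areas in km^2.
#'
#' @param a_current,a_future Areas in km^2 (`a_current > 0`).
#' @return Scalar percentage.
#' @export
range_change_pct <- function(a_current, a_future) {
  if (a_current <= 0) stop("current suitable area must be positive: range change undefined")
  100 * (a_future - a_current) / a_current
}

#' @param current,future Binary [layer()]s on the same grid.
#' @rdname range_change_pct
#' @export
range_change <- function(current, future) {
  range_change_pct(layer_area_km2(current), layer_area_km2(future))
}

#' Restrict a layer to one side of the population boundary
#'
#' Used to report population-level projections within the population's own
#' region: cells on the other side of the boundary are masked out.
#'
#' @param lyr A [layer()].
#' @param boundary A [boundary_line()].
#' @param side `"west"` (EIOS) or `"east"` (WPI).
#' @return A [layer()] with the reduced mask.
#' @export
restrict_to_side <- function(lyr, boundary, side = c("west", "east")) {
  side <- match.arg(side)
  g <- lyr$grid
  ctr_lon <- g$lon_min + (seq_len(g$n_cols) - 0.5) * g$resolution
  ctr_lat <- g$lat_max - (seq_len(g$n_rows) - 0.5) * g$resolution
  lon_m <- matrix(ctr_lon, g$n_rows, g$n_cols, byrow = TRUE)
  lat_m <- matrix(ctr_lat, g$n_rows, g$n_cols)
  on_side <- matrix(
    boundary_side(boundary, as.numeric(lon_m), as.numeric(lat_m)) == side,
    g$n_rows, g$n_cols
  )
  new_mask <- lyr$mask & on_side
  vals <- lyr$values
  vals[!new_mask] <- NA_real_
  layer(g, vals, mask = new_mask, name = lyr$name, units = lyr$units)
}
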