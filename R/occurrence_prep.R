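# Occurrence data preparation: cleaning, one-record-per-grid-cell thinning,
# population assignment against the boundary line, and balanced
# pseudo-absence generation outside the presence environmental envelope.

.occ_cols <- c("id", "lon", "lat", "population", "response")

as_occurrence_table <- function(df) {
  if (!"id" %in% names(df)) df$id <- sprintf("occ_%05d", seq_len(nrow(df)))
  if (!"population" %in% names(df)) df$population <- "unassigned"
  if (!"response" %in% names(df)) df$response <- 1L
  stopifnot(all(c("lon", "lat") %in% names(df)))
  df[, .occ_cols]
}

#' Clean raw occurrence records
#'
#' Removes records with missing coordinates, collapses exact duplicate
#' coordinates (first record kept, order stable), and drops records outside
#' the grid extent or on masked (land) cells.
#'
#' @param raw Occurrence data.frame with at least `lon`, `lat`; optional
#'   `id`, `population`, `response`.
#' @param stack A [predictor_stack()] providing the grid and the sea mask.
#' @return Cleaned occurrence data.frame.
#' @export
clean_records <- function(raw, stack) {
  stopifnot(inherits(stack, "predictor_stack"))
  occ <- as_occurrence_table(raw)
  occ <- occ[!is.na(occ$lon) & !is.na(occ$lat), , drop = FALSE]
  dup <- duplicated(occ[, c("lon", "lat")])
  occ <- occ[!dup, , drop = FALSE]
  g <- stack$grid
  inext <- occ$lon >= g$lon_min & occ$lon < g$lon_max &
    occ$lat > g$lat_min & occ$lat <= g$lat_max
  occ <- occ[inext, , drop = FALSE]
  if (nrow(occ) > 0) {
    rc <- point_to_cell(g, occ$lon, occ$lat)
    on_sea <- stack$mask[cbind(rc$row, rc$col)]
    occ <- occ[on_sea, , drop = FALSE]
  }
  if (nrow(occ) == 0) stop("no occurrence records survive cleaning")
  rownames(occ) <- NULL
  occ
}

#' Thin occurrences to one record per grid cell
#'
#' Each grid cell keeps at most one presence; the retained record is the
#' first in input order. Presences and absences are thinned separately so
#' that the (cell, response) pairs are unique. Idempotent.
#'
#' @param occ Cleaned occurrence data.frame.
#' @param grid A [grid_spec()].
#' @return Thinned occurrence data.frame.
#' @export
thin_to_grid <- function(occ, grid) {
  stopifnot(inherits(grid, "grid_spec"))
  if (nrow(occ) == 0) return(occ)
  rc <- point_to_cell(grid, occ$lon, occ$lat)
  key <- paste(rc$row, rc$col, occ$response, sep = ":")
  out <- occ[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign records to a population by side of the boundary
#'
#' Records west of (or exactly on) the boundary line are labelled `EIOS`,
#' records east of it `WPI`. On-boundary assignment to the west side is a
#' fixed convention and is reported via a message.
#'
#' @param occ Occurrence data.frame.
#' @param boundary A [boundary_line()].
#' @return The table with `population` filled in for every record.
#' @export
assign_population <- function(occ, boundary) {
  stopifnot(inherits(boundary, "boundary_line"))
  b <- boundary_lon_at(boundary, occ$lat)
  on_line <- occ$lon == b
  if (any(on_line)) {
    message(sum(on_line), " record(s) exactly on the boundary assigned to EIOS (west) by convention")
  }
  occ$population <- ifelse(occ$lon <= b, "EIOS", "WPI")
  occ
}

#' Generate balanced pseudo-absences
#'
#' Draws exactly as many pseudo-absence records as there are presences,
#' uniformly at random without replacement from sea cells that (a) contain
#' no presence and (b) fall outside the presences' environmental envelope
#' (at least one predictor outside the presences' observed \[min, max\]).
#' If the envelope rule leaves fewer eligible cells than needed it is
#' relaxed to presence-free cells only, with a warning. Absences are placed
#' at cell centers; deterministic given `seed`.
#'
#' @param presences Occurrence data.frame of presences (`response == 1`).
#' @param stack A [predictor_stack()].
#' @param seed Integer RNG seed.
#' @param strategy `"envelope"` (default) or `"cells_only"` (skip rule (b)).
#' @return Occurrence data.frame of pseudo-absences (`response == 0`).
#' @export
generate_pseudo_absences <- function(presences, stack, seed = 1L,
                                     strategy = c("envelope", "cells_only")) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(stack, "predictor_stack"))
  presences <- presences[presences$response == 1L, , drop = FALSE]
  n <- nrow(presences)
  if (n < 1) stop("at least one presence is required")
  g <- stack$grid
  rc <- point_to_cell(g, presences$lon, presences$lat)
  pres_cells <- unique((rc$col - 1L) * g$n_rows + rc$row)
  sea_cells <- which(stack$mask)
  cand <- setdiff(sea_cells, pres_cells)
  if (length(cand) == 0) stop("no presence-free sea cells available for pseudo-absences")
  env_all <- stack_env_matrix(stack)
  sea_index <- match(cand, sea_cells)
  if (strategy == "envelope") {
    env_pres <- extract_env(presences, stack)
    lo <- apply(env_pres, 2, min)
    hi <- apply(env_pres, 2, max)
    envc <- env_all[sea_index, , drop = FALSE]
    outside <- rowSums(
      sweep(envc, 2, lo, "<") | sweep(envc, 2, hi, ">")
    ) > 0
    eligible <- cand[outside]
    if (length(eligible) < n) {
      warning(
        "only ", length(eligible), " cells outside the presence envelope for ",
        n, " pseudo-absences; relaxing to presence-free cells"
      )
      eligible <- cand
    }
  } else {
    eligible <- cand
  }
  if (length(eligible) < n) {
    stop(
      "only ", length(eligible),
      " eligible cells for ", n, " pseudo-absences"
    )
  }
  set.seed(seed)
  chosen <- eligible[sample.int(length(eligible), n)]
  row <- ((chosen - 1) %% g$n_rows) + 1
  col <- ((chosen - 1) %/% g$n_rows) + 1
  ctr <- cell_center(g, row, col)
  data.frame(
    id = sprintf("abs_%05d", seq_len(n)),
    lon = ctr$lon, lat = ctr$lat,
    population = "unassigned",
    response = 0L,
    stringsAsFactors = FALSE
  )
}

#' Build the balanced presence / pseudo-absence response table
#'
#' Convenience wrapper: clean, thin, optionally assign populations, and
#' append an equal number of pseudo-absences.
#'
#' @inheritParams generate_pseudo_absences
#' @param raw Raw occurrence data.frame.
#' @param boundary Optional [boundary_line()] for population labels.
#' @param thin Apply grid-cell thinning (default `TRUE`).
#' @return Occurrence data.frame with balanced 0/1 `response`.
#' @export
prepare_response_table <- function(raw, stack, boundary = NULL, seed = 1L,
                                   strategy = "envelope", thin = TRUE) {
  occ <- clean_records(raw, stack)
  if (thin) occ <- thin_to_grid(occ, stack$grid)
  if (!is.null(boundary)) occ <- assign_population(occ, boundary)
  abs <- generate_pseudo_absences(occ, stack, seed = seed, strategy = strategy)
  out <- rbind(occ, abs)
  rownames(out) <- NULL
  out
}
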