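# Synthetic study system: nine autocorrelated environmental layers over a
# tropical Indo-Pacific window, two populations with different temperature /
# salinity optima, climate-scenario perturbations of the dynamic layers, and
# rectangular marine protected areas. Everything is deterministic given a
# seed, so the full analysis is testable without any data download.

#' The nine environmental predictor layers
#'
#' Canonical layer names, units, plausible value ranges used by the
#' generator, and whether a layer is dynamic (has future-scenario variants)
#' or static (assumed unchanged in the future).
#'
#' @return data.frame with columns `name`, `units`, `lo`, `hi`, `dynamic`.
#' @export
predictor_table <- function() {
  data.frame(
    name = c(
      "current_velocity", "salinity", "temperature_mean", "temperature_range",
      "depth", "distance_to_shore", "dissolved_oxygen", "light_at_bottom",
      "phytoplankton"
    ),
    units = c(
      "m s-1", "PSS", "degC", "degC", "m", "km", "mol m-3", "", "umol m-3"
    ),
    lo = c(0.05, 31, 20, 1, NA, 0, 0.18, 0, 0.5),
    hi = c(1.5, 36, 31, 8, NA, 300, 0.26, 60, 8),
    dynamic = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' Names of the dynamic layers
#' @return Character vector of the four layers with future-scenario variants.
#' @export
dynamic_layers <- function() {
  pt <- predictor_table()
  pt$name[pt$dynamic]
}

#' The default study window
#'
#' 90-140 degrees E, 11 degrees S to 15 degrees N at 5 arc-minute
#' resolution (600 x 312 cells).
#' @return A [grid_spec()].
#' @export
default_grid <- function() grid_spec(90, 140, -11, 15, 5 / 60)

# Smooth a white-noise matrix with a separable Gaussian kernel of standard
# deviation `sigma` cells (edge-replicated padding), then restandardise.
.gaussian_field <- function(n_rows, n_cols, sigma) {
  z <- matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols)
  if (sigma <= 0) return(z)
  half <- ceiling(3 * sigma)
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  smooth_cols <- function(m) {
    pad_top <- m[rep(1, half), , drop = FALSE]
    pad_bot <- m[rep(nrow(m), half), , drop = FALSE]
    mp <- rbind(pad_top, m, pad_bot)
    f <- stats::filter(mp, k, sides = 2)
    f[(half + 1):(half + nrow(m)), , drop = FALSE]
  }
  z <- smooth_cols(z)
  z <- t(smooth_cols(t(z)))
  z <- matrix(as.numeric(z), n_rows, n_cols)
  (z - mean(z)) / stats::sd(z)
}

#' Simulate a stack of nine autocorrelated predictor layers
#'
#' Each layer is spatially correlated Gaussian noise (white noise smoothed
#' with a Gaussian kernel of scale `autocorr_cells` cells) affinely mapped
#' into a plausible range for that variable (see [predictor_table()]). The
#' land/sea mask is derived from the synthetic `depth` layer: cells with
#' depth > 0 are sea. Output is deterministic given `seed`.
#'
#' @param grid A [grid_spec()]; default [default_grid()].
#' @param seed Integer RNG seed.
#' @param autocorr_cells Gaussian smoothing scale in cells (0 = white
#'   noise). Default 6 (about 55 km at 5 arc-minutes), a mesoscale
#'   correlation length.
#' @return A [predictor_stack()] with `scenario_tag = "current"`.
#' @export
simulate_predictors <- function(grid = default_grid(), seed = 1L,
                                autocorr_cells = 6) {
  stopifnot(inherits(grid, "grid_spec"), autocorr_cells >= 0)
  pt <- predictor_table()
  set.seed(seed)
  # depth first: it defines the mask (sea where depth > 0, in metres)
  zd <- .gaussian_field(grid$n_rows, grid$n_cols, autocorr_cells)
  depth_vals <- 1000 + 1000 * zd
  mask <- depth_vals > 0
  if (!any(mask)) stop("synthetic depth field produced no sea cells")
  layers <- vector("list", nrow(pt))
  for (i in seq_len(nrow(pt))) {
    nm <- pt$name[i]
    if (nm == "depth") {
      vals <- depth_vals
    } else {
      z <- .gaussian_field(grid$n_rows, grid$n_cols, autocorr_cells)
      mid <- (pt$lo[i] + pt$hi[i]) / 2
      vals <- mid + (pt$hi[i] - pt$lo[i]) / 6 * z
      if (pt$name[i] %in% c("distance_to_shore", "phytoplankton", "light_at_bottom")) {
        vals <- pmax(vals, 0)
      }
    }
    vals[!mask] <- NA_real_
    layers[[i]] <- layer(grid, vals, mask = mask, name = nm, units = pt$units[i])
  }
  predictor_stack(layers, scenario_tag = "current")
}

#' Define a climate-scenario perturbation of the dynamic layers
#'
#' A scenario delta is an additive offset and an optional multiplicative
#' factor per layer, applied as `value * factor + offset`. Only the four
#' dynamic layers (current velocity, salinity, temperature mean,
#' temperature range) may be touched; naming a static layer is a contract
#' violation.
#'
#' @param offset Named numeric vector of additive offsets (layer units).
#' @param factor Named numeric vector of multiplicative factors.
#' @return Object of class `scenario_delta`.
#' @export
scenario_delta <- function(offset = numeric(), factor = numeric()) {
  touched <- union(names(offset), names(factor))
  bad <- setdiff(touched, dynamic_layers())
  if (length(bad)) {
    stop(
      "scenario delta touches static layer(s): ", paste(bad, collapse = ", "),
      " (only ", paste(dynamic_layers(), collapse = ", "), " may change)"
    )
  }
  structure(list(offset = offset, factor = factor), class = "scenario_delta")
}

#' Built-in scenario presets
#'
#' Four presets crossing period (2050s, 2100s) with an optimistic (RCP 2.6)
#' and pessimistic (RCP 8.5) emission pathway. Sea-surface temperature
#' offsets grow monotonically from 2050s RCP 2.6 (+0.6 degC) to 2100s
#' RCP 8.5 (+3.0 degC); salinity freshens slightly and the seasonal
#' temperature range widens with warming.
#'
#' @param period `"2050s"` or `"2100s"`.
#' @param rcp `"RCP2.6"` or `"RCP8.5"`.
#' @return A [scenario_delta()].
#' @export
scenario_preset <- function(period = c("2050s", "2100s"),
                            rcp = c("RCP2.6", "RCP8.5")) {
  period <- match.arg(period)
  rcp <- match.arg(rcp)
  key <- paste(period, rcp)
  temp <- c("2050s RCP2.6" = 0.6, "2100s RCP2.6" = 0.9,
            "2050s RCP8.5" = 1.4, "2100s RCP8.5" = 3.0)[[key]]
  sal <- c("2050s RCP2.6" = -0.05, "2100s RCP2.6" = -0.08,
           "2050s RCP8.5" = -0.15, "2100s RCP8.5" = -0.30)[[key]]
  tr_fac <- c("2050s RCP2.6" = 1.03, "2100s RCP2.6" = 1.05,
              "2050s RCP8.5" = 1.08, "2100s RCP8.5" = 1.15)[[key]]
  cv_fac <- c("2050s RCP2.6" = 0.99, "2100s RCP2.6" = 0.98,
              "2050s RCP8.5" = 0.97, "2100s RCP8.5" = 0.95)[[key]]
  scenario_delta(
    offset = c(temperature_mean = temp, salinity = sal),
    factor = c(temperature_range = tr_fac, current_velocity = cv_fac)
  )
}

#' Apply a scenario delta to a predictor stack
#'
#' Dynamic layers are transformed as `value * factor + offset`; static
#' layers are bit-identical to the input. The result carries `tag` as its
#' scenario tag.
#'
#' @param stack A [predictor_stack()].
#' @param delta A [scenario_delta()].
#' @param tag Scenario tag for the output stack.
#' @return A [predictor_stack()].
#' @export
apply_scenario <- function(stack, delta, tag) {
  stopifnot(inherits(stack, "predictor_stack"), inherits(delta, "scenario_delta"))
  layers <- lapply(stack$layers, function(l) {
    fac <- if (l$name %in% names(delta$factor)) delta$factor[[l$name]] else 1
    off <- if (l$name %in% names(delta$offset)) delta$offset[[l$name]] else 0
    if (fac == 1 && off == 0) return(l)
    v <- l$values * fac + off
    layer(l$grid, v, mask = l$mask, name = l$name, units = l$units)
  })
  predictor_stack(layers, scenario_tag = tag)
}

#' Gaussian niche response function
#'
#' A smooth, unimodal suitability surface: the product of independent
#' Gaussian terms `exp(-((x - optimum) / tolerance)^2 / 2)` over the named
#' variables, scaled by `max_suitability`. Variables not named are ignored
#' (flat response). The maximum is attained exactly at the optimum vector.
#'
#' @param optima Named numeric vector of per-variable optima (layer units).
#' @param tolerances Named numeric vector of per-variable tolerances
#'   (Gaussian standard deviations), same names as `optima`.
#' @param max_suitability Peak suitability in (0, 1].
#' @return Object of class `niche_function`.
#' @export
niche_function <- function(optima, tolerances, max_suitability = 1) {
  stopifnot(
    length(optima) == length(tolerances),
    setequal(names(optima), names(tolerances)),
    all(tolerances > 0),
    max_suitability > 0, max_suitability <= 1
  )
  tolerances <- tolerances[names(optima)]
  structure(
    list(optima = optima, tolerances = tolerances, max_suitability = max_suitability),
    class = "niche_function"
  )
}

#' Evaluate a niche function on rows of environmental values
#'
#' @param niche A [niche_function()].
#' @param env data.frame or matrix with columns named after the niche's
#'   variables (extra columns ignored).
#' @return Numeric vector of suitabilities in `[0, 1]`.
#' @export
niche_suitability <- function(niche, env) {
  stopifnot(inherits(niche, "niche_function"))
  miss <- setdiff(names(niche$optima), colnames(env))
  if (length(miss)) stop("env is missing niche variable(s): ", paste(miss, collapse = ", "))
  s <- rep(niche$max_suitability, nrow(env))
  for (v in names(niche$optima)) {
    s <- s * exp(-0.5 * ((env[, v] - niche$optima[[v]]) / niche$tolerances[[v]])^2)
  }
  as.numeric(s)
}

#' True suitability of every sea cell under a niche function
#'
#' @param stack A [predictor_stack()].
#' @param niche A [niche_function()].
#' @return A [layer()] named `"suitability"` with values in `[0, 1]`.
#' @export
niche_suitability_map <- function(stack, niche) {
  env <- stack_env_matrix(stack)
  s <- niche_suitability(niche, env)
  vals <- matrix(NA_real_, stack$grid$n_rows, stack$grid$n_cols)
  vals[stack$mask] <- s
  layer(stack$grid, vals, mask = stack$mask, name = "suitability", units = "")
}

# All sea-cell values of a stack as a matrix (cells x layers), in mask order
# (column-major over the grid). Used internally by sampling and projection.
stack_env_matrix <- function(stack) {
  env <- vapply(
    stack$layers, function(l) l$values[stack$mask],
    numeric(sum(stack$mask))
  )
  colnames(env) <- names(stack$layers)
  env
}

#' Default niche functions for the two synthetic populations
#'
#' The populations differ in their temperature and salinity optima, the two
#' variables that drive the niche divergence this pipeline is designed to
#' detect; the `separation` argument is the Euclidean distance between the
#' optima in tolerance-standardised niche space, split equally between the
#' two variables. The temperature optima sit at or below the centre of the
#' simulated temperature field — the species is already at its thermal
#' optimum under current conditions — so any scenario warming pushes cells
#' past the optimum and shrinks suitable habitat, the regime the projected
#' range losses emulate.
#'
#' @param separation Distance between the population optima in
#'   tolerance-standardised units (Euclidean over temperature and
#'   salinity). Default 2.
#' @return Named list with elements `EIOS` and `WPI`, each a
#'   [niche_function()].
#' @export
default_population_niches <- function(separation = 2) {
  tol <- c(temperature_mean = 1.5, salinity = 1.0)
  center <- c(temperature_mean = 24.5, salinity = 33.3)
  half <- separation / (2 * sqrt(2)) # per-variable half-shift, tolerance units
  list(
    EIOS = niche_function(center - half * tol, tol),
    WPI = niche_function(center + half * tol, tol)
  )
}

#' Sample presence records proportional to niche suitability
#'
#' Sea cells are drawn with probability proportional to the niche
#' suitability of their environmental values; each draw is placed at the
#' cell center and labelled with the population side of `boundary`
#' (west = EIOS, east = WPI). By default cells are drawn with replacement
#' (repeat observations of well-suited cells, later collapsed by grid
#' thinning); with `distinct = TRUE` each cell is used at most once and
#' requesting more records than there are eligible sea cells is an
#' explicit error. Deterministic given `seed`.
#'
#' @param stack A [predictor_stack()].
#' @param niche A [niche_function()].
#' @param n Number of presence points to draw.
#' @param seed Integer RNG seed.
#' @param boundary A [boundary_line()], or `NULL` to leave the population
#'   label `"unassigned"`.
#' @param distinct Draw each cell at most once (default `FALSE`).
#' @return Occurrence data.frame with columns `id`, `lon`, `lat`,
#'   `population`, `response` (all 1).
#' @export
sample_occurrences <- function(stack, niche, n, seed = 1L, boundary = NULL,
                               distinct = FALSE) {
  stopifnot(inherits(stack, "predictor_stack"), n > 0)
  env <- stack_env_matrix(stack)
  suit <- niche_suitability(niche, env)
  eligible <- sum(suit > 0)
  if (eligible == 0) stop("no sea cell has positive suitability")
  if (distinct && n > eligible) {
    stop(
      "n = ", n, " exceeds the ", eligible,
      " sea cells with positive suitability (one record per cell after thinning)"
    )
  }
  idx_mask <- which(stack$mask)                # column-major cell ids
  set.seed(seed)
  draw <- sample.int(length(idx_mask), size = n, replace = !distinct, prob = suit)
  cells <- idx_mask[draw]
  row <- ((cells - 1) %% stack$grid$n_rows) + 1
  col <- ((cells - 1) %/% stack$grid$n_rows) + 1
  ctr <- cell_center(stack$grid, row, col)
  pop <- if (is.null(boundary)) {
    rep("unassigned", n)
  } else {
    ifelse(boundary_side(boundary, ctr$lon, ctr$lat) == "west", "EIOS", "WPI")
  }
  data.frame(
    id = sprintf("occ_%05d", seq_len(n)),
    lon = ctr$lon, lat = ctr$lat,
    population = pop,
    response = 1L,
    stringsAsFactors = FALSE
  )
}

#' Simulate rectangular marine protected areas
#'
#' Places `n_polygons` axis-aligned rectangles centred on randomly chosen
#' sea cells and iteratively rescales their common side length until the
#' realised sea-area coverage (fraction of sea-cell centers inside at least
#' one rectangle) is within 10% relative of `coverage_target`; if after the
#' rescaling passes the coverage is still off by more than 20% relative a
#' warning is emitted and the best effort returned. Deterministic given
#' `seed`.
#'
#' @param stack A [predictor_stack()] providing grid and sea mask.
#' @param coverage_target Target fraction of sea area protected, in (0, 1).
#' @param n_polygons Number of rectangles (0 gives an empty set).
#' @param seed Integer RNG seed.
#' @return Named list of rectangle polygons (data.frames of `lon`, `lat`),
#'   with attribute `realized_coverage`.
#' @export
simulate_mpas <- function(stack, coverage_target = 0.16, n_polygons = 25, seed = 1L) {
  stopifnot(inherits(stack, "predictor_stack"))
  if (n_polygons == 0) {
    out <- list()
    attr(out, "realized_coverage") <- 0
    return(out)
  }
  stopifnot(coverage_target > 0, coverage_target < 1)
  g <- stack$grid
  sea <- which(stack$mask)
  n_sea <- length(sea)
  set.seed(seed)
  centers <- sea[sample.int(n_sea, min(n_polygons, n_sea))]
  crow <- ((centers - 1) %% g$n_rows) + 1
  ccol <- ((centers - 1) %/% g$n_rows) + 1
  ctr <- cell_center(g, crow, ccol)
  sea_ctr <- cell_center(
    g,
    ((sea - 1) %% g$n_rows) + 1,
    ((sea - 1) %/% g$n_rows) + 1
  )
  # nominal square side assuming ~80% of a rectangle lands on sea; each
  # polygon gets its own size jitter so the realised coverage responds
  # smoothly to the global scale factor tuned below
  side0 <- sqrt(coverage_target * n_sea / length(centers) / 0.8) * g$resolution
  jit_w <- stats::runif(length(centers), 0.7, 1.3)
  jit_h <- stats::runif(length(centers), 0.7, 1.3)
  build <- function(scale) {
    lapply(seq_along(centers), function(i) {
      hw <- scale * side0 * jit_w[i] / 2
      hh <- scale * side0 * jit_h[i] / 2
      data.frame(
        lon = pmin(pmax(c(ctr$lon[i] - hw, ctr$lon[i] + hw, ctr$lon[i] + hw, ctr$lon[i] - hw), g$lon_min), g$lon_max),
        lat = pmin(pmax(c(ctr$lat[i] - hh, ctr$lat[i] - hh, ctr$lat[i] + hh, ctr$lat[i] + hh), g$lat_min), g$lat_max)
      )
    })
  }
  coverage_of <- function(polys) {
    inside <- rep(FALSE, n_sea)
    for (p in polys) {
      inside <- inside |
        (sea_ctr$lon >= min(p$lon) & sea_ctr$lon <= max(p$lon) &
           sea_ctr$lat >= min(p$lat) & sea_ctr$lat <= max(p$lat))
    }
    mean(inside)
  }
  # realised coverage is monotone in the scale factor: bisect on it
  lo <- 0.05
  hi <- 8
  s <- 1
  polys <- build(s)
  realized <- coverage_of(polys)
  for (i in 1:30) {
    if (abs(realized - coverage_target) / coverage_target <= 0.05) break
    if (realized < coverage_target) lo <- s else hi <- s
    s <- (lo + hi) / 2
    polys <- build(s)
    realized <- coverage_of(polys)
  }
  if (realized == 0 || abs(realized - coverage_target) / coverage_target > 0.2) {
    warning(sprintf(
      "simulate_mpas: realized coverage %.3f misses target %.3f by > 20%%; returning best effort",
      realized, coverage_target
    ))
  }
  names(polys) <- sprintf("mpa_%03d", seq_along(polys))
  attr(polys, "realized_coverage") <- realized
  polys
}
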