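# Orchestration: one configuration drives synthetic-data generation (or
# file input), occurrence prep, predictor screening, the niche hypervolume
# comparison, ensemble fitting per level, scenario projection, and the MPA
# gap analysis, with a run log, a manifest, and per-stage derived seeds.

# Derived per-stage seed: reproducible even if stages are re-ordered,
# always a valid 32-bit integer.
stage_seed <- function(base_seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(base_seed) * 131 + h) %% 2147483647)
}

#' Default pipeline configuration
#'
#' All stage parameters in one list; every value can be overridden. With
#' no input paths the pipeline simulates its own predictors, occurrences,
#' boundary and MPAs (demo mode).
#'
#' @param seed Base seed; per-stage seeds are derived from it.
#' @param out_dir Output directory for the run.
#' @param ... Overrides of top-level config entries.
#' @return Named list of class `run_config`.
#' @export
default_config <- function(seed = 1L, out_dir = tempfile("nichecast_run_"), ...) {
  cfg <- list(
    seed = as.integer(seed),
    out_dir = out_dir,
    grid = list(lon_min = 90, lon_max = 140, lat_min = -11, lat_max = 15,
                resolution = 5 / 60),
    autocorr_cells = 6,
    n_presences = 1000,
    niche_separation = 2,
    levels = c("species", "EIOS", "WPI"),
    algorithms = .ALGORITHMS,
    cv = list(folds = 5, replicates = 10),
    gates = list(tss_min = 0.7, auc_min = 0.8),
    weighting = "equal",
    pseudo_absence_strategy = "envelope",
    pca_k = 4,
    hypervolume = list(n_stochastic = 20000, quantile = 0.95),
    scenarios = list(
      list(period = "2050s", rcp = "RCP2.6"),
      list(period = "2100s", rcp = "RCP2.6"),
      list(period = "2050s", rcp = "RCP8.5"),
      list(period = "2100s", rcp = "RCP8.5")
    ),
    mpa = list(coverage_target = 0.16, n_polygons = 25),
    inputs = list(stack_dir = NULL, occurrences = NULL, boundary = NULL, mpas = NULL)
  )
  over <- list(...)
  cfg[names(over)] <- over
  class(cfg) <- "run_config"
  cfg
}

# Restrict every layer of a stack (and its mask) to one side of the
# boundary; used to sample each population in its own region.
restrict_stack_to_side <- function(stack, boundary, side) {
  g <- stack$grid
  ctr_lon <- g$lon_min + (seq_len(g$n_cols) - 0.5) * g$resolution
  ctr_lat <- g$lat_max - (seq_len(g$n_rows) - 0.5) * g$resolution
  lon_m <- matrix(ctr_lon, g$n_rows, g$n_cols, byrow = TRUE)
  lat_m <- matrix(ctr_lat, g$n_rows, g$n_cols)
  on_side <- matrix(
    boundary_side(boundary, as.numeric(lon_m), as.numeric(lat_m)) == side,
    g$n_rows, g$n_cols
  )
  layers <- lapply(stack$layers, function(l) {
    v <- l$values
    m <- l$mask & on_side
    v[!m] <- NA_real_
    layer(g, v, mask = m, name = l$name, units = l$units)
  })
  predictor_stack(layers, scenario_tag = stack$scenario_tag)
}

.write_csv <- function(df, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes, in order: predictor simulation (or load), scenario stacks,
#' occurrence sampling/cleaning/thinning/population split, balanced
#' pseudo-absences, collinearity screening, PCA + niche hypervolume
#' comparison, per-level cross-validated ensemble fitting with gating,
#' current and future projection with maxTSS binarisation, change maps and
#' range-change percentages, and the MPA gap analysis with PCA/POCA masks.
#' Each stage logs its decisions to `run.log`; a `manifest.yml` records
#' the configuration and derived seeds. Conservation identities
#' (loss + stable = current area; stable + gain = future area;
#' PCA and POCA partition the loss class) are asserted on every run.
#'
#' @param config A [default_config()] list.
#' @return Invisibly, a list with the run directory and the in-memory
#'   stage results (`occ`, `cv`, `ensembles`, `thresholds`, `niche`,
#'   `binary_maps`, `range_table`, `gap_report`, `importance`, ...).
#' @export
run_pipeline <- function(config = default_config()) {
  cfg <- config
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(cfg$out_dir, "run.log")
  unlink(log_path)
  logln <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path, append = TRUE)
  logln("run started (base seed %d)", cfg$seed)

  grid <- grid_spec(
    cfg$grid$lon_min, cfg$grid$lon_max, cfg$grid$lat_min, cfg$grid$lat_max,
    cfg$grid$resolution
  )

  ## -- predictors -----------------------------------------------------------
  if (!is.null(cfg$inputs$stack_dir)) {
    current <- read_stack(cfg$inputs$stack_dir)
    logln("predictors: loaded from %s", cfg$inputs$stack_dir)
  } else {
    current <- simulate_predictors(grid, seed = stage_seed(cfg$seed, "predictors"),
                                   autocorr_cells = cfg$autocorr_cells)
    logln("predictors: simulated %d layers, %d sea cells",
          length(current$layers), sum(current$mask))
  }
  scen_tag <- function(s) paste0(s$period, "_", s$rcp)
  futures <- list()
  for (s in cfg$scenarios) {
    tag <- scen_tag(s)
    futures[[tag]] <- apply_scenario(current, scenario_preset(s$period, s$rcp), tag)
    logln("scenario %s: dynamic layers perturbed", tag)
  }

  ## -- boundary, niches, occurrences ---------------------------------------
  boundary <- if (!is.null(cfg$inputs$boundary)) {
    read_geojson_boundary(cfg$inputs$boundary)
  } else {
    boundary_line()
  }
  niches <- default_population_niches(cfg$niche_separation)
  if (!is.null(cfg$inputs$occurrences)) {
    raw <- utils::read.csv(cfg$inputs$occurrences, stringsAsFactors = FALSE)
    logln("occurrences: loaded %d raw records", nrow(raw))
  } else {
    west <- restrict_stack_to_side(current, boundary, "west")
    east <- restrict_stack_to_side(current, boundary, "east")
    n_each <- ceiling(cfg$n_presences / 2)
    raw <- rbind(
      sample_occurrences(west, niches$EIOS, n_each,
                         seed = stage_seed(cfg$seed, "occurrences_EIOS"),
                         boundary = boundary),
      sample_occurrences(east, niches$WPI, cfg$n_presences - n_each,
                         seed = stage_seed(cfg$seed, "occurrences_WPI"),
                         boundary = boundary)
    )
    raw$id <- sprintf("occ_%05d", seq_len(nrow(raw)))
    logln("occurrences: sampled %d presences (two populations)", nrow(raw))
  }
  .write_csv(raw, file.path(cfg$out_dir, "occurrences", "presences_raw.csv"))

  occ <- clean_records(raw, current)
  logln("cleaning: %d -> %d records", nrow(raw), nrow(occ))
  occ <- thin_to_grid(occ, grid)
  logln("thinning: %d records after one-per-cell thinning", nrow(occ))
  occ <- assign_population(occ, boundary)
  logln("population split: %d EIOS, %d WPI",
        sum(occ$population == "EIOS"), sum(occ$population == "WPI"))
  .write_csv(occ, file.path(cfg$out_dir, "occurrences", "presences_clean.csv"))

  levels <- cfg$levels
  level_presences <- list(
    species = occ,
    EIOS = occ[occ$population == "EIOS", , drop = FALSE],
    WPI = occ[occ$population == "WPI", , drop = FALSE]
  )[levels]
  tables <- list()
  for (lv in levels) {
    pres <- level_presences[[lv]]
    abs <- generate_pseudo_absences(
      pres, current,
      seed = stage_seed(cfg$seed, paste0("pseudo_absences_", lv)),
      strategy = cfg$pseudo_absence_strategy
    )
    tab <- rbind(pres, abs)
    rownames(tab) <- NULL
    tables[[lv]] <- tab
    logln("%s table: %d presences + %d pseudo-absences", lv, nrow(pres), nrow(abs))
    .write_csv(tab, file.path(cfg$out_dir, "occurrences", paste0("response_", lv, ".csv")))
  }

  ## -- predictor screening --------------------------------------------------
  env_pres <- extract_env(occ, current)
  screen <- collinearity_filter(env_pres)
  logln("collinearity screen: %d of %d variables retained",
        length(screen$retained), ncol(env_pres))
  .write_csv(screen$report, file.path(cfg$out_dir, "screening", "collinearity_report.csv"))
  vars <- screen$retained

  ## -- niche hypervolumes ----------------------------------------------------
  niche_out <- NULL
  if (all(c("EIOS", "WPI") %in% occ$population) &&
      min(table(occ$population)) >= 5) {
    pca <- pca_fit(env_pres[, vars, drop = FALSE], k = min(cfg$pca_k, length(vars)))
    logln("PCA: %d components, %.1f%% of variance",
          pca$k, 100 * sum(pca$variance_explained[seq_len(pca$k)]))
    hv_seed <- stage_seed(cfg$seed, "hypervolumes")
    hv1 <- build_hypervolume(pca$scores[occ$population == "EIOS", , drop = FALSE],
                             n_stochastic = cfg$hypervolume$n_stochastic,
                             quantile = cfg$hypervolume$quantile, seed = hv_seed)
    hv2 <- build_hypervolume(pca$scores[occ$population == "WPI", , drop = FALSE],
                             n_stochastic = cfg$hypervolume$n_stochastic,
                             quantile = cfg$hypervolume$quantile, seed = hv_seed + 1L)
    cmp <- overlap_hypervolumes(hv1, hv2, seed = hv_seed + 2L,
                                n_mc = cfg$hypervolume$n_stochastic)
    logln("niche: V_EIOS %.3f, V_WPI %.3f, beta_total %.3f (shift %.3f, rich %.3f)",
          cmp$V1, cmp$V2, cmp$beta_total, cmp$beta_shift, cmp$beta_rich)
    .write_csv(niche_comparison_df(cmp), file.path(cfg$out_dir, "niche", "niche_comparison.csv"))
    .write_csv(
      rbind(
        data.frame(population = "EIOS", t(hv1$centroid)),
        data.frame(population = "WPI", t(hv2$centroid))
      ),
      file.path(cfg$out_dir, "niche", "centroids.csv")
    )
    .write_csv(as.data.frame(hv1$stochastic_points),
               file.path(cfg$out_dir, "niche", "stochastic_points_EIOS.csv"))
    .write_csv(as.data.frame(hv2$stochastic_points),
               file.path(cfg$out_dir, "niche", "stochastic_points_WPI.csv"))
    niche_out <- list(pca = pca, hv_EIOS = hv1, hv_WPI = hv2, comparison = cmp)
  } else {
    logln("niche: skipped (need >= 5 records in both populations)")
  }

  ## -- ensembles per level ---------------------------------------------------
  specs <- learner_specs(cfg$algorithms)
  ensembles <- list(); thresholds <- list(); cv_all <- list(); imp_all <- list()
  maps_dir <- file.path(cfg$out_dir, "maps")
  dir.create(maps_dir, recursive = TRUE, showWarnings = FALSE)
  binary_maps <- list()
  range_rows <- list()
  for (lv in levels) {
    tab <- tables[[lv]]
    env <- extract_env(tab, current)[, vars, drop = FALSE]
    y <- tab$response
    cv <- cross_validate(specs, env, y,
                         folds = cfg$cv$folds, replicates = cfg$cv$replicates,
                         seed = stage_seed(cfg$seed, paste0("cv_", lv)))
    cv_all[[lv]] <- cv
    .write_csv(cv$summary, file.path(cfg$out_dir, "models", paste0("cv_scores_", lv, ".csv")))
    sel <- select_members(cv, cfg$gates$tss_min, cfg$gates$auc_min)
    for (i in seq_len(nrow(sel$exclusions))) {
      logln("%s gate: excluded %s (%s)", lv,
            sel$exclusions$learner[i], sel$exclusions$reason[i])
    }
    logln("%s ensemble: %d members (%s)", lv, length(sel$included),
          paste(sel$included, collapse = ", "))
    .write_csv(sel$exclusions, file.path(cfg$out_dir, "models", paste0("exclusions_", lv, ".csv")))
    ens <- build_ensemble(sel$included, env, y, scores = cv,
                          weighting = cfg$weighting,
                          seed = stage_seed(cfg$seed, paste0("ensemble_", lv)))
    ensembles[[lv]] <- ens
    tau <- ensemble_threshold(ens, env, y)
    thresholds[[lv]] <- tau
    logln("%s maxTSS threshold: %.4f", lv, tau)
    imp <- variable_importance(ens, env, n_perm = 10,
                               seed = stage_seed(cfg$seed, paste0("importance_", lv)))
    imp_all[[lv]] <- imp
    .write_csv(imp, file.path(cfg$out_dir, "models", paste0("importance_", lv, ".csv")))
    curves <- do.call(rbind, lapply(vars, function(v) {
      cbind(variable = v, response_curve(ens, env, v))
    }))
    .write_csv(curves, file.path(cfg$out_dir, "models", paste0("response_curves_", lv, ".csv")))

    ## projections
    cur_map <- predict_map(ens, current)
    cur_bin <- binarize(cur_map, tau)
    write_ascii_raster(cur_map, file.path(maps_dir, paste0(lv, "_current_suitability.asc")))
    write_ascii_raster(cur_bin, file.path(maps_dir, paste0(lv, "_current_binary.asc")))
    report_side <- switch(lv, EIOS = "west", WPI = "east", NULL)
    rep_cur <- if (is.null(report_side)) cur_bin else restrict_to_side(cur_bin, boundary, report_side)
    binary_maps[[lv]] <- list(current = cur_bin, current_reported = rep_cur)
    for (tag in names(futures)) {
      fut_map <- predict_map(ens, futures[[tag]])
      fut_bin <- binarize(fut_map, tau)
      chg <- change_map(cur_bin, fut_bin)
      ca <- change_areas(chg)
      a_cur <- layer_area_km2(cur_bin)
      a_fut <- layer_area_km2(fut_bin)
      stopifnot(
        abs(ca[["loss"]] + ca[["stable"]] - a_cur) < 1e-6 * max(a_cur, 1),
        abs(ca[["stable"]] + ca[["gain"]] - a_fut) < 1e-6 * max(a_fut, 1)
      )
      write_ascii_raster(fut_map, file.path(maps_dir, paste0(lv, "_", tag, "_suitability.asc")))
      write_ascii_raster(fut_bin, file.path(maps_dir, paste0(lv, "_", tag, "_binary.asc")))
      write_ascii_raster(chg, file.path(maps_dir, paste0(lv, "_", tag, "_change.asc")))
      rep_fut <- if (is.null(report_side)) fut_bin else restrict_to_side(fut_bin, boundary, report_side)
      rc <- range_change(rep_cur, rep_fut)
      range_rows[[length(range_rows) + 1L]] <- data.frame(
        level = lv, scenario = tag, range_change_pct = rc,
        stringsAsFactors = FALSE
      )
      logln("%s %s: range change %.2f%%", lv, tag, rc)
      binary_maps[[lv]][[tag]] <- fut_bin
    }
  }
  range_table <- do.call(rbind, range_rows)
  .write_csv(range_table, file.path(cfg$out_dir, "tables", "range_change.csv"))
  .write_csv(
    data.frame(level = levels,
               threshold = unlist(thresholds[levels]),
               stringsAsFactors = FALSE),
    file.path(cfg$out_dir, "models", "thresholds.csv")
  )

  ## -- MPA gap analysis ------------------------------------------------------
  gap_report <- NULL
  if ("species" %in% levels) {
    mpas <- if (!is.null(cfg$inputs$mpas)) {
      read_geojson_polygons(cfg$inputs$mpas)
    } else {
      simulate_mpas(current, cfg$mpa$coverage_target, cfg$mpa$n_polygons,
                    seed = stage_seed(cfg$seed, "mpas"))
    }
    logln("MPAs: %d polygons", length(mpas))
    write_geojson_polygons(mpas, file.path(cfg$out_dir, "mpas.geojson"))
    mpa_mask <- rasterize_mpas(mpas, grid)
    rows <- list(protection_stats(binary_maps$species$current, mpa_mask, "current"))
    for (tag in names(futures)) {
      rows[[length(rows) + 1L]] <-
        protection_stats(binary_maps$species[[tag]], mpa_mask, tag)
    }
    gap_report <- do.call(rbind, rows)
    .write_csv(gap_report, file.path(cfg$out_dir, "tables", "gap_report.csv"))
    worst <- names(futures)[length(futures)]
    cons <- classify_conservation(binary_maps$species$current,
                                  binary_maps$species[[worst]], mpa_mask)
    chg_loss <- binary_maps$species$current$values == 1 &
      binary_maps$species[[worst]]$values == 0
    chg_loss[is.na(chg_loss)] <- FALSE
    stopifnot(
      !any(cons$pca & cons$poca),
      identical(cons$pca | cons$poca, chg_loss)
    )
    dir.create(file.path(cfg$out_dir, "conservation"), showWarnings = FALSE)
    for (nm in c("pca", "poca")) {
      msk <- layer(grid, ifelse(current$mask, as.numeric(cons[[nm]]), NA_real_),
                   mask = current$mask, name = paste0(nm, "_mask"))
      write_ascii_raster(msk, file.path(cfg$out_dir, "conservation", paste0(nm, "_mask.asc")))
    }
    logln("gap analysis: %.2f%% of current suitable area protected",
          gap_report$percent_protected[1])
  }

  ## -- manifest --------------------------------------------------------------
  manifest <- list(
    package = "nichecast",
    package_version = as.character(utils::packageVersion("nichecast")),
    r_version = as.character(getRversion()),
    base_seed = cfg$seed,
    stage_seeds = list(
      predictors = stage_seed(cfg$seed, "predictors"),
      hypervolumes = stage_seed(cfg$seed, "hypervolumes"),
      mpas = stage_seed(cfg$seed, "mpas")
    ),
    config = cfg[setdiff(names(cfg), "out_dir")]
  )
  yaml::write_yaml(manifest, file.path(cfg$out_dir, "manifest.yml"))
  logln("run finished")

  invisible(list(
    out_dir = cfg$out_dir, config = cfg, boundary = boundary,
    stack = current, futures = futures,
    occ = occ, tables = tables, screening = screen,
    niche = niche_out, cv = cv_all, ensembles = ensembles,
    thresholds = thresholds, importance = imp_all,
    binary_maps = binary_maps, range_table = range_table,
    gap_report = gap_report
  ))
}

#' Run the all-synthetic demonstration analysis
#'
#' A scaled-down but complete run of [run_pipeline()] on a coarser grid
#' with fewer presences and cross-validation replicates, suitable for
#' examples and smoke tests.
#'
#' @param out_dir Output directory.
#' @param seed Base seed.
#' @param ... Further config overrides.
#' @return The [run_pipeline()] result, invisibly.
#' @export
run_demo <- function(out_dir = tempfile("nichecast_demo_"), seed = 1L, ...) {
  cfg <- default_config(
    seed = seed, out_dir = out_dir,
    grid = list(lon_min = 90, lon_max = 140, lat_min = -11, lat_max = 15,
                resolution = 0.25),
    n_presences = 300,
    cv = list(folds = 5, replicates = 2),
    hypervolume = list(n_stochastic = 5000, quantile = 0.95),
    ...
  )
  run_pipeline(cfg)
}
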