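# Cleaning, grid thinning, population assignment and pseudo-absences.

test_that("clean_records applies the missing/duplicate/land/extent rules", {
  g <- small_grid(4, 4, 1, lon_min = 100, lat_max = 2)
  mask <- matrix(TRUE, 4, 4)
  mask[1, 1] <- FALSE # land cell: lon 100-101, lat 1-2
  st <- toy_stack(g, mask = mask)
  raw <- data.frame(
    lon = c(101.5, 101.5, 102.5, NA, 100.5, 103.5, 999),
    lat = c(0.5, 0.5, 0.5, 1.0, 1.5, -1.5, 0)
  )
  # drops: one duplicate, one missing lat, one land point, one out of extent
  out <- clean_records(raw, st)
  expect_equal(nrow(out), 3)
  expect_false(any(duplicated(out[, c("lon", "lat")])))
  # order of survivors is stable
  expect_equal(out$lon, c(101.5, 102.5, 103.5))
  expect_error(clean_records(data.frame(lon = NA_real_, lat = NA_real_), st), "survive")
})

test_that("a toy table with one missing, two duplicates and one land point keeps four rows", {
  g <- small_grid(4, 4, 1, lon_min = 100, lat_max = 2)
  mask <- matrix(TRUE, 4, 4)
  mask[1, 1] <- FALSE
  st <- toy_stack(g, mask = mask)
  raw <- data.frame(
    lon = c(101.5, 101.5, 102.5, NA, 100.5, 103.5, 103.2),
    lat = c(0.5, 0.5, 0.5, 1.0, 1.5, -1.5, -1.2)
  )
  expect_equal(nrow(clean_records(raw, st)), 4)
})

test_that("thinning keeps the first record per cell and is idempotent", {
  g <- small_grid(6, 8, 0.5)
  st <- toy_stack(g)
  two <- data.frame(id = c("a", "b"), lon = c(100.1, 100.2), lat = c(1.9, 1.8))
  thin <- thin_to_grid(clean_records(two, st), g)
  expect_equal(nrow(thin), 1)
  expect_equal(thin$id, "a")
  # distinct cells pass through unchanged
  apart <- clean_records(
    data.frame(lon = c(100.1, 101.1, 102.1), lat = c(1.9, 1.9, 1.9)), st
  )
  expect_equal(nrow(thin_to_grid(apart, g)), 3)
  # 50 clustered points: retained count equals brute-force occupied cells
  set.seed(31)
  pts <- data.frame(
    lon = 100 + sample(0:5, 50, TRUE) * 0.5 + 0.25,
    lat = 2 - sample(0:3, 50, TRUE) * 0.5 - 0.25
  )
  occ <- clean_records(pts, st)
  thinned <- thin_to_grid(occ, g)
  rc <- point_to_cell(g, occ$lon, occ$lat)
  expect_equal(nrow(thinned), length(unique(paste(rc$row, rc$col))))
  # idempotence of clean -> thin
  expect_identical(thin_to_grid(thinned, g), thinned)
})

test_that("population assignment matches a brute-force point-in-polygon test", {
  b <- boundary_line(data.frame(lon = c(104, 106, 105), lat = c(-5, 0, 5)))
  set.seed(17)
  occ <- data.frame(
    id = sprintf("p%03d", 1:500),
    lon = runif(500, 100, 110),
    lat = runif(500, -5, 5),
    population = "unassigned",
    response = 1L
  )
  got <- assign_population(occ, b)
  # brute force: close the western region with the extent's west edge
  west_poly <- data.frame(
    lon = c(99, 104, 106, 105, 99),
    lat = c(-6, -5, 0, 5, 6)
  )
  inside_west <- point_in_polygon(occ$lon, occ$lat, west_poly)
  expect_identical(got$population, ifelse(inside_west, "EIOS", "WPI"))
  # extremes
  expect_identical(assign_population(occ[which.min(occ$lon), ], b)$population, "EIOS")
  expect_identical(assign_population(occ[which.max(occ$lon), ], b)$population, "WPI")
  # invariant to record order
  perm <- sample(nrow(occ))
  got2 <- assign_population(occ[perm, ], b)
  expect_identical(got2$population, got$population[perm])
  # on-boundary points go west, with a message
  on_line <- data.frame(id = "x", lon = 106, lat = 0, population = "unassigned", response = 1L)
  expect_message(res <- assign_population(on_line, b), "EIOS")
  expect_identical(res$population, "EIOS")
})

test_that("a 213-record table partitions into 113 west and 100 east records", {
  b <- boundary_line(data.frame(lon = c(117.5, 117.5), lat = c(-11, 15)))
  set.seed(4)
  occ <- data.frame(
    id = sprintf("r%03d", 1:213),
    lon = c(runif(113, 95, 117), runif(100, 118, 139)),
    lat = runif(213, -10, 14),
    population = "unassigned",
    response = 1L
  )
  out <- assign_population(occ, b)
  expect_equal(unname(table(out$population)["EIOS"]), 113)
  expect_equal(unname(table(out$population)["WPI"]), 100)
  expect_equal(nrow(out), 213) # lossless partition
})

test_that("pseudo-absences are balanced, deterministic and outside the envelope", {
  g <- grid_spec(100, 110, -5, 5, 0.5)
  st <- toy_stack(g, seed = 6)
  niche <- niche_function(
    c(temperature_mean = 30), c(temperature_mean = 0.5)
  )
  pres <- thin_to_grid(sample_occurrences(st, niche, 60, seed = 2), g)
  abs1 <- generate_pseudo_absences(pres, st, seed = 5)
  expect_equal(nrow(abs1), nrow(pres))
  expect_true(all(abs1$response == 0L))
  expect_identical(abs1, generate_pseudo_absences(pres, st, seed = 5))
  # brute-force envelope check: every absence outside [min, max] of the
  # presences in at least one variable
  env_p <- extract_env(pres, st)
  env_a <- extract_env(abs1, st)
  lo <- apply(env_p, 2, min)
  hi <- apply(env_p, 2, max)
  for (i in seq_len(nrow(env_a))) {
    expect_true(any(env_a[i, ] < lo | env_a[i, ] > hi))
  }
  # absences never share a cell with a presence
  rc_p <- point_to_cell(g, pres$lon, pres$lat)
  rc_a <- point_to_cell(g, abs1$lon, abs1$lat)
  expect_length(
    intersect(paste(rc_p$row, rc_p$col), paste(rc_a$row, rc_a$col)), 0
  )
})

test_that("pseudo-absence generation fails when presences fill the sea", {
  g <- small_grid(2, 2, 1, lon_min = 100, lat_max = 2)
  st <- toy_stack(g)
  ctr <- cell_center(g, c(1, 1, 2, 2), c(1, 2, 1, 2))
  pres <- data.frame(
    id = paste0("p", 1:4), lon = ctr$lon, lat = ctr$lat,
    population = "unassigned", response = 1L
  )
  expect_error(generate_pseudo_absences(pres, st, seed = 1), "presence-free")
})

test_that("prepare_response_table yields a balanced 0/1 design", {
  g <- grid_spec(100, 110, -5, 5, 0.5)
  st <- toy_stack(g, seed = 9)
  b <- boundary_line(data.frame(lon = c(105, 105), lat = c(-5, 5)))
  raw <- sample_occurrences(st, niche_function(numeric(0), numeric(0)), 120, seed = 3)
  # presences scattered over the whole sea leave too few cells outside
  # their environmental envelope, so the rule is relaxed with a warning
  expect_warning(
    tab <- prepare_response_table(raw, st, boundary = b, seed = 10),
    "relaxing"
  )
  expect_equal(sum(tab$response == 1), sum(tab$response == 0))
  expect_true(all(tab$population[tab$response == 1] %in% c("EIOS", "WPI")))
})
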