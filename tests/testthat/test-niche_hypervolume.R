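# Hypervolume construction, Monte-Carlo volumes against fine-grid KDE
# integration oracles, overlap decomposition and its algebraic identities.

test_that("1-D hypervolume matches grid integration and the normal HDR scale", {
  set.seed(1)
  x <- matrix(rnorm(2000), ncol = 1, dimnames = list(NULL, "PC1"))
  hv <- build_hypervolume(x, n_stochastic = 20000, quantile = 0.95, seed = 2)
  oracle <- grid_kde_volume(
    hv$train, hv$bandwidth, hv$threshold, hv$box_lo, hv$box_hi,
    n_grid = 4000
  )
  expect_lt(abs(hv$volume - oracle) / oracle, 0.10)
  # a 95% region of a standard normal is a bit wider than 2 * 1.96 because
  # of kernel widening; it must bracket that scale
  expect_gt(hv$volume, 2 * 1.96 * 0.9)
  expect_lt(hv$volume, 2 * 1.96 * 1.5)
})

test_that("2-D hypervolume of a uniform square approaches its true area", {
  set.seed(3)
  x <- matrix(runif(2 * 5000), ncol = 2, dimnames = list(NULL, c("PC1", "PC2")))
  hv <- build_hypervolume(x, n_stochastic = 20000, quantile = 1, seed = 4)
  # Silverman smoothing of a sharp-edged uniform widens the region by a few
  # bandwidths, so the estimate sits somewhat above the true area of 1; the
  # grid-integration oracle of the same KDE must agree closely
  expect_lt(abs(hv$volume - 1), 0.2)
  oracle <- grid_kde_volume(
    hv$train, hv$bandwidth, hv$threshold, hv$box_lo, hv$box_hi, n_grid = 220
  )
  expect_lt(abs(hv$volume - oracle) / oracle, 0.10)
})

test_that("2-D volume agrees with fine-grid integration of the same KDE", {
  set.seed(9)
  x <- matrix(rnorm(2 * 400), ncol = 2, dimnames = list(NULL, c("PC1", "PC2")))
  hv <- build_hypervolume(x, n_stochastic = 40000, quantile = 0.95, seed = 5)
  oracle <- grid_kde_volume(
    hv$train, hv$bandwidth, hv$threshold, hv$box_lo, hv$box_hi,
    n_grid = 250
  )
  expect_lt(abs(hv$volume - oracle) / oracle, 0.10)
})

test_that("Monte-Carlo volume is stable under doubling the draw count", {
  set.seed(6)
  x <- matrix(rnorm(2 * 800), ncol = 2)
  v1 <- build_hypervolume(x, n_stochastic = 20000, seed = 7)$volume
  v2 <- build_hypervolume(x, n_stochastic = 40000, seed = 8)$volume
  expect_lt(abs(v2 - v1) / v1, 0.05)
})

test_that("degenerate inputs are rejected with informative errors", {
  expect_error(build_hypervolume(matrix(rnorm(8), 4, 2)), "at least 5")
  x <- cbind(PC1 = rnorm(50), PC2 = rep(2, 50))
  expect_error(build_hypervolume(x), "PC2")
  h1 <- build_hypervolume(matrix(rnorm(100), ncol = 1), seed = 1)
  h2 <- build_hypervolume(matrix(rnorm(100), ncol = 2), seed = 1)
  expect_error(overlap_hypervolumes(h1, h2), "dimensions differ")
})

test_that("identical niches give near-zero divergence, disjoint niches near one", {
  set.seed(10)
  x <- matrix(rnorm(2 * 500), ncol = 2)
  h1 <- build_hypervolume(x, seed = 11)
  h2 <- build_hypervolume(x, seed = 12)
  same <- overlap_hypervolumes(h1, h2, seed = 13)
  expect_lt(same$beta_total, 0.05)
  # congruent but fully disjoint clouds: total -> 1, all of it shift
  y <- x
  y[, 1] <- y[, 1] + 40
  h3 <- build_hypervolume(y, seed = 14)
  far <- overlap_hypervolumes(h1, h3, seed = 15, n_mc = 50000)
  expect_gt(far$beta_total, 0.95)
  expect_gt(far$beta_shift, 0.9)
  expect_lt(far$beta_rich, 0.1)
})

test_that("nested regions with a 2:1 volume ratio decompose into richness", {
  set.seed(16)
  big <- matrix(runif(4000, 0, 2), ncol = 1)
  small <- matrix(runif(4000, 0.5, 1.5), ncol = 1)
  h_big <- build_hypervolume(big, quantile = 1, seed = 17)
  h_small <- build_hypervolume(small, quantile = 1, seed = 18)
  expect_equal(h_big$volume / h_small$volume, 2, tolerance = 0.15)
  cmp <- overlap_hypervolumes(h_big, h_small, seed = 19, n_mc = 50000)
  # plugging V1 = 2V2, shared = V2 into the formulas: total = 1/2 = rich
  expect_equal(cmp$beta_total, 0.5, tolerance = 0.1)
  expect_lt(cmp$beta_shift, 0.1)
  expect_equal(cmp$beta_rich, cmp$beta_total - cmp$beta_shift, tolerance = 1e-12)
})

test_that("beta decomposition identity and symmetry hold on random pairs", {
  for (seed in 1:5) {
    set.seed(seed)
    a <- matrix(rnorm(2 * 150, sd = 1), ncol = 2)
    b <- matrix(rnorm(2 * 150, mean = seed / 2), ncol = 2)
    ha <- build_hypervolume(a, n_stochastic = 8000, seed = seed + 100)
    hb <- build_hypervolume(b, n_stochastic = 8000, seed = seed + 200)
    ab <- overlap_hypervolumes(ha, hb, seed = seed + 300, n_mc = 8000)
    ba <- overlap_hypervolumes(hb, ha, seed = seed + 300, n_mc = 8000)
    # exact algebraic identity 2 min(u1,u2) + |u1-u2| = u1 + u2
    expect_equal(ab$beta_total, ab$beta_shift + ab$beta_rich, tolerance = 1e-12)
    expect_true(ab$beta_total >= 0 && ab$beta_total <= 1)
    expect_true(ab$V_shared >= 0 && ab$V_shared <= min(ab$V1, ab$V2) + 1e-12)
    expect_equal(abs(ab$V_union - (ab$V1 + ab$V2 - ab$V_shared)), 0, tolerance = 1e-9)
    # order of arguments does not matter
    expect_equal(ba$beta_total, ab$beta_total, tolerance = 1e-12)
    expect_equal(ba$beta_shift, ab$beta_shift, tolerance = 1e-12)
    expect_equal(ba$beta_rich, ab$beta_rich, tolerance = 1e-12)
  }
})

test_that("well-separated optima diverge while identical samples do not", {
  # stand-ins for two populations' PCA scores: equal generating
  # distributions versus optima more than 4 tolerance units apart
  set.seed(20)
  same1 <- matrix(rnorm(2 * 500), ncol = 2)
  same2 <- matrix(rnorm(2 * 500), ncol = 2)
  h1 <- build_hypervolume(same1, seed = 21)
  h2 <- build_hypervolume(same2, seed = 22)
  expect_lt(overlap_hypervolumes(h1, h2, seed = 23)$beta_total, 0.15)
  apart <- matrix(rnorm(2 * 500, mean = 4.5 / sqrt(2)), ncol = 2)
  h3 <- build_hypervolume(apart, seed = 24)
  expect_gt(overlap_hypervolumes(h1, h3, seed = 25)$beta_total, 0.7)
})

test_that("decomposition shares reproduce the printed component split", {
  sh <- decomposition_shares(list(beta_shift = 0.28, beta_rich = 0.33))
  expect_equal(round(unname(sh["shift_share"]), 2), 45.90)
  expect_equal(round(unname(sh["rich_share"]), 2), 54.10)
  expect_equal(sum(sh), 100, tolerance = 1e-9)
  expect_equal(0.28 + 0.33, 0.61, tolerance = 1e-12)
  expect_equal(
    unname(decomposition_shares(list(beta_shift = 0.2, beta_rich = 0.2))),
    c(50, 50)
  )
  expect_equal(
    unname(decomposition_shares(list(beta_shift = 0.4, beta_rich = 0))),
    c(100, 0)
  )
  expect_error(decomposition_shares(list(beta_shift = 0, beta_rich = 0)), "undefined")
})
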