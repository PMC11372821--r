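# Shared fixtures: small grids and hand-built predictor stacks.

small_grid <- function(n_rows = 6, n_cols = 8, res = 0.5,
                       lon_min = 100, lat_max = 2) {
  grid_spec(lon_min, lon_min + n_cols * res, lat_max - n_rows * res, lat_max, res)
}

# Build a stack from named value matrices (all sharing one mask).
stack_from_values <- function(grid, values, mask = NULL, tag = "current") {
  if (is.null(mask)) mask <- matrix(TRUE, grid$n_rows, grid$n_cols)
  layers <- lapply(names(values), function(nm) {
    v <- values[[nm]]
    v[!mask] <- NA_real_
    layer(grid, v, mask = mask, name = nm)
  })
  predictor_stack(layers, scenario_tag = tag)
}

# A deterministic all-sea toy stack with the nine canonical layers, values
# linear in lon/lat so extraction is easy to predict.
toy_stack <- function(grid = small_grid(), seed = 1, mask = NULL) {
  set.seed(seed)
  nms <- predictor_table()$name
  vals <- lapply(seq_along(nms), function(i) {
    matrix(
      stats::rnorm(grid$n_rows * grid$n_cols, mean = i * 10, sd = 1),
      grid$n_rows, grid$n_cols
    )
  })
  names(vals) <- nms
  vals$depth <- abs(vals$depth) + 1 # all positive: everything is sea
  if (is.null(mask)) mask <- matrix(TRUE, grid$n_rows, grid$n_cols)
  stack_from_values(grid, vals, mask = mask)
}

# A balanced toy presence/absence modelling table with signal in the first
# column; returns list(env, y).
toy_model_table <- function(n = 200, p = 4, seed = 1, signal = 2.5) {
  set.seed(seed)
  env <- matrix(stats::rnorm(n * p), n, p,
    dimnames = list(NULL, paste0("v", seq_len(p)))
  )
  prob <- stats::plogis(signal * env[, 1])
  y <- stats::rbinom(n, 1, prob)
  # enforce both classes
  if (sum(y) < 2) y[1:2] <- 1L
  if (sum(1 - y) < 2) y[(n - 1):n] <- 0L
  list(env = env, y = as.integer(y))
}

# Independent trapezoidal ROC integration (oracle for the rank AUC).
trapezoid_auc <- function(pred, obs) {
  th <- sort(unique(pred), decreasing = TRUE)
  th <- c(Inf, th)
  tpr <- vapply(th, function(t) mean(pred[obs == 1] >= t), numeric(1))
  fpr <- vapply(th, function(t) mean(pred[obs == 0] >= t), numeric(1))
  tpr <- c(tpr, 1)
  fpr <- c(fpr, 1)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

# Independent fine-grid integration of a Gaussian product KDE: volume of
# the region where the KDE of `train` (bandwidth bw) is >= thr.
grid_kde_volume <- function(train, bw, thr, lo, hi, n_grid = 200) {
  d <- ncol(train)
  axes <- lapply(seq_len(d), function(j) seq(lo[j], hi[j], length.out = n_grid))
  pts <- as.matrix(expand.grid(axes))
  dens <- rep(0, nrow(pts))
  for (i in seq_len(nrow(train))) {
    contrib <- rep(1, nrow(pts))
    for (j in seq_len(d)) {
      contrib <- contrib * stats::dnorm(pts[, j], train[i, j], bw[j])
    }
    dens <- dens + contrib
  }
  dens <- dens / nrow(train)
  cell <- prod(vapply(axes, function(a) a[2] - a[1], numeric(1)))
  sum(dens >= thr) * cell
}
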