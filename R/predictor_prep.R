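# Model-matrix construction: point extraction from the raster stack,
# collinearity screening by pairwise Pearson correlation and variance
# inflation factors, and standardized principal component analysis.

#' Extract environmental values at occurrence points
#'
#' Nearest-cell extraction (the value of the grid cell containing each
#' point, no interpolation); row order is preserved and row names carry the
#' record ids.
#'
#' @param occ Occurrence data.frame with `lon`, `lat` (and ideally `id`).
#' @param stack A [predictor_stack()].
#' @return Numeric matrix, rows = records, columns = predictor variables in
#'   stack order.
#' @export
extract_env <- function(occ, stack) {
  stopifnot(inherits(stack, "predictor_stack"))
  rc <- point_to_cell(stack$grid, occ$lon, occ$lat)
  idx <- cbind(rc$row, rc$col)
  bad <- !stack$mask[idx]
  if (any(bad)) {
    ids <- if ("id" %in% names(occ)) occ$id[bad] else which(bad)
    stop(
      "record(s) on masked (land) cells: ",
      paste(utils::head(ids, 5), collapse = ", "),
      if (sum(bad) > 5) sprintf(" and %d more", sum(bad) - 5) else ""
    )
  }
  env <- vapply(stack$layers, function(l) l$values[idx], numeric(nrow(occ)))
  if (nrow(occ) == 1) env <- matrix(env, nrow = 1, dimnames = list(NULL, names(stack$layers)))
  rownames(env) <- if ("id" %in% names(occ)) occ$id else NULL
  env
}

# VIF of every column: 1 / (1 - R^2) of each variable regressed on the
# others, computed from the correlation matrix inverse.
.vif_all <- function(x) {
  r <- stats::cor(x)
  ri <- tryCatch(solve(r), error = function(e) MASS::ginv(r))
  v <- diag(ri)
  names(v) <- colnames(x)
  pmax(v, 1)
}

#' Screen predictors for collinearity
#'
#' Two-stage iterative filter. Stage 1: while any pair of retained
#' variables has `|Pearson r| >= r_max`, drop from the worst pair the
#' variable with the larger mean absolute correlation against all other
#' retained variables. Stage 2: while any retained variable has
#' `VIF >= vif_max` (VIF = 1/(1 - R^2) of that variable regressed on the
#' rest), drop the largest. Constant columns are dropped up front with a
#' warning (their VIF is undefined).
#'
#' @param env Numeric matrix or data.frame (rows = records, columns =
#'   variables); at least 2 columns and 3 rows.
#' @param r_max Pairwise absolute-correlation threshold (default 0.7).
#' @param vif_max Variance-inflation threshold (default 10).
#' @return List with `retained` (character vector) and `report` (data.frame
#'   with columns `variable`, `action`, `statistic`, `value` documenting
#'   every drop and the final per-variable VIFs).
#' @export
collinearity_filter <- function(env, r_max = 0.7, vif_max = 10) {
  x <- as.matrix(env)
  stopifnot(ncol(x) >= 2, nrow(x) >= 3)
  report <- data.frame(
    variable = character(), action = character(),
    statistic = character(), value = numeric(),
    stringsAsFactors = FALSE
  )
  const <- apply(x, 2, function(v) stats::sd(v) == 0 || !is.finite(stats::sd(v)))
  if (any(const)) {
    warning("dropping constant column(s): ", paste(colnames(x)[const], collapse = ", "))
    for (v in colnames(x)[const]) {
      report[nrow(report) + 1L, ] <- list(v, "dropped", "constant (VIF undefined)", NA_real_)
    }
    x <- x[, !const, drop = FALSE]
  }
  repeat {
    if (ncol(x) < 2) break
    r <- stats::cor(x)
    diag(r) <- 0
    worst <- max(abs(r))
    if (worst < r_max) break
    pair <- which(abs(r) == worst, arr.ind = TRUE)[1, ]
    mean_abs <- rowMeans(abs(r))
    drop_ix <- pair[which.max(mean_abs[pair])]
    v <- colnames(x)[drop_ix]
    report[nrow(report) + 1L, ] <- list(v, "dropped", "pairwise |r|", worst)
    x <- x[, -drop_ix, drop = FALSE]
  }
  repeat {
    if (ncol(x) < 2) break
    v_all <- .vif_all(x)
    if (max(v_all) < vif_max) break
    drop_ix <- which.max(v_all)
    v <- colnames(x)[drop_ix]
    report[nrow(report) + 1L, ] <- list(v, "dropped", "VIF", max(v_all))
    x <- x[, -drop_ix, drop = FALSE]
  }
  if (ncol(x) >= 2) {
    v_all <- .vif_all(x)
    for (v in colnames(x)) {
      report[nrow(report) + 1L, ] <- list(v, "retained", "VIF", unname(v_all[v]))
    }
  } else {
    for (v in colnames(x)) {
      report[nrow(report) + 1L, ] <- list(v, "retained", "VIF", NA_real_)
    }
  }
  list(retained = colnames(x), report = report)
}

#' Standardized principal component analysis
#'
#' Variables are centred and scaled to unit variance before the
#' eigen-decomposition; each component's sign is fixed so that its
#' largest-magnitude loading is positive.
#'
#' @param env Numeric matrix or data.frame, rows = records.
#' @param k Number of components to retain (default 4).
#' @return Object of class `pca_result` with fields `loadings`
#'   (variables x k), `scores` (records x k), `variance_explained`
#'   (fractions, all components), `k`, `center`, `scale`.
#' @export
pca_fit <- function(env, k = 4) {
  x <- as.matrix(env)
  if (k < 1) stop("k must be >= 1")
  if (k > ncol(x)) stop("k exceeds the number of variables")
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  flip <- apply(pc$rotation, 2, function(l) sign(l[which.max(abs(l))]))
  flip[flip == 0] <- 1
  rot <- sweep(pc$rotation, 2, flip, "*")
  sco <- sweep(pc$x, 2, flip, "*")
  structure(
    list(
      loadings = rot[, seq_len(k), drop = FALSE],
      scores = sco[, seq_len(k), drop = FALSE],
      variance_explained = ve,
      k = k,
      center = pc$center,
      scale = pc$scale
    ),
    class = "pca_result"
  )
}

#' @export
print.pca_result <- function(x, ...) {
  cum <- cumsum(x$variance_explained)[x$k]
  cat(sprintf(
    "pca_result: %d of %d components retained, %.1f%% of variance\n",
    x$k, length(x$variance_explained), 100 * cum
  ))
  invisible(x)
}

#' Project new data onto a fitted PCA
#'
#' @param pca A [pca_fit()] result.
#' @param env New data with the same variables.
#' @return Score matrix (rows x k).
#' @export
pca_project <- function(pca, env) {
  x <- as.matrix(env)[, rownames(pca$loadings), drop = FALSE]
  xs <- sweep(sweep(x, 2, pca$center, "-"), 2, pca$scale, "/")
  xs %*% pca$loadings
}
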