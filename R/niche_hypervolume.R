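# Kernel-density niche hypervolumes and the decomposition of pairwise
# niche difference into shift (spatial replacement) and
# contraction/expansion (net volume difference) components.
#
# A hypervolume is the region of (PCA) niche space where a Gaussian
# product-kernel density estimate of the population's occurrence scores
# exceeds a quantile-based inclusion threshold; its size is estimated by
# uniform Monte-Carlo sampling over a bounding box.

# Evaluate a Gaussian product-kernel density estimate with per-dimension
# bandwidths `bw` (train = n x d matrix) at the rows of `y`.
.kde_eval <- function(train, bw, y) {
  n <- nrow(train)
  d <- ncol(train)
  norm_const <- 1 / (n * prod(bw) * (2 * pi)^(d / 2))
  acc <- numeric(nrow(y))
  yb <- sweep(y, 2, bw, "/")
  tb <- sweep(train, 2, bw, "/")
  for (i in seq_len(n)) {
    z2 <- rowSums(sweep(yb, 2, tb[i, ], "-")^2)
    acc <- acc + exp(-0.5 * z2)
  }
  acc * norm_const
}

# Per-dimension Silverman bandwidth for a d-dimensional Gaussian kernel:
# bw_j = sd_j * (4 / ((d + 2) n))^(1 / (d + 4)).
silverman_bandwidth <- function(scores) {
  n <- nrow(scores)
  d <- ncol(scores)
  apply(scores, 2, stats::sd) * (4 / ((d + 2) * n))^(1 / (d + 4))
}

#' Build a kernel-density niche hypervolume
#'
#' Fits a Gaussian product-kernel density (per-dimension Silverman
#' bandwidth) to the training scores, sets the inclusion threshold at the
#' density value below which only `1 - quantile` of the training points
#' fall, and estimates the region's volume by uniform Monte-Carlo sampling
#' over the training bounding box expanded by 3 bandwidths:
#' `volume = box_volume * fraction of uniform draws with density >=
#' threshold`. The accepted draws are kept as the hypervolume's stochastic
#' points (capped at `n_stochastic`). Deterministic given `seed`.
#'
#' @param scores Numeric matrix, rows = records, columns = niche axes
#'   (typically retained principal components); at least 5 rows.
#' @param n_stochastic Number of uniform Monte-Carlo draws (and the cap on
#'   retained stochastic points). Default 20000.
#' @param quantile Fraction of training points the region must contain
#'   (default 0.95).
#' @param seed Integer RNG seed.
#' @return Object of class `hypervolume_kde` with fields `dim`, `train`,
#'   `bandwidth`, `threshold`, `quantile`, `box_lo`, `box_hi`, `volume`,
#'   `stochastic_points`, `centroid`, `n_draws`, `seed`.
#' @export
build_hypervolume <- function(scores, n_stochastic = 20000, quantile = 0.95,
                              seed = 1L) {
  scores <- as.matrix(scores)
  if (nrow(scores) < 5) stop("at least 5 records are required to build a hypervolume")
  d <- ncol(scores)
  if (is.null(colnames(scores))) colnames(scores) <- paste0("PC", seq_len(d))
  bw <- silverman_bandwidth(scores)
  if (any(bw <= 0 | !is.finite(bw))) {
    stop(
      "zero bandwidth in dimension(s): ",
      paste(colnames(scores)[bw <= 0 | !is.finite(bw)], collapse = ", "),
      " (constant dimension?)"
    )
  }
  dens_train <- .kde_eval(scores, bw, scores)
  thr <- unname(stats::quantile(dens_train, probs = 1 - quantile))
  lo <- apply(scores, 2, min) - 3 * bw
  hi <- apply(scores, 2, max) + 3 * bw
  box_vol <- prod(hi - lo)
  set.seed(seed)
  u <- matrix(stats::runif(n_stochastic * d), n_stochastic, d)
  draws <- sweep(sweep(u, 2, hi - lo, "*"), 2, lo, "+")
  colnames(draws) <- colnames(scores)
  inside <- .kde_eval(scores, bw, draws) >= thr
  vol <- box_vol * mean(inside)
  pts <- draws[inside, , drop = FALSE]
  if (nrow(pts) > n_stochastic) pts <- pts[seq_len(n_stochastic), , drop = FALSE]
  structure(
    list(
      dim = d, train = scores, bandwidth = bw, threshold = thr,
      quantile = quantile, box_lo = lo, box_hi = hi, volume = vol,
      stochastic_points = pts, centroid = colMeans(scores),
      n_draws = n_stochastic, seed = seed
    ),
    class = "hypervolume_kde"
  )
}

#' @export
print.hypervolume_kde <- function(x, ...) {
  cat(sprintf(
    "hypervolume_kde: d = %d, n = %d records, volume = %.4g (inclusion quantile %.2f)\n",
    x$dim, nrow(x$train), x$volume, x$quantile
  ))
  invisible(x)
}

#' Test whether points fall inside a hypervolume
#'
#' @param hv A [build_hypervolume()] result.
#' @param y Matrix of points (columns = the hypervolume's axes).
#' @return Logical vector.
#' @export
hypervolume_contains <- function(hv, y) {
  .kde_eval(hv$train, hv$bandwidth, as.matrix(y)) >= hv$threshold
}

#' Overlap two hypervolumes and decompose their difference
#'
#' The shared volume is estimated by uniform sampling over the union of the
#' two bounding boxes, counting draws inside both inclusion regions (then
#' clamped into `[0, min(V1, V2)]` against Monte-Carlo noise). With
#' `unique_i = V_i - V_shared` and `V_union = V1 + V2 - V_shared`, the
#' total niche difference and its decomposition are
#' \deqn{\beta_{total} = (u_1 + u_2) / V_{union},\quad
#'       \beta_{shift} = 2\min(u_1, u_2)/V_{union},\quad
#'       \beta_{rich} = |u_1 - u_2|/V_{union},}
#' so that `beta_total = beta_shift + beta_rich` holds exactly:
#' shift is spatial replacement between the regions, rich the net
#' contraction/expansion. All three lie in `[0, 1]`, from complete overlap
#' (0) to complete separation (1).
#'
#' @param hv1,hv2 Hypervolumes of equal dimension.
#' @param seed Integer RNG seed for the shared-volume draw.
#' @param n_mc Number of uniform draws over the union box (default 20000).
#' @return Object of class `niche_comparison`: `V1`, `V2`, `V_shared`,
#'   `V_union`, `beta_total`, `beta_shift`, `beta_rich`, and the centroids.
#' @export
overlap_hypervolumes <- function(hv1, hv2, seed = 1L, n_mc = 20000) {
  stopifnot(inherits(hv1, "hypervolume_kde"), inherits(hv2, "hypervolume_kde"))
  if (hv1$dim != hv2$dim) stop("hypervolume dimensions differ (", hv1$dim, " vs ", hv2$dim, ")")
  d <- hv1$dim
  lo <- pmin(hv1$box_lo, hv2$box_lo)
  hi <- pmax(hv1$box_hi, hv2$box_hi)
  box_vol <- prod(hi - lo)
  set.seed(seed)
  u <- matrix(stats::runif(n_mc * d), n_mc, d)
  draws <- sweep(sweep(u, 2, hi - lo, "*"), 2, lo, "+")
  in1 <- hypervolume_contains(hv1, draws)
  in2 <- hypervolume_contains(hv2, draws)
  v_shared <- box_vol * mean(in1 & in2)
  v_shared <- min(max(v_shared, 0), min(hv1$volume, hv2$volume))
  u1 <- hv1$volume - v_shared
  u2 <- hv2$volume - v_shared
  v_union <- hv1$volume + hv2$volume - v_shared
  structure(
    list(
      V1 = hv1$volume, V2 = hv2$volume,
      V_shared = v_shared, V_union = v_union,
      beta_total = (u1 + u2) / v_union,
      beta_shift = 2 * min(u1, u2) / v_union,
      beta_rich = abs(u1 - u2) / v_union,
      centroid1 = hv1$centroid, centroid2 = hv2$centroid
    ),
    class = "niche_comparison"
  )
}

#' @export
print.niche_comparison <- function(x, ...) {
  cat(sprintf(
    "niche_comparison: V1 = %.4g, V2 = %.4g, shared = %.4g\n  beta_total = %.3f = shift %.3f + contraction/expansion %.3f\n",
    x$V1, x$V2, x$V_shared, x$beta_total, x$beta_shift, x$beta_rich
  ))
  invisible(x)
}

#' Percentage shares of the niche-difference components
#'
#' Expresses the shift and contraction/expansion components as percentages
#' of the total difference: `100 * beta_shift / beta_total` and
#' `100 * beta_rich / beta_total` (they sum to 100).
#'
#' @param cmp A [overlap_hypervolumes()] result, or any list with
#'   `beta_shift` and `beta_rich`.
#' @return Named numeric vector `c(shift_share, rich_share)` in percent.
#' @export
decomposition_shares <- function(cmp) {
  bt <- cmp$beta_shift + cmp$beta_rich
  if (bt <= 0) stop("beta_total is zero: component shares are undefined")
  c(
    shift_share = 100 * cmp$beta_shift / bt,
    rich_share = 100 * cmp$beta_rich / bt
  )
}

#' Flatten a niche comparison to a one-row data.frame
#'
#' @param cmp A [overlap_hypervolumes()] result.
#' @return data.frame with volumes, beta components, and shares (percent).
#' @export
niche_comparison_df <- function(cmp) {
  sh <- decomposition_shares(cmp)
  data.frame(
    V1 = cmp$V1, V2 = cmp$V2, V_shared = cmp$V_shared, V_union = cmp$V_union,
    beta_total = cmp$beta_total, beta_shift = cmp$beta_shift,
    beta_rich = cmp$beta_rich,
    shift_share_pct = unname(sh["shift_share"]),
    rich_share_pct = unname(sh["rich_share"])
  )
}
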