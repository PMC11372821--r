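# Candidate suitability learners, TSS/AUC evaluation, replicated stratified
# cross-validation, gate-and-weight ensembling, permutation importance and
# response curves.
#
# Ten algorithms are available: GLM, GAM, MARS, CTA, RF, GBM, ANN, FDA,
# MAXENT and SRE. Each is fit on a balanced presence / pseudo-absence table
# and exposes a suitability prediction in [0, 1]. The surface range
# envelope (SRE) is a bespoke percentile envelope on the presences; MARS is
# a logistic fit on fixed-knot hinge basis functions; FDA is linear
# discriminant analysis on a quadratic basis; MAXENT is an L1-regularised
# logistic model on an expanded feature set. Hyperparameters are fixed and
# recorded on each spec.

.ALGORITHMS <- c("GLM", "GAM", "MARS", "CTA", "RF", "GBM", "ANN", "FDA", "MAXENT", "SRE")

#' Learner specifications
#'
#' @param algorithms Character vector of algorithm names (subset of
#'   `GLM, GAM, MARS, CTA, RF, GBM, ANN, FDA, MAXENT, SRE`).
#' @return List of specs, each `list(name, params)` with the fixed
#'   hyperparameters used for that algorithm.
#' @export
learner_specs <- function(algorithms = .ALGORITHMS) {
  bad <- setdiff(algorithms, .ALGORITHMS)
  if (length(bad)) stop("unknown algorithm(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(algorithms)) stop("duplicate algorithm names")
  params <- list(
    GLM = list(terms = "linear+quadratic"),
    GAM = list(k = 4),
    MARS = list(knot_probs = c(0.25, 0.5, 0.75), lambda = 1e-3),
    CTA = list(cp = 0.01, minsplit = 10),
    RF = list(ntree = 300),
    GBM = list(nrounds = 100, max_depth = 3, eta = 0.1),
    ANN = list(size = 5, decay = 0.01, maxit = 300),
    FDA = list(basis = "quadratic"),
    MAXENT = list(lambda = 0.002, features = "linear+quadratic+hinge"),
    SRE = list(q = 0.025)
  )
  lapply(algorithms, function(a) list(name = a, params = params[[a]]))
}

# ---- feature expansions -----------------------------------------------------

.quad_expand <- function(x) {
  q <- cbind(x, x^2)
  colnames(q) <- c(colnames(x), paste0(colnames(x), "_sq"))
  q
}

.hinge_knots <- function(x, probs) {
  lapply(seq_len(ncol(x)), function(j) {
    unique(stats::quantile(x[, j], probs = probs, names = FALSE))
  })
}

.hinge_expand <- function(x, knots) {
  cols <- list(x)
  for (j in seq_len(ncol(x))) {
    for (c0 in knots[[j]]) {
      cols[[length(cols) + 1L]] <- cbind(
        pmax(x[, j] - c0, 0),
        pmax(c0 - x[, j], 0)
      )
    }
  }
  out <- do.call(cbind, cols)
  colnames(out) <- paste0("f", seq_len(ncol(out)))
  out
}

.clamp01 <- function(p) pmin(pmax(as.numeric(p), 0), 1)

# ---- fitting ----------------------------------------------------------------

#' Fit one suitability learner
#'
#' @param spec One element of [learner_specs()].
#' @param env Numeric matrix of predictors (rows = records).
#' @param response Integer 0/1 vector (pseudo-absence / presence), both
#'   classes present.
#' @param seed Integer seed for stochastic learners (RF, GBM, ANN).
#' @return Object of class `sdm_member`; predict with [predict_member()].
#' @export
fit_learner <- function(spec, env, response, seed = 1L) {
  x <- as.matrix(env)
  y <- as.integer(response)
  if (length(unique(y)) < 2) stop("single-class response: cannot fit '", spec$name, "'")
  stopifnot(nrow(x) == length(y))
  p <- spec$params
  fit <- extra <- NULL
  set.seed(seed)
  switch(spec$name,
    GLM = {
      df <- as.data.frame(.quad_expand(x))
      df$.y <- y
      fit <- suppressWarnings(stats::glm(.y ~ ., data = df, family = stats::binomial()))
    },
    GAM = {
      df <- as.data.frame(x)
      df$.y <- y
      k <- p$k
      sm <- vapply(colnames(x), function(v) {
        ku <- min(k, length(unique(x[, v])) - 1)
        if (ku >= 3) sprintf("s(%s, k = %d)", v, ku) else v
      }, character(1))
      f <- stats::as.formula(paste(".y ~", paste(sm, collapse = " + ")))
      # convergence chatter on nearly separable folds is expected and benign
      fit <- suppressWarnings(
        mgcv::gam(f, data = df, family = stats::binomial(), method = "REML")
      )
    },
    MARS = {
      extra <- list(knots = .hinge_knots(x, p$knot_probs))
      xf <- .hinge_expand(x, extra$knots)
      fit <- glmnet::glmnet(
        xf, y, family = "binomial", alpha = 0,
        lambda = p$lambda, standardize = TRUE
      )
    },
    CTA = {
      df <- as.data.frame(x)
      df$.y <- factor(y, levels = c(0, 1))
      fit <- rpart::rpart(
        .y ~ ., data = df, method = "class",
        control = rpart::rpart.control(cp = p$cp, minsplit = p$minsplit)
      )
    },
    RF = {
      fit <- randomForest::randomForest(x, factor(y, levels = c(0, 1)), ntree = p$ntree)
    },
    GBM = {
      dtrain <- xgboost::xgb.DMatrix(x, label = y, nthread = 1)
      fit <- xgboost::xgb.train(
        params = list(
          objective = "binary:logistic", max_depth = p$max_depth,
          eta = p$eta, nthread = 1
        ),
        data = dtrain, nrounds = p$nrounds, verbose = 0
      )
    },
    ANN = {
      ctr <- colMeans(x)
      scl <- apply(x, 2, stats::sd)
      scl[scl == 0] <- 1
      xs <- sweep(sweep(x, 2, ctr, "-"), 2, scl, "/")
      extra <- list(center = ctr, scale = scl)
      fit <- nnet::nnet(
        xs, y, size = p$size, decay = p$decay, maxit = p$maxit,
        entropy = TRUE, trace = FALSE
      )
    },
    FDA = {
      xf <- .quad_expand(x)
      keep <- apply(xf, 2, function(v) stats::sd(v) > 0)
      extra <- list(keep = keep)
      fit <- MASS::lda(xf[, keep, drop = FALSE], grouping = factor(y, levels = c(0, 1)))
    },
    MAXENT = {
      extra <- list(knots = .hinge_knots(x, c(0.25, 0.5, 0.75)))
      xf <- cbind(.hinge_expand(x, extra$knots), x^2)
      colnames(xf) <- paste0("f", seq_len(ncol(xf)))
      fit <- glmnet::glmnet(
        xf, y, family = "binomial", alpha = 1,
        lambda = p$lambda, standardize = TRUE
      )
    },
    SRE = {
      pres <- x[y == 1L, , drop = FALSE]
      fit <- list(
        lo = apply(pres, 2, stats::quantile, probs = p$q, names = FALSE),
        hi = apply(pres, 2, stats::quantile, probs = 1 - p$q, names = FALSE)
      )
    },
    stop("unknown algorithm: ", spec$name)
  )
  structure(
    list(name = spec$name, params = p, fit = fit, extra = extra, vars = colnames(x)),
    class = "sdm_member"
  )
}

#' Predict suitability from a fitted member
#'
#' @param member A [fit_learner()] result.
#' @param env Numeric matrix with the training variables as columns.
#' @return Numeric vector of suitabilities in `[0, 1]`.
#' @export
predict_member <- function(member, env) {
  x <- as.matrix(env)[, member$vars, drop = FALSE]
  p <- switch(member$name,
    GLM = stats::predict(member$fit, newdata = as.data.frame(.quad_expand(x)), type = "response"),
    GAM = stats::predict(member$fit, newdata = as.data.frame(x), type = "response"),
    MARS = stats::predict(member$fit, newx = .hinge_expand(x, member$extra$knots), type = "response")[, 1],
    CTA = stats::predict(member$fit, newdata = as.data.frame(x), type = "prob")[, "1"],
    RF = stats::predict(member$fit, newdata = x, type = "prob")[, "1"],
    GBM = stats::predict(member$fit, newdata = xgboost::xgb.DMatrix(x, nthread = 1)),
    ANN = {
      xs <- sweep(sweep(x, 2, member$extra$center, "-"), 2, member$extra$scale, "/")
      stats::predict(member$fit, xs)[, 1]
    },
    FDA = {
      xf <- .quad_expand(x)[, member$extra$keep, drop = FALSE]
      stats::predict(member$fit, xf)$posterior[, "1"]
    },
    MAXENT = {
      xf <- cbind(.hinge_expand(x, member$extra$knots), x^2)
      colnames(xf) <- paste0("f", seq_len(ncol(xf)))
      stats::predict(member$fit, newx = xf, type = "response")[, 1]
    },
    SRE = {
      ok <- rep(TRUE, nrow(x))
      for (j in seq_len(ncol(x))) {
        ok <- ok & x[, j] >= member$fit$lo[j] & x[, j] <= member$fit$hi[j]
      }
      as.numeric(ok)
    },
    stop("unknown algorithm: ", member$name)
  )
  .clamp01(p)
}

# ---- evaluation -------------------------------------------------------------

#' TSS, AUC and the maxTSS threshold
#'
#' AUC is the rank-based (Mann-Whitney) statistic with midrank tie
#' correction: the probability that a random presence outscores a random
#' absence. TSS(threshold) = sensitivity + specificity - 1, with
#' `prediction >= threshold` counting as presence, is evaluated at every
#' candidate threshold (the sorted unique predictions and the midpoints
#' between consecutive ones); the maximum and its (smallest) argmax are
#' returned.
#'
#' @param pred Numeric suitability vector.
#' @param obs Integer 0/1 vector (both classes present).
#' @return List with `tss`, `auc`, `threshold`, `sensitivity`,
#'   `specificity` (the last two at the maxTSS threshold).
#' @export
evaluate_predictions <- function(pred, obs) {
  obs <- as.integer(obs)
  if (length(unique(obs)) < 2) stop("obs must contain both classes")
  stopifnot(length(pred) == length(obs))
  pos <- pred[obs == 1]
  neg <- pred[obs == 0]
  n1 <- length(pos)
  n0 <- length(neg)
  r <- rank(c(pos, neg))
  auc <- (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  u <- sort(unique(pred))
  cand <- sort(unique(c(u, (u[-1] + u[-length(u)]) / 2)))
  sp <- sort(pos)
  sn <- sort(neg)
  lt_pos <- findInterval(cand, sp, left.open = TRUE)   # presences with pred <  t
  lt_neg <- findInterval(cand, sn, left.open = TRUE)   # absences  with pred <  t
  sens <- (n1 - lt_pos) / n1
  spec <- lt_neg / n0
  tss <- sens + spec - 1
  best <- which.max(tss)   # smallest threshold among ties
  list(
    tss = tss[best], auc = auc, threshold = cand[best],
    sensitivity = sens[best], specificity = spec[best]
  )
}

# ---- cross-validation -------------------------------------------------------

# stratified fold assignment: a permutation of 1..folds within each class
.stratified_folds <- function(y, folds) {
  f <- integer(length(y))
  for (cls in unique(y)) {
    ix <- which(y == cls)
    f[ix] <- sample(rep_len(seq_len(folds), length(ix)))
  }
  f
}

#' Replicated stratified cross-validation of the candidate learners
#'
#' Each replicate draws a fresh stratified `folds`-fold partition (classes
#' balanced across folds); each fold trains every learner on the remaining
#' 80% (for the default 5 folds) and scores TSS and AUC on the held-out
#' 20%. Means and standard errors are taken over the
#' `folds * replicates` runs. A learner failing on a fold is recorded as a
#' missing run and excluded from its mean. Deterministic given `seed`.
#'
#' @param specs List of learner specs ([learner_specs()]).
#' @param env Predictor matrix.
#' @param response 0/1 vector.
#' @param folds Folds per replicate (default 5).
#' @param replicates Replicates (default 10).
#' @param seed Integer RNG seed.
#' @return Object of class `cv_scores`: `summary` data.frame (per learner:
#'   `tss_mean`, `tss_se`, `auc_mean`, `auc_se`, `n_runs`, `n_failed`) and
#'   the full `runs` table.
#' @export
cross_validate <- function(specs, env, response, folds = 5, replicates = 10,
                           seed = 1L) {
  x <- as.matrix(env)
  y <- as.integer(response)
  stopifnot(min(table(y)) >= folds)
  runs <- list()
  for (r in seq_len(replicates)) {
    set.seed(seed + 1000L * r)
    fold_id <- .stratified_folds(y, folds)
    for (k in seq_len(folds)) {
      tr <- fold_id != k
      te <- !tr
      for (s in specs) {
        res <- tryCatch(
          {
            m <- fit_learner(s, x[tr, , drop = FALSE], y[tr],
              seed = seed + 1000L * r + 10L * k
            )
            pr <- predict_member(m, x[te, , drop = FALSE])
            ev <- evaluate_predictions(pr, y[te])
            c(tss = ev$tss, auc = ev$auc)
          },
          error = function(e) c(tss = NA_real_, auc = NA_real_)
        )
        runs[[length(runs) + 1L]] <- data.frame(
          learner = s$name, replicate = r, fold = k,
          tss = res[["tss"]], auc = res[["auc"]],
          stringsAsFactors = FALSE
        )
      }
    }
  }
  runs <- do.call(rbind, runs)
  se <- function(v) stats::sd(v) / sqrt(length(v))
  summ <- do.call(rbind, lapply(split(runs, runs$learner), function(d) {
    ok <- !is.na(d$tss)
    data.frame(
      learner = d$learner[1],
      tss_mean = mean(d$tss[ok]), tss_se = se(d$tss[ok]),
      auc_mean = mean(d$auc[ok]), auc_se = se(d$auc[ok]),
      n_runs = sum(ok), n_failed = sum(!ok),
      stringsAsFactors = FALSE
    )
  }))
  ord <- match(vapply(specs, `[[`, character(1), "name"), summ$learner)
  summ <- summ[ord, , drop = FALSE]
  rownames(summ) <- NULL
  structure(list(summary = summ, runs = runs, folds = folds, replicates = replicates),
    class = "cv_scores"
  )
}

#' @export
print.cv_scores <- function(x, ...) {
  cat(sprintf(
    "cv_scores: %d-fold x %d replicates\n", x$folds, x$replicates
  ))
  print(x$summary, digits = 3)
  invisible(x)
}

#' Gate learners on cross-validated TSS and AUC
#'
#' A learner is included iff its mean TSS strictly exceeds `tss_min` and
#' its mean AUC strictly exceeds `auc_min`.
#'
#' @param scores A [cross_validate()] result.
#' @param tss_min,auc_min Gates (defaults 0.7 and 0.8).
#' @return List with `included` (character vector) and `exclusions`
#'   (data.frame naming each excluded learner and its failing statistics).
#' @export
select_members <- function(scores, tss_min = 0.7, auc_min = 0.8) {
  s <- scores$summary
  pass <- !is.na(s$tss_mean) & !is.na(s$auc_mean) &
    s$tss_mean > tss_min & s$auc_mean > auc_min
  excl <- s[!pass, , drop = FALSE]
  reason <- vapply(seq_len(nrow(excl)), function(i) {
    tm <- excl$tss_mean[i]
    am <- excl$auc_mean[i]
    msgs <- c(
      if (is.na(tm) || tm <= tss_min) sprintf("TSS %.3f <= %.2f", tm, tss_min),
      if (is.na(am) || am <= auc_min) sprintf("AUC %.3f <= %.2f", am, auc_min)
    )
    paste(msgs, collapse = "; ")
  }, character(1))
  exclusions <- data.frame(
    learner = excl$learner,
    tss_mean = excl$tss_mean, auc_mean = excl$auc_mean,
    reason = reason,
    stringsAsFactors = FALSE
  )
  if (!any(pass)) {
    stop(
      "no learner passed the gates (TSS > ", tss_min, ", AUC > ", auc_min,
      "); review the thresholds or the data"
    )
  }
  list(included = s$learner[pass], exclusions = exclusions)
}

#' Build the gated, weighted ensemble
#'
#' The included members are refit on the full table; the ensemble
#' prediction is the weighted average of the member predictions, with
#' either equal weights (default) or weights proportional to the members'
#' mean cross-validated TSS.
#'
#' @param included Character vector of gated algorithm names.
#' @param env Full predictor matrix.
#' @param response Full 0/1 vector.
#' @param scores The [cross_validate()] result (needed for
#'   `tss_proportional` weighting and stored as metadata).
#' @param weighting `"equal"` or `"tss_proportional"`.
#' @param seed Integer seed for member refits.
#' @return Object of class `sdm_ensemble` with fields `members`, `weights`,
#'   `weighting`, `gates`, `scores`.
#' @export
build_ensemble <- function(included, env, response, scores = NULL,
                           weighting = c("equal", "tss_proportional"),
                           seed = 1L) {
  weighting <- match.arg(weighting)
  stopifnot(length(included) >= 1)
  specs <- learner_specs(included)
  members <- lapply(specs, fit_learner, env = env, response = response, seed = seed)
  names(members) <- included
  if (weighting == "equal") {
    w <- rep(1 / length(members), length(members))
  } else {
    if (is.null(scores)) stop("tss_proportional weighting needs cv scores")
    tss <- scores$summary$tss_mean[match(included, scores$summary$learner)]
    if (any(is.na(tss) | tss <= 0)) stop("non-positive or missing TSS for a member")
    w <- tss / sum(tss)
  }
  names(w) <- included
  structure(
    list(
      members = members, weights = w, weighting = weighting,
      scores = scores
    ),
    class = "sdm_ensemble"
  )
}

#' @export
print.sdm_ensemble <- function(x, ...) {
  cat(sprintf(
    "sdm_ensemble: %d members (%s), %s weights\n",
    length(x$members), paste(names(x$members), collapse = ", "), x$weighting
  ))
  invisible(x)
}

#' Ensemble suitability prediction
#'
#' @param ensemble A [build_ensemble()] result.
#' @param env Predictor matrix.
#' @return Weighted-average suitability in `[0, 1]` (a convex combination
#'   of the member predictions).
#' @export
predict_ensemble <- function(ensemble, env) {
  stopifnot(inherits(ensemble, "sdm_ensemble"))
  p <- numeric(nrow(as.matrix(env)))
  for (nm in names(ensemble$members)) {
    p <- p + ensemble$weights[[nm]] * predict_member(ensemble$members[[nm]], env)
  }
  p
}

#' Permutation importance of each predictor
#'
#' For each variable, `importance = 1 - cor(pred_original,
#' pred_with_variable_permuted)`, averaged over `n_perm` random shuffles,
#' clipped to `[0, 1]`; the standard error is taken over the shuffles. A
#' variable the ensemble ignores scores ~0. If the ensemble's predictions
#' are constant the importance is defined as 0 with a warning.
#'
#' @param ensemble A [build_ensemble()] result.
#' @param env Predictor matrix (typically the training table).
#' @param n_perm Number of shuffles per variable (default 10).
#' @param seed Integer RNG seed.
#' @return data.frame with `variable`, `importance`, `se`, sorted by
#'   decreasing importance.
#' @export
variable_importance <- function(ensemble, env, n_perm = 10, seed = 1L) {
  x <- as.matrix(env)
  p0 <- predict_ensemble(ensemble, x)
  if (stats::sd(p0) == 0) {
    warning("constant ensemble predictions: importance set to 0 for all variables")
    return(data.frame(
      variable = colnames(x), importance = 0, se = 0,
      stringsAsFactors = FALSE
    ))
  }
  set.seed(seed)
  out <- lapply(colnames(x), function(v) {
    imp <- vapply(seq_len(n_perm), function(k) {
      xp <- x
      xp[, v] <- sample(xp[, v])
      pk <- predict_ensemble(ensemble, xp)
      if (stats::sd(pk) == 0) 1 else 1 - stats::cor(p0, pk)
    }, numeric(1))
    imp <- pmin(pmax(imp, 0), 1)
    data.frame(
      variable = v, importance = mean(imp),
      se = stats::sd(imp) / sqrt(n_perm),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  out <- out[order(-out$importance), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Response curve of the ensemble along one variable
#'
#' Evaluation-strip curve: the variable sweeps a regular grid across its
#' observed range while every other variable is held at its median.
#'
#' @param ensemble A [build_ensemble()] result.
#' @param env Predictor matrix defining the observed ranges and medians.
#' @param variable Variable name.
#' @param n_grid Number of grid points (default 100).
#' @return data.frame with columns `value`, `suitability`.
#' @export
response_curve <- function(ensemble, env, variable, n_grid = 100) {
  x <- as.matrix(env)
  if (!variable %in% colnames(x)) stop("variable '", variable, "' not in table")
  med <- apply(x, 2, stats::median)
  grid <- seq(min(x[, variable]), max(x[, variable]), length.out = n_grid)
  strip <- matrix(rep(med, each = n_grid), nrow = n_grid,
    dimnames = list(NULL, colnames(x))
  )
  strip[, variable] <- grid
  data.frame(value = grid, suitability = predict_ensemble(ensemble, strip))
}
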