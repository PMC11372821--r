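# TSS/AUC evaluation, cross-validation, gating, ensembling, permutation
# importance and response curves.

test_that("evaluation reproduces hand-computed confusion arithmetic", {
  # 50 presences (40 scored 0.9, 10 scored 0.1), 50 absences (45 at 0.1,
  # 5 at 0.9): at the optimum TP 40, FN 10, TN 45, FP 5
  pred <- c(rep(0.9, 40), rep(0.1, 10), rep(0.1, 45), rep(0.9, 5))
  obs <- c(rep(1, 50), rep(0, 50))
  ev <- evaluate_predictions(pred, obs)
  expect_equal(ev$sensitivity, 0.8)
  expect_equal(ev$specificity, 0.9)
  expect_equal(ev$tss, 0.7)
  # pair counting: 40*45 wins + half of (40*5 + 10*45) ties over 2500 pairs
  expect_equal(ev$auc, (40 * 45 + 0.5 * (40 * 5 + 10 * 45)) / 2500)
})

test_that("perfect separation gives TSS = AUC = 1 and chance level gives ~0.5", {
  pred <- c(runif(30, 0.6, 1), runif(30, 0, 0.4))
  obs <- rep(c(1, 0), each = 30)
  ev <- evaluate_predictions(pred, obs)
  expect_equal(ev$tss, 1)
  expect_equal(ev$auc, 1)
  set.seed(123)
  ev0 <- evaluate_predictions(runif(2000), rbinom(2000, 1, 0.5))
  expect_lt(abs(ev0$auc - 0.5), 0.04)
  # a constant prediction has no skill
  expect_equal(evaluate_predictions(rep(0.5, 40), rep(c(0, 1), 20))$tss, 0)
  expect_error(evaluate_predictions(runif(5), rep(1, 5)), "both classes")
})

test_that("maxTSS equals a brute-force threshold scan on 50 random instances", {
  for (i in 1:50) {
    set.seed(i)
    n <- 60
    # round to 3 decimals so plateaus are wider than the scan step
    pred <- round(runif(n), 3)
    obs <- rbinom(n, 1, 0.5)
    if (length(unique(obs)) < 2) obs[1:2] <- c(0L, 1L)
    ev <- evaluate_predictions(pred, obs)
    taus <- seq(0, 1, by = 1e-4)
    tss_scan <- vapply(taus, function(t) {
      sens <- mean(pred[obs == 1] >= t)
      spec <- mean(pred[obs == 0] < t)
      sens + spec - 1
    }, numeric(1))
    expect_equal(ev$tss, max(tss_scan), tolerance = 1e-12)
  }
})

test_that("rank AUC equals trapezoidal ROC integration and pROC on tie-free data", {
  set.seed(99)
  pred <- sample(seq(0.001, 0.999, length.out = 200)) # no ties
  obs <- rbinom(200, 1, plogis(6 * (pred - 0.5)))
  obs[1:2] <- c(0L, 1L)
  ev <- evaluate_predictions(pred, obs)
  expect_equal(ev$auc, trapezoid_auc(pred, obs), tolerance = 1e-9)
  proc <- as.numeric(pROC::auc(pROC::roc(obs, pred, quiet = TRUE, direction = "<")))
  expect_equal(ev$auc, proc, tolerance = 1e-9)
})

test_that("the surface range envelope matches a brute-force per-variable test", {
  tt <- toy_model_table(n = 300, p = 3, seed = 5)
  spec <- learner_specs("SRE")[[1]]
  m <- fit_learner(spec, tt$env, tt$y, seed = 1)
  new <- matrix(rnorm(200 * 3, sd = 2), 200, 3, dimnames = list(NULL, colnames(tt$env)))
  got <- predict_member(m, new)
  pres <- tt$env[tt$y == 1, , drop = FALSE]
  lo <- apply(pres, 2, quantile, probs = 0.025)
  hi <- apply(pres, 2, quantile, probs = 0.975)
  brute <- as.numeric(vapply(
    seq_len(200),
    function(i) all(new[i, ] >= lo & new[i, ] <= hi),
    logical(1)
  ))
  expect_identical(got, brute)
  # q = 0 keeps the full presence range
  spec0 <- spec
  spec0$params$q <- 0
  m0 <- fit_learner(spec0, tt$env, tt$y, seed = 1)
  expect_equal(predict_member(m0, pres), rep(1, nrow(pres)))
})

test_that("every learner fits and predicts within [0, 1]", {
  tt <- toy_model_table(n = 240, p = 4, seed = 7)
  for (spec in learner_specs()) {
    m <- fit_learner(spec, tt$env, tt$y, seed = 3)
    p <- predict_member(m, tt$env)
    expect_length(p, 240)
    expect_true(all(p >= 0 & p <= 1), label = paste(spec$name, "range"))
    # every learner must beat chance on its own training data
    expect_gt(evaluate_predictions(p, tt$y)$auc, 0.6)
  }
  expect_error(
    fit_learner(learner_specs("GLM")[[1]], tt$env, rep(1L, 240)),
    "single-class"
  )
})

test_that("a GLM separates linearly separable toy data perfectly", {
  set.seed(8)
  x <- matrix(rnorm(200), 100, 2, dimnames = list(NULL, c("a", "b")))
  y <- as.integer(x[, 1] > 0)
  m <- fit_learner(learner_specs("GLM")[[1]], x, y, seed = 1)
  expect_equal(evaluate_predictions(predict_member(m, x), y)$auc, 1)
})

test_that("cross-validation is replicated, stratified and deterministic", {
  tt <- toy_model_table(n = 200, p = 3, seed = 11)
  specs <- learner_specs(c("GLM", "SRE", "CTA"))
  cv <- cross_validate(specs, tt$env, tt$y, folds = 5, replicates = 10, seed = 42)
  expect_equal(nrow(cv$runs), 3 * 50)
  expect_true(all(cv$summary$n_runs + cv$summary$n_failed == 50))
  cv2 <- cross_validate(specs, tt$env, tt$y, folds = 5, replicates = 10, seed = 42)
  expect_identical(cv$summary, cv2$summary)
  expect_true(all(cv$summary$auc_mean >= 0 & cv$summary$auc_mean <= 1))
  expect_true(all(cv$summary$tss_mean >= -1 & cv$summary$tss_mean <= 1))
})

test_that("gating respects the strict TSS and AUC thresholds", {
  fake <- structure(list(
    summary = data.frame(
      learner = c("A", "B", "C", "D"),
      tss_mean = c(0.69, 0.75, 0.71, 0.90),
      tss_se = 0.01,
      auc_mean = c(0.90, 0.85, 0.80, 0.95),
      auc_se = 0.01, n_runs = 50, n_failed = 0,
      stringsAsFactors = FALSE
    ),
    runs = NULL, folds = 5, replicates = 10
  ), class = "cv_scores")
  sel <- select_members(fake, tss_min = 0.7, auc_min = 0.8)
  # A fails TSS despite a high AUC; C sits exactly on the AUC gate (strict)
  expect_setequal(sel$included, c("B", "D"))
  expect_setequal(sel$exclusions$learner, c("A", "C"))
  expect_match(sel$exclusions$reason[sel$exclusions$learner == "A"], "TSS")
  expect_match(sel$exclusions$reason[sel$exclusions$learner == "C"], "AUC")
  fake$summary$tss_mean[] <- 0.1
  expect_error(select_members(fake), "no learner")
})

test_that("ensemble weights and predictions follow the stated arithmetic", {
  tt <- toy_model_table(n = 200, p = 3, seed = 13)
  fake <- structure(list(summary = data.frame(
    learner = c("GLM", "CTA"), tss_mean = c(0.8, 0.72), tss_se = 0.01,
    auc_mean = c(0.9, 0.9), auc_se = 0.01, n_runs = 50, n_failed = 0,
    stringsAsFactors = FALSE
  )), class = "cv_scores")
  ens_eq <- build_ensemble(c("GLM", "CTA"), tt$env, tt$y, scores = fake, seed = 2)
  expect_equal(unname(ens_eq$weights), c(0.5, 0.5))
  ens_w <- build_ensemble(c("GLM", "CTA"), tt$env, tt$y,
    scores = fake, weighting = "tss_proportional", seed = 2
  )
  expect_equal(unname(ens_w$weights), c(0.8, 0.72) / 1.52, tolerance = 1e-12)
  expect_equal(unname(ens_w$weights[1]), 0.5263, tolerance = 1e-4)
  # prediction is the weighted member average, exactly
  p_members <- vapply(
    ens_eq$members, predict_member, numeric(200), env = tt$env
  )
  expect_equal(predict_ensemble(ens_eq, tt$env), rowMeans(p_members), tolerance = 1e-12)
  # single-member ensemble is that member
  ens1 <- build_ensemble("GLM", tt$env, tt$y, seed = 2)
  expect_equal(
    predict_ensemble(ens1, tt$env),
    predict_member(ens1$members$GLM, tt$env),
    tolerance = 1e-12
  )
  # convex combination: bounded by member extremes
  pmin_ <- apply(p_members, 1, min)
  pmax_ <- apply(p_members, 1, max)
  pe <- predict_ensemble(ens_eq, tt$env)
  expect_true(all(pe >= pmin_ - 1e-12 & pe <= pmax_ + 1e-12))
})

test_that("permutation importance isolates the driving variable", {
  set.seed(15)
  n <- 1000
  env <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("driver", "noise1", "noise2")))
  y <- rbinom(n, 1, plogis(3 * env[, "driver"]))
  y[1:2] <- c(0L, 1L)
  ens <- build_ensemble(c("GLM", "RF"), env, y, seed = 4)
  imp <- variable_importance(ens, env, n_perm = 10, seed = 5)
  expect_equal(imp$variable[1], "driver")
  expect_lt(max(imp$importance[imp$variable != "driver"]), 0.05)
  # a model that provably ignores a variable scores exactly zero on it:
  # the SRE envelope of a variable spanning all observed values never fires
  env2 <- cbind(env, wide = runif(n))
  ens_sre <- build_ensemble("SRE", env2, y, seed = 6)
  ens_sre$members$SRE$fit$lo["wide"] <- -Inf
  ens_sre$members$SRE$fit$hi["wide"] <- Inf
  imp2 <- variable_importance(ens_sre, env2, n_perm = 5, seed = 7)
  expect_equal(imp2$importance[imp2$variable == "wide"], 0)
})

test_that("response curves are flat for ignored variables and monotone for logistic truth", {
  set.seed(18)
  n <- 2000
  env <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("x", "ignored")))
  y <- rbinom(n, 1, plogis(1.5 * env[, "x"]))
  y[1:2] <- c(0L, 1L)
  ens <- build_ensemble("GLM", env, y, seed = 3)
  # a model that structurally ignores a variable has an exactly flat curve
  ens_sre <- build_ensemble("SRE", env, y, seed = 3)
  ens_sre$members$SRE$fit$lo["ignored"] <- -Inf
  ens_sre$members$SRE$fit$hi["ignored"] <- Inf
  rc_flat <- response_curve(ens_sre, env, "ignored")
  expect_lt(diff(range(rc_flat$suitability)), 1e-6)
  rc_x <- response_curve(ens, env, "x", n_grid = 100)
  expect_equal(nrow(rc_x), 100)
  # a monotone logistic truth yields a monotone fitted curve
  expect_true(all(diff(rc_x$suitability) > -1e-6))
  expect_lt(rc_x$suitability[1], 0.15)
  expect_gt(rc_x$suitability[100], 0.85)
  expect_error(response_curve(ens, env, "nope"), "not in table")
})
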