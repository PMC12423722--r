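# Multivariable regressions, oversampling, general and hierarchical
# models, leave-one-participant-out validation, feature importance.

test_that("multivariable regression recovers planted coefficients exactly", {
  set.seed(61)
  n <- 20
  df <- data.frame(age = runif(n, 30, 80), SI = runif(n, 40, 90),
                   M = sample(180:220, n, replace = TRUE))
  x <- df$SI / df$M^(1 / 3)
  pwv <- 10 * df$age - 2 * x + 500
  fit <- fit_multivariable(df, pwv, "si")
  expect_lt(max(abs(coef(fit) - c(C1 = 10, C2 = -2, C3 = 500)) /
                c(10, 2, 500)), 1e-6)
  expect_equal(as.numeric(predict(fit, df)), as.numeric(pwv), tolerance = 1e-6)

  # P2O variant
  df$P2O <- runif(n, 100, 160)
  pwv2 <- -4 * df$age + 300 * (df$P2O / df$M) + 1500
  fit2 <- fit_multivariable(df, pwv2, "p2o")
  expect_lt(max(abs(coef(fit2) - c(C1 = -4, C2 = 300, C3 = 1500)) /
                c(4, 300, 1500)), 1e-6)

  df$age <- 50                                # constant regressor
  expect_error(fit_multivariable(df, pwv, "si"), "rank")
})

test_that("multivariable estimates are unbiased under noise", {
  set.seed(62)
  reps <- 100; n <- 200
  c1 <- matrix(NA_real_, reps, 3)
  for (r in seq_len(reps)) {
    df <- data.frame(age = runif(n, 30, 80), SI = runif(n, 40, 90),
                     M = sample(180:220, n, replace = TRUE))
    x <- df$SI / df$M^(1 / 3)
    pwv <- 10 * df$age - 2 * x + 500 + rnorm(n, 0, 100)
    c1[r, ] <- coef(fit_multivariable(df, pwv, "si"))
  }
  bias <- colMeans(c1) - c(10, -2, 500)
  se <- apply(c1, 2, sd) / sqrt(reps)
  expect_true(all(abs(bias) <= 2 * se))
})

test_that("oversampling balances every non-empty 100 cm/s bin", {
  train <- data.frame(pwv = c(rep(1050, 3), rep(1150, 5), rep(1250, 2)),
                      x = 1:10)
  bal <- oversample_bins(train, seed = 3)
  counts <- table(floor(bal$pwv / 100))
  expect_true(all(counts == 5))
  expect_equal(sum(!bal$.oversampled), 10)     # originals all retained
  # already balanced: unchanged
  even <- data.frame(pwv = c(1050, 1150, 1250), x = 1:3)
  expect_equal(nrow(oversample_bins(even, seed = 1)), 3)
  single <- data.frame(pwv = rep(1450, 4), x = 1:4)
  expect_equal(nrow(oversample_bins(single, seed = 1)), 4)
})

test_that("the general boosted model learns, overfits in-sample, repeats", {
  co <- synth_feature_cohort(seed = 71)
  sp <- split_cohort(co, seed = 71)
  fit <- fit_general(sp$train, model_features, seed = 71,
                     test_ids = sp$test$participant_id)
  expect_lt(rmse_of(fit, sp$test), stats::sd(sp$test$pwv))
  expect_lte(rmse_of(fit, sp$train), rmse_of(fit, sp$test))
  fit2 <- fit_general(sp$train, model_features, seed = 71)
  expect_identical(as.numeric(predict(fit, sp$test)),
                   as.numeric(predict(fit2, sp$test)))
  expect_error(fit_general(sp$train, character(0)), "empty")
})

test_that("overlap-zone semantics match the printed validation ranges", {
  co <- synth_feature_cohort(seed = 72)
  sp <- split_cohort(co, seed = 72)
  fit <- fit_hierarchical(sp$train, model_features, tau = 1600, W = 400,
                          seed = 72)
  expect_equal(unname(fit$ranges["low_max"]), 1800)
  expect_equal(unname(fit$ranges["high_min"]), 1400)
  # W = 0: disjoint ranges at the boundary
  fit0 <- fit_hierarchical(sp$train, model_features, tau = 1600, W = 0,
                           seed = 72)
  expect_equal(unname(fit0$ranges["low_max"]), 1600)
  expect_equal(unname(fit0$ranges["high_min"]), 1600)
  # a measurement at 1500 trains BOTH submodels when W = 400
  tr <- sp$train
  tr$pwv[1] <- 1500
  fit4 <- fit_hierarchical(tr, model_features, tau = 1600, W = 400, seed = 72)
  expect_true(1500 <= fit4$ranges["low_max"] && 1500 >= fit4$ranges["high_min"])
  low_rows <- tr$pwv <= 1800; high_rows <- tr$pwv >= 1400
  expect_true(low_rows[1] && high_rows[1])
  expect_error(fit_hierarchical(sp$train[1:6, ], model_features, W = 400,
                                seed = 1), "fewer than 5")
})

test_that("prediction routes hard by the classifier vote", {
  co <- synth_feature_cohort(seed = 73)
  sp <- split_cohort(co, seed = 73)
  fit <- fit_hierarchical(sp$train, model_features, seed = 73)
  pred <- predict(fit, sp$test)
  routed <- attr(pred, "class_routed")
  m <- as.matrix(sp$test[, fit$features])
  storage.mode(m) <- "double"
  p_low <- as.numeric(predict(fit$low, m))
  p_high <- as.numeric(predict(fit$high, m))
  expect_equal(as.numeric(pred),
               ifelse(routed == "low", p_low, p_high))
  # requesting prediction without the model features errors informatively
  expect_error(predict(fit, sp$test[, c("pwv", "age")]), "missing")
})

test_that("misrouted boundary samples stay inside the overlap coverage", {
  # pooled over seeds: misrouted low-range samples handed to the high
  # submodel (trained from 1400 with W=400) err at most ~2x the matched
  # correctly-routed samples
  err_mis <- c(); err_ok <- c()
  for (s in 1:10) {
    co <- synth_feature_cohort(seed = s)
    sp <- split_cohort(co, seed = s)
    fit <- fit_hierarchical(oversample_bins(sp$train, seed = s),
                            model_features, W = 400, seed = s)
    band <- synth_feature_cohort(n_participants = 30, rounds_per_participant = 2,
                                 pwv_range = c(1450, 1600), seed = 9000 + s)
    pred <- predict(fit, band)
    mis <- attr(pred, "class_routed") == "high"      # true class is low
    e <- abs(band$pwv - as.numeric(pred))
    err_mis <- c(err_mis, e[mis]); err_ok <- c(err_ok, e[!mis])
  }
  expect_gt(length(err_mis), 10)                     # misrouting does occur
  expect_lte(mean(err_mis), 2 * mean(err_ok))
})

test_that("leave-one-out validation refits once per participant and is
           deterministic over duplicate grid points", {
  co <- synth_feature_cohort(n_participants = 6, rounds_per_participant = 3,
                             seed = 74)
  grid <- data.frame(num_trees = c(50, 50), clf_depth = c(5, 5),
                     xgb_depth = c(3, 3))
  out <- loo_validate(co, model_features, grid, model = "general", seed = 74)
  # duplicate grid points: identical pooled errors, first chosen
  expect_equal(out$rmse[1], out$rmse[2])
  expect_equal(out$best_index, 1)
  expect_length(out$per_participant, 6)              # one refit per participant

  expect_error(loo_validate(co, model_features, grid[0, ], seed = 1), "empty")
  few <- co[co$participant_id %in% unique(co$participant_id)[1:3], ]
  expect_error(loo_validate(few, model_features, grid, seed = 1),
               "6 participants")
})

test_that("feature importance is normalized and finds the informative feature", {
  set.seed(75)
  n <- 300
  df <- data.frame(participant_id = rep(sprintf("P%02d", 1:30), each = 10),
                   good = runif(n), junk1 = runif(n), junk2 = runif(n))
  df$pwv <- 1000 + 1200 * df$good + rnorm(n, 0, 20)
  fit <- fit_hierarchical(df, c("good", "junk1", "junk2"), seed = 75)
  imp <- feature_importance(fit)
  for (comp in c("classifier", "low", "high")) {
    expect_equal(sum(imp[[comp]]$importance), 1, tolerance = 1e-9)
    expect_equal(imp[[comp]]$feature[1], "good")
  }
  expect_error(feature_importance(structure(list(), class = "lm")),
               "unfitted|unsupported")
})

test_that("participant splits are asserted on every fit path", {
  co <- synth_feature_cohort(seed = 76)
  sp <- split_cohort(co, seed = 76)
  leaky <- sp$test$participant_id[1]
  expect_error(fit_general(sp$train, model_features, seed = 1,
                           test_ids = c(leaky, sp$train$participant_id[1])),
               "participant-split")
  expect_error(fit_hierarchical(sp$train, model_features, seed = 1,
                                test_ids = sp$train$participant_id[1]),
               "participant-split")
  expect_silent(check_participant_split(c("a", "b"), c("c")))
})
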