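# Estimation models: multivariable baseline regressions, a general
# boosted-tree regressor, and the hierarchical classify-then-regress model
# with overlapping training zones; training utilities (participant-split
# checks, bin oversampling, leave-one-participant-out validation, feature
# importance).

#' Assert participant-disjoint data splits
#'
#' @param train_ids,test_ids participant identifier vectors.
#' @return TRUE invisibly; error when the sets intersect.
#' @export
check_participant_split <- function(train_ids, test_ids) {
  common <- intersect(unique(train_ids), unique(test_ids))
  if (length(common))
    stop("participant-split violated: ", paste(common, collapse = ", "))
  invisible(TRUE)
}

#' Fit a multivariable baseline regression
#'
#' Ordinary least squares of PWV on age and one pulse-shape predictor:
#' variant `"si"` uses the Fridericia-corrected stiffness index
#' `SI / M^(1/3)`, variant `"p2o"` uses the pulse-length-normalized
#' systolic-peak-to-onset interval `P2O / M`. The model is
#' `PWV = C1 * Age + C2 * x + C3`.
#'
#' @param features data.frame with columns `age`, `M`, and `SI` or `P2O`.
#' @param pwv reference PWV values (cm/s).
#' @param variant `"si"` (default) or `"p2o"`.
#' @return object of class `pwv_mvreg` wrapping the [stats::lm] fit with
#'   coefficients `C1`, `C2`, `C3`.
#' @export
fit_multivariable <- function(features, pwv, variant = c("si", "p2o")) {
  variant <- match.arg(variant)
  stopifnot(nrow(features) == length(pwv))
  if (length(pwv) < 3) stop("need at least 3 measurements")
  x <- switch(variant,
              si = features$SI / features$M^(1 / 3),
              p2o = features$P2O / features$M)
  df <- data.frame(pwv = pwv, age = features$age, x = x)
  df <- df[stats::complete.cases(df), ]
  if (nrow(df) < 3) stop("fewer than 3 complete measurements")
  fit <- stats::lm(pwv ~ age + x, data = df)
  if (any(is.na(stats::coef(fit)))) stop("rank-deficient design")
  structure(list(fit = fit,
                 coefficients = c(C1 = unname(stats::coef(fit)["age"]),
                                  C2 = unname(stats::coef(fit)["x"]),
                                  C3 = unname(stats::coef(fit)["(Intercept)"])),
                 variant = variant, n = nrow(df)), class = "pwv_mvreg")
}

#' @export
coef.pwv_mvreg <- function(object, ...) object$coefficients

#' @export
print.pwv_mvreg <- function(x, ...) {
  lab <- switch(x$variant, si = "SI/M^(1/3)", p2o = "P2O/M")
  cat(sprintf("Multivariable PWV regression (n = %d):\n", x$n))
  cat(sprintf("  PWV = %.4g * Age + %.4g * %s + %.4g\n",
              x$coefficients["C1"], x$coefficients["C2"], lab,
              x$coefficients["C3"]))
  invisible(x)
}

#' @export
predict.pwv_mvreg <- function(object, newdata, ...) {
  x <- switch(object$variant,
              si = newdata$SI / newdata$M^(1 / 3),
              p2o = newdata$P2O / newdata$M)
  as.numeric(stats::predict(object$fit,
                            data.frame(age = newdata$age, x = x)))
}

#' Oversample PWV bins to a balanced training distribution
#'
#' Duplicates rows (sampling with replacement, fixed seed) so that every
#' non-empty `bin_width` cm/s PWV bin reaches the count of the largest
#' bin; the original rows are all retained and duplicates are tagged in
#' column `.oversampled`.
#'
#' @param train data.frame with a `pwv` column.
#' @param bin_width bin width in cm/s (default 100).
#' @param seed integer seed for the duplicate draw.
#' @return the balanced data.frame.
#' @export
oversample_bins <- function(train, bin_width = 100, seed = 1) {
  stopifnot(nrow(train) > 0, "pwv" %in% names(train))
  bins <- floor(train$pwv / bin_width)
  counts <- table(bins)
  target <- max(counts)
  set.seed(as.integer(seed))
  out <- train
  out$.oversampled <- FALSE
  extra <- list()
  for (b in names(counts)) {
    need <- target - counts[[b]]
    if (need > 0) {
      rows <- which(bins == as.numeric(b))
      pick <- rows[sample.int(length(rows), need, replace = TRUE)]
      add <- train[pick, , drop = FALSE]
      add$.oversampled <- TRUE
      extra[[b]] <- add
    }
  }
  if (length(extra)) out <- rbind(out, do.call(rbind, extra))
  rownames(out) <- NULL
  out
}

# Feature-matrix helper: numeric matrix of the model features.
.model_matrix <- function(data, features) {
  miss <- setdiff(features, names(data))
  if (length(miss)) stop("missing model features: ", paste(miss, collapse = ", "))
  m <- as.matrix(data[, features, drop = FALSE])
  storage.mode(m) <- "double"
  m
}

#' Boosted-tree hyperparameters
#'
#' Defaults mirror the reported regressor settings: 200 estimators,
#' column subsampling 0.7, minimum loss reduction 0, depth 3 (5 for the
#' low submodel profile), learning rate 0.1.
#'
#' @param nrounds,max_depth,colsample_bytree,gamma,eta see [xgboost::xgboost].
#' @return parameter list.
#' @export
xgb_params <- function(nrounds = 200, max_depth = 3, colsample_bytree = 0.7,
                       gamma = 0, eta = 0.1) {
  list(nrounds = nrounds, max_depth = max_depth,
       colsample_bytree = colsample_bytree, gamma = gamma, eta = eta)
}

#' Random-forest hyperparameters
#'
#' Defaults mirror the reported classifier settings: 100 trees, maximum
#' depth 20, minimum node size to split 3, i.e. a split needs more than
#' 2 samples (the 250-tree / depth-9 profile is the reported alternative).
#'
#' @param num_trees,max_depth,min_node_size see [ranger::ranger].
#' @return parameter list.
#' @export
rf_params <- function(num_trees = 100, max_depth = 20, min_node_size = 3) {
  list(num_trees = num_trees, max_depth = max_depth,
       min_node_size = min_node_size)
}

.fit_xgb <- function(data, features, params, seed) {
  set.seed(as.integer(seed))
  dtrain <- xgboost::xgb.DMatrix(.model_matrix(data, features),
                                 label = data$pwv, nthread = 1)
  xgboost::xgb.train(
    params = list(max_depth = params$max_depth,
                  colsample_bytree = params$colsample_bytree,
                  gamma = params$gamma, eta = params$eta,
                  objective = "reg:squarederror",
                  nthread = 1, seed = as.integer(seed)),
    data = dtrain, nrounds = params$nrounds, verbose = 0)
}

#' Fit the general boosted-tree regression model
#'
#' One XGBoost regressor over the whole PWV range (the comparison model
#' for the hierarchical estimator). Deterministic given the seed.
#'
#' @param train data.frame with feature columns, `pwv` and
#'   `participant_id`.
#' @param features character vector of feature column names.
#' @param params [xgb_params()].
#' @param seed integer seed.
#' @param test_ids optional participant ids of the evaluation set; the
#'   participant split is asserted when given.
#' @return object of class `pwv_xgb`.
#' @export
fit_general <- function(train, features, params = xgb_params(), seed = 1,
                        test_ids = NULL) {
  if (length(features) == 0) stop("empty feature set")
  if (!is.null(test_ids)) check_participant_split(train$participant_id, test_ids)
  booster <- .fit_xgb(train, features, params, seed)
  structure(list(booster = booster, features = features, params = params,
                 seed = seed, n = nrow(train)), class = "pwv_xgb")
}

#' @export
predict.pwv_xgb <- function(object, newdata, ...) {
  as.numeric(stats::predict(object$booster,
                            .model_matrix(newdata, object$features)))
}

#' @export
print.pwv_xgb <- function(x, ...) {
  cat(sprintf("General XGBoost PWV regressor: %d rounds, depth %d, n = %d\n",
              x$params$nrounds, x$params$max_depth, x$n))
  invisible(x)
}

#' Fit the hierarchical classify-then-regress model
#'
#' A global random-forest classifier assigns each measurement to the low
#' or high PWV subdivision (boundary `tau`); subdivision-specific XGBoost
#' regressors are trained on ranges extended symmetrically by the
#' overlapping zone: low on `pwv <= tau + W/2`, high on
#' `pwv >= tau - W/2`, so misclassified measurements near the boundary
#' remain inside the training range of the regressor that receives them.
#'
#' @param train data.frame with feature columns, `pwv`, `participant_id`.
#' @param features character vector of feature column names.
#' @param tau subdivision boundary in cm/s (default 1600).
#' @param W overlapping-zone width in cm/s (default 400; 0, 200, 400 and
#'   600 are the studied settings).
#' @param clf_params [rf_params()].
#' @param reg_params_low,reg_params_high [xgb_params()]; the low-submodel
#'   default depth is 5 and the high-submodel default 3.
#' @param seed integer seed.
#' @param test_ids optional evaluation participant ids (split asserted).
#' @return object of class `pwv_hier`.
#' @export
fit_hierarchical <- function(train, features, tau = 1600, W = 400,
                             clf_params = rf_params(),
                             reg_params_low = xgb_params(max_depth = 5),
                             reg_params_high = xgb_params(max_depth = 3),
                             seed = 1, test_ids = NULL) {
  stopifnot(W >= 0)
  if (!is.null(test_ids)) check_participant_split(train$participant_id, test_ids)
  low_rows <- train[train$pwv <= tau + W / 2, , drop = FALSE]
  high_rows <- train[train$pwv >= tau - W / 2, , drop = FALSE]
  if (nrow(low_rows) < 5 || nrow(high_rows) < 5)
    stop("a submodel training range holds fewer than 5 measurements")
  cls <- factor(ifelse(train$pwv < tau, "low", "high"), levels = c("low", "high"))
  clf_df <- data.frame(.cls = cls, train[, features, drop = FALSE])
  classifier <- ranger::ranger(
    dependent.variable.name = ".cls", data = clf_df,
    num.trees = clf_params$num_trees, max.depth = clf_params$max_depth,
    min.node.size = clf_params$min_node_size,
    importance = "impurity", probability = FALSE,
    seed = as.integer(seed), num.threads = 1)
  low_reg <- .fit_xgb(low_rows, features, reg_params_low, seed)
  high_reg <- .fit_xgb(high_rows, features, reg_params_high, seed + 1)
  structure(list(classifier = classifier, low = low_reg, high = high_reg,
                 features = features, tau = tau, W = W,
                 clf_params = clf_params,
                 reg_params = list(low = reg_params_low, high = reg_params_high),
                 ranges = c(low_max = tau + W / 2, high_min = tau - W / 2),
                 n = nrow(train), seed = seed), class = "pwv_hier")
}

#' Predict PWV with the hierarchical model
#'
#' The global classifier routes each measurement (majority vote) and the
#' associated local regressor produces the estimate; no blending by
#' default.
#'
#' @param object a `pwv_hier` model.
#' @param newdata data.frame carrying the model features.
#' @param blend when TRUE, weight the two submodel predictions by the
#'   forest's class probabilities instead of hard routing.
#' @param ... ignored.
#' @return numeric PWV estimates (cm/s) with attribute `class` (the
#'   routed subdivision per row).
#' @export
predict.pwv_hier <- function(object, newdata, blend = FALSE, ...) {
  m <- .model_matrix(newdata, object$features)  # errors list missing features
  pred_low <- as.numeric(stats::predict(object$low, m))
  pred_high <- as.numeric(stats::predict(object$high, m))
  cls_pred <- stats::predict(object$classifier,
                             data = as.data.frame(newdata[, object$features,
                                                          drop = FALSE]))
  if (blend) {
    votes <- .rf_vote_fraction(object$classifier, newdata, object$features)
    out <- votes * pred_low + (1 - votes) * pred_high
    routed <- ifelse(votes >= 0.5, "low", "high")
  } else {
    routed <- as.character(cls_pred$predictions)
    out <- ifelse(routed == "low", pred_low, pred_high)
  }
  attr(out, "class_routed") <- routed
  out
}

# Fraction of trees voting "low".
.rf_vote_fraction <- function(classifier, newdata, features) {
  pa <- stats::predict(classifier,
                       data = as.data.frame(newdata[, features, drop = FALSE]),
                       predict.all = TRUE)$predictions
  lv <- 1  # "low" is level 1
  rowMeans(pa == lv)
}

#' @export
print.pwv_hier <- function(x, ...) {
  cat(sprintf("Hierarchical PWV model: tau = %g cm/s, overlap W = %g cm/s\n",
              x$tau, x$W))
  cat(sprintf("  low submodel trained on pwv <= %g, high on pwv >= %g (n = %d)\n",
              x$ranges["low_max"], x$ranges["high_min"], x$n))
  invisible(x)
}

#' @export
summary.pwv_hier <- function(object, ...) {
  imp <- feature_importance(object)
  cat(sprintf("Hierarchical PWV model (tau = %g, W = %g)\n", object$tau, object$W))
  for (comp in names(imp)) {
    top <- utils::head(imp[[comp]], 5)
    cat(sprintf("  top features, %s: %s\n", comp,
                paste(sprintf("%s (%.2f)", top$feature, top$importance),
                      collapse = ", ")))
  }
  invisible(imp)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Feature importance of a fitted model
#'
#' Normalized (sum 1) importance scores: impurity importance for the
#' forest classifier, gain for the boosted regressors; per component for
#' hierarchical models.
#'
#' @param model a `pwv_hier` or `pwv_xgb`.
#' @return named list of data.frames (`feature`, `importance`), ranked.
#' @export
feature_importance <- function(model) {
  norm_rank <- function(v) {
    v <- v / sum(v)
    data.frame(feature = names(v), importance = as.numeric(v),
               row.names = NULL)[order(-v), ]
  }
  xgb_imp <- function(booster, features) {
    tab <- xgboost::xgb.importance(model = booster)
    v <- stats::setNames(rep(0, length(features)), features)
    v[tab$Feature] <- tab$Gain
    if (sum(v) == 0) v[] <- 1 / length(v)
    norm_rank(v)
  }
  if (inherits(model, "pwv_hier")) {
    vi <- model$classifier$variable.importance
    vi[vi < 0] <- 0
    list(classifier = norm_rank(vi),
         low = xgb_imp(model$low, model$features),
         high = xgb_imp(model$high, model$features))
  } else if (inherits(model, "pwv_xgb")) {
    list(regressor = xgb_imp(model$booster, model$features))
  } else stop("unfitted or unsupported model")
}

#' Leave-one-participant-out validation over a parameter grid
#'
#' For each grid point, every participant is held out in turn: all their
#' measurements are removed from fitting and predicted by a model trained
#' on the rest; the grid point minimizing pooled RMSE wins. Ties prefer
#' the smaller model (fewer trees, then shallower).
#'
#' @param train data.frame with features, `pwv`, `participant_id`.
#' @param features feature column names.
#' @param grid data.frame of candidate settings with columns among
#'   `num_trees`, `clf_depth`, `xgb_depth`, `eta`.
#' @param model `"hierarchical"` (default) or `"general"`.
#' @param tau,W hierarchical settings.
#' @param seed integer seed.
#' @return list with `best` (the chosen grid row), `rmse` (per grid
#'   point) and `per_participant` (validation errors of the best point).
#' @export
loo_validate <- function(train, features, grid, model = "hierarchical",
                         tau = 1600, W = 400, seed = 1) {
  if (nrow(grid) == 0) stop("empty parameter grid")
  parts <- unique(train$participant_id)
  if (length(parts) < 6) stop("need >= 6 participants for leave-one-out validation")
  rmse <- numeric(nrow(grid))
  per_part <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    row <- grid[g, , drop = FALSE]
    errs <- numeric(0); perr <- numeric(length(parts))
    for (pi in seq_along(parts)) {
      held <- train$participant_id == parts[pi]
      tr <- train[!held, , drop = FALSE]
      te <- train[held, , drop = FALSE]
      fit <- tryCatch({
        if (model == "hierarchical") {
          fit_hierarchical(tr, features, tau = tau, W = W,
            clf_params = rf_params(num_trees = row$num_trees %||% 100,
                                   max_depth = row$clf_depth %||% 20),
            reg_params_low = xgb_params(max_depth = row$xgb_depth %||% 5,
                                        eta = row$eta %||% 0.1),
            reg_params_high = xgb_params(max_depth = row$xgb_depth %||% 3,
                                         eta = row$eta %||% 0.1),
            seed = seed, test_ids = te$participant_id)
        } else {
          fit_general(tr, features,
                      params = xgb_params(max_depth = row$xgb_depth %||% 3,
                                          eta = row$eta %||% 0.1),
                      seed = seed, test_ids = te$participant_id)
        }
      }, error = function(e) NULL)
      if (is.null(fit)) { perr[pi] <- NA; next }
      e <- te$pwv - as.numeric(predict(fit, te))
      errs <- c(errs, e)
      perr[pi] <- sqrt(mean(e^2))
    }
    rmse[g] <- sqrt(mean(errs^2))
    per_part[[g]] <- stats::setNames(perr, parts)
  }
  size <- (grid$num_trees %||% rep(0, nrow(grid))) * 1e3 +
    (grid$xgb_depth %||% rep(0, nrow(grid)))
  best <- order(rmse, size)[1]
  list(best = grid[best, , drop = FALSE], best_index = best, rmse = rmse,
       per_participant = per_part[[best]])
}
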