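# shared constructor for fitted pKa regressors
new_pka_regressor <- function(algorithm, fit, columns, hyperparams,
                              metrics, extra = list()) {
  structure(c(list(algorithm = algorithm, fit = fit, columns = columns,
                   hyperparams = hyperparams, metrics = metrics), extra),
            class = "pka_regressor")
}

#' @export
print.pka_regressor <- function(x, ...) {
  cat(sprintf("pka_regressor [%s]: %d features\n", x$algorithm,
              length(x$columns)))
  m <- x$metrics
  cat(sprintf("  train R2 %.3f RMSE %.3f | CV Q2 %.3f RMSE %.3f\n",
              m$r2_fit, m$rmse_fit, m$q2_cv, m$rmse_cv))
  invisible(x)
}

as_feature_matrix <- function(fm) {
  m <- if (inherits(fm, "pka_features")) fm$values else fm
  stopifnot(is.matrix(m))
  m
}

check_target <- function(y, n) {
  stopifnot(is.numeric(y), length(y) == n)
  if (anyNA(y)) stop("missing target values")
  if (stats::var(y) == 0) stop("degenerate single-valued target")
  invisible(y)
}

# out-of-fold predictions for an arbitrary fit/predict pair
oof_predictions <- function(x, y, folds, fit_fun, predict_fun) {
  pred <- rep(NA_real_, length(y))
  for (f in sort(unique(folds))) {
    te <- folds == f
    mod <- fit_fun(x[!te, , drop = FALSE], y[!te])
    pred[te] <- predict_fun(mod, x[te, , drop = FALSE])
  }
  pred
}

#' Train an epsilon-regression SVM pKa model
#'
#' LibSVM epsilon-regression (RBF kernel) with cost, gamma and epsilon
#' tuned by grid search on cross-validated RMSE. The cross-validated Q2
#' and RMSE of the winning combination are computed from its out-of-fold
#' predictions; the model is then refit on all training rows.
#'
#' @param fm Training features (`pka_features` or matrix); binary
#'   fingerprints plus fragment counts is the best-performing choice.
#' @param y Numeric pKa targets.
#' @param cv_folds Number of cross-validation folds (default 5).
#' @param cost_grid,gamma_grid,epsilon_grid Hyperparameter grids.
#' @param seed Integer seed controlling fold assignment.
#' @return A `pka_regressor` (algorithm `"svm"`).
#' @export
train_svm <- function(fm, y, cv_folds = 5L,
                      cost_grid = 2^seq(-2, 10, by = 2),
                      gamma_grid = 2^seq(-10, 2, by = 2),
                      epsilon_grid = c(0.01, 0.1, 0.5),
                      seed = 1L) {
  x <- as_feature_matrix(fm)
  check_target(y, nrow(x))
  folds <- make_folds(nrow(x), cv_folds, seed = derive_seed(seed, "svm"))
  grid <- expand.grid(cost = cost_grid, gamma = gamma_grid,
                      epsilon = epsilon_grid)
  best <- NULL
  for (g in seq_len(nrow(grid))) {
    pred <- oof_predictions(x, y, folds,
      function(xt, yt) e1071::svm(xt, yt, type = "eps-regression",
                                  kernel = "radial", cost = grid$cost[g],
                                  gamma = grid$gamma[g],
                                  epsilon = grid$epsilon[g], scale = FALSE),
      function(m, xt) as.numeric(stats::predict(m, xt)))
    rmse <- sqrt(mean((y - pred)^2))
    if (is.null(best) || rmse < best$rmse) {
      best <- list(rmse = rmse, pred = pred, params = grid[g, ])
    }
  }
  cv <- compute_metrics(y, best$pred)
  fit <- e1071::svm(x, y, type = "eps-regression", kernel = "radial",
                    cost = best$params$cost, gamma = best$params$gamma,
                    epsilon = best$params$epsilon, scale = FALSE)
  train_pred <- as.numeric(stats::predict(fit, x))
  tr <- compute_metrics(y, train_pred)
  new_pka_regressor("svm", fit, colnames(x),
                    as.list(best$params),
                    list(r2_fit = tr$r2, rmse_fit = tr$rmse,
                         q2_cv = cv$r2, rmse_cv = cv$rmse,
                         n = length(y)))
}

#' Train a gradient-boosted pKa model
#'
#' Boosted linear model (default) or trees via xgboost, tuned on
#' repeated cross-validated RMSE (five folds, repeated; the classical
#' setup is 5 x 5). Operates on a reduced feature matrix (D1-D3).
#' Variable importance is exposed in `$importance`.
#'
#' @param fm Training features (`pka_features` or matrix).
#' @param y Numeric pKa targets.
#' @param cv_folds,cv_repeats Cross-validation controls (defaults 5, 5).
#' @param booster `"gblinear"` or `"gbtree"`.
#' @param nrounds Boosting rounds (default 150).
#' @param lambda_grid,alpha_grid L2/L1 regularization grids (gblinear).
#' @param seed Integer seed.
#' @return A `pka_regressor` (algorithm `"xgb"`).
#' @export
train_xgb <- function(fm, y, cv_folds = 5L, cv_repeats = 5L,
                      booster = c("gblinear", "gbtree"), nrounds = 150L,
                      lambda_grid = c(0, 0.1, 1), alpha_grid = c(0, 0.1),
                      seed = 1L) {
  x <- as_feature_matrix(fm)
  check_target(y, nrow(x))
  booster <- match.arg(booster)
  grid <- expand.grid(lambda = lambda_grid, alpha = alpha_grid)
  if (booster == "gbtree") grid <- grid[1, , drop = FALSE]
  scores <- matrix(NA_real_, nrow(grid), cv_repeats)
  oof_best <- NULL
  for (g in seq_len(nrow(grid))) {
    params <- if (booster == "gblinear") {
      list(booster = "gblinear", lambda = grid$lambda[g],
           alpha = grid$alpha[g], objective = "reg:squarederror",
           nthread = 1L)
    } else {
      list(booster = "gbtree", max_depth = 6L, eta = 0.1,
           subsample = 0.8, objective = "reg:squarederror", nthread = 1L)
    }
    oof_first <- NULL
    for (r in seq_len(cv_repeats)) {
      folds <- make_folds(nrow(x), cv_folds,
                          seed = derive_seed(seed, paste0("xgb", r)))
      pred <- oof_predictions(x, y, folds,
        function(xt, yt) {
          xgboost::xgb.train(params = params,
                             data = xgboost::xgb.DMatrix(xt, label = yt),
                             nrounds = nrounds, verbose = 0)
        },
        function(m, xt) as.numeric(stats::predict(m, xt)))
      scores[g, r] <- sqrt(mean((y - pred)^2))
      if (r == 1L) oof_first <- pred
    }
    if (is.null(oof_best) ||
        mean(scores[g, ]) < oof_best$score) {
      oof_best <- list(score = mean(scores[g, ]), pred = oof_first,
                       params = params, row = g)
    }
  }
  cv <- compute_metrics(y, oof_best$pred)
  fit <- xgboost::xgb.train(params = oof_best$params,
                            data = xgboost::xgb.DMatrix(x, label = y),
                            nrounds = nrounds, verbose = 0)
  train_pred <- as.numeric(stats::predict(fit, x))
  tr <- compute_metrics(y, train_pred)
  imp <- tryCatch(xgboost::xgb.importance(model = fit),
                  error = function(e) NULL)
  new_pka_regressor("xgb", fit, colnames(x),
                    c(oof_best$params, nrounds = nrounds),
                    list(r2_fit = tr$r2, rmse_fit = tr$rmse,
                         q2_cv = cv$r2, rmse_cv = cv$rmse,
                         n = length(y)),
                    extra = list(importance = imp))
}

#' Predict pKa values from a fitted regressor
#'
#' @param object A `pka_regressor`.
#' @param newdata Features (`pka_features` or matrix) on the training
#'   columns.
#' @param ... Unused.
#' @return Numeric vector of predicted pKa values, in input row order.
#' @export
predict.pka_regressor <- function(object, newdata, ...) {
  x <- as_feature_matrix(newdata)
  if (!is.null(colnames(x))) {
    missing_cols <- setdiff(object$columns, colnames(x))
    if (length(missing_cols)) {
      stop("newdata lacks training features: ",
           paste(head(missing_cols, 5), collapse = ", "))
    }
    x <- x[, object$columns, drop = FALSE]
  } else if (ncol(x) != length(object$columns)) {
    stop("newdata has ", ncol(x), " columns; model expects ",
         length(object$columns))
  }
  pred <- switch(object$algorithm,
    svm = as.numeric(stats::predict(object$fit, x)),
    xgb = as.numeric(stats::predict(object$fit, x)),
    dnn = mlp_forward_predict(object$fit, x),
    stop("unknown algorithm: ", object$algorithm))
  unname(pred)
}
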