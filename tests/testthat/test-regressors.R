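toy_binary_regression <- function(n = 200L, p = 12L, seed = 1L,
                                  noise = 0.3) {
  set.seed(seed)
  x <- matrix(stats::rbinom(n * p, 1, 0.4), n, p,
              dimnames = list(NULL, paste0("f", seq_len(p))))
  beta <- c(2, -1.5, 1, 0.8, -0.6, rep(0, p - 5))
  y <- as.numeric(4 + x %*% beta + stats::rnorm(n, 0, noise))
  list(x = x, y = y, beta = beta)
}

test_that("SVM interpolates clean points at large cost", {
  set.seed(9)
  x <- matrix(stats::rnorm(10 * 4), 10, 4,
              dimnames = list(NULL, paste0("f", 1:4)))
  y <- as.numeric(x %*% c(1, -1, 0.5, 0)) + 3
  m <- train_svm(x, y, cv_folds = 5, cost_grid = 1024,
                 gamma_grid = 0.25, epsilon_grid = 0.01)
  expect_lt(m$metrics$rmse_fit, 0.2)
})

test_that("SVM recovers a constructed binary-feature signal", {
  d <- toy_binary_regression()
  tr <- 1:150; te <- 151:200
  m <- train_svm(d$x[tr, ], d$y[tr], cost_grid = 2^c(0, 2, 4),
                 gamma_grid = 2^c(-6, -4, -2), epsilon_grid = 0.1)
  met <- compute_metrics(d$y[te], predict(m, d$x[te, ]))
  expect_gt(met$r2, 0.9)
  # cross-validated Q2 does not beat the resubstitution fit
  expect_lte(m$metrics$q2_cv, m$metrics$r2_fit + 0.05)
})

test_that("XGB importance ranks the true generative features first", {
  d <- toy_binary_regression(seed = 5)
  m <- train_xgb(d$x, d$y, cv_repeats = 2, lambda_grid = c(0, 0.1),
                 alpha_grid = 0)
  expect_s3_class(m$importance, "data.table")
  top3 <- m$importance$Feature[1:3]
  expect_true(all(top3 %in% paste0("f", 1:5)))
  met <- m$metrics
  expect_lt(met$rmse_cv, 0.6)
})

test_that("degenerate targets are rejected by every branch", {
  x <- matrix(stats::rnorm(40), 10, 4,
              dimnames = list(NULL, paste0("f", 1:4)))
  y <- rep(5, 10)
  expect_error(train_svm(x, y), "degenerate")
  expect_error(train_xgb(x, y), "degenerate")
  expect_error(train_dnn(x, y), "degenerate")
})

test_that("the MLP learns a single-feature linear target", {
  set.seed(2)
  x <- matrix(stats::runif(160, -1, 1), ncol = 1,
              dimnames = list(NULL, "f1"))
  y <- as.numeric(3 + 2 * x[, 1])
  m <- train_dnn(x[1:120, , drop = FALSE], y[1:120],
                 hidden = c(16L, 16L), dropout = 0, batchnorm = FALSE,
                 epochs = 300, tune_epochs = 60, lr_grid = c(1e-2, 1e-3),
                 seed = 7)
  pred <- predict(m, x[121:160, , drop = FALSE])
  expect_lt(sqrt(mean((y[121:160] - pred)^2)), 0.25)
})

test_that("MLP training is deterministic per seed", {
  d <- toy_binary_regression(n = 120, seed = 3)
  args <- list(d$x[1:90, ], d$y[1:90], hidden = c(24L, 24L),
               epochs = 60, tune_epochs = 20, lr_grid = 1e-2, seed = 42)
  m1 <- do.call(train_dnn, args)
  m2 <- do.call(train_dnn, args)
  p1 <- predict(m1, d$x[91:120, ])
  p2 <- predict(m2, d$x[91:120, ])
  expect_identical(p1, p2)
})

test_that("serialized models predict identically after reload", {
  d <- toy_binary_regression(n = 80, seed = 13)
  q <- d$x[61:80, ]
  svm_m <- train_svm(d$x[1:60, ], d$y[1:60], cost_grid = 4,
                     gamma_grid = 0.1, epsilon_grid = 0.1)
  path <- tempfile(fileext = ".rds")
  saveRDS(svm_m, path)
  expect_identical(predict(readRDS(path), q), predict(svm_m, q))

  xgb_m <- train_xgb(d$x[1:60, ], d$y[1:60], cv_repeats = 1,
                     lambda_grid = 0.1, alpha_grid = 0)
  raw <- xgboost::xgb.save.raw(xgb_m$fit)
  restored <- xgb_m
  restored$fit <- xgboost::xgb.load.raw(raw)
  expect_equal(predict(restored, q), predict(xgb_m, q))

  dnn_m <- train_dnn(d$x[1:60, ], d$y[1:60], hidden = c(16L, 16L),
                     epochs = 40, tune_epochs = 15, lr_grid = 1e-2)
  path2 <- tempfile(fileext = ".rds")
  saveRDS(dnn_m, path2)
  expect_identical(predict(readRDS(path2), q), predict(dnn_m, q))
})
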