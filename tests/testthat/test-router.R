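test_that("ionizability follows hydrogen donor/acceptor sites", {
  expect_false(is_ionizable("C"))            # methane
  expect_true(is_ionizable("CC(=O)O"))       # carboxyl donor
  expect_true(is_ionizable("c1ccncc1"))      # pyridine ring-N acceptor
  expect_error(is_ionizable("xyzzy"), "unparsable")
})

test_that("zero-distance query returns its training class with k = 1", {
  x <- matrix(c(0, 0, 1, 1, 5, 5), ncol = 2, byrow = TRUE,
              dimnames = list(NULL, c("u", "v")))
  model <- fit_router(x, c("acidic", "basic", "amphoteric"), k = 1)
  expect_identical(unname(predict(model, x[2, , drop = FALSE])), "basic")
})

test_that("majority vote decides among five neighbours", {
  # five training points nearly equidistant from the origin query:
  # 2 acidic vs 3 basic -> basic
  x <- matrix(c(1, 0, -1, 0.01, 0, 1.01, 0.02, -1, 1.005, 0.02),
              ncol = 2, byrow = TRUE,
              dimnames = list(NULL, c("u", "v")))
  labels <- c("acidic", "acidic", "basic", "basic", "basic")
  model <- fit_router(x, labels, k = 5)
  q <- matrix(c(0, 0), 1, dimnames = list(NULL, c("u", "v")))
  expect_identical(unname(predict(model, q)), "basic")
})

test_that("classification equals the brute-force neighbour oracle", {
  set.seed(31)
  n <- 40
  x <- matrix(stats::rnorm(2 * n), ncol = 2,
              dimnames = list(NULL, c("u", "v")))
  labels <- ifelse(x[, 1] + x[, 2] > 0.3, "acidic",
                   ifelse(x[, 1] - x[, 2] > 0.3, "basic", "amphoteric"))
  q <- matrix(stats::rnorm(2 * 15), ncol = 2,
              dimnames = list(NULL, c("u", "v")))
  model <- fit_router(x, labels, k = 5)
  got <- predict(model, q)
  # oracle z-scores from scratch with its own arithmetic
  mu <- colMeans(x); sg <- apply(x, 2, stats::sd)
  xs <- sweep(sweep(x, 2, mu), 2, sg, "/")
  qs <- sweep(sweep(q, 2, mu), 2, sg, "/")
  want <- vapply(seq_len(nrow(qs)), function(i) {
    bf_knn(xs, labels, qs[i, ], 5)
  }, character(1))
  expect_identical(unname(got), want)
})

test_that("prediction is invariant to training-row permutation", {
  set.seed(8)
  x <- matrix(stats::rnorm(60), ncol = 2,
              dimnames = list(NULL, c("u", "v")))
  labels <- sample(c("acidic", "basic", "amphoteric"), 30, replace = TRUE)
  q <- matrix(stats::rnorm(10), ncol = 2,
              dimnames = list(NULL, c("u", "v")))
  m1 <- fit_router(x, labels, k = 3)
  ord <- sample(30)
  m2 <- fit_router(x[ord, ], labels[ord], k = 3)
  expect_identical(predict(m1, q), predict(m2, q))
})

test_that("router self-prediction with k = 1 is perfect and errors are raised", {
  set.seed(4)
  x <- matrix(stats::rnorm(40), ncol = 2,
              dimnames = list(NULL, c("u", "v")))
  labels <- rep(c("acidic", "basic"), each = 10)
  model <- fit_router(x, labels, k = 1)
  ev <- evaluate_router(model)
  expect_equal(ev$train_ba, 1)
  expect_error(fit_router(x, labels, k = 100), "k exceeds")
  expect_error(fit_router(x, rep("acidic", 20)), "two classes")
})

test_that("permuted labels give chance-level test balanced accuracy", {
  set.seed(15)
  n <- 120
  x <- matrix(stats::rnorm(2 * n), ncol = 2,
              dimnames = list(NULL, c("u", "v")))
  labels <- sample(c("acidic", "basic", "amphoteric"), n, replace = TRUE)
  tr <- seq_len(90); te <- 91:120
  model <- fit_router(x[tr, ], labels[tr], k = 5)
  ev <- evaluate_router(model, x[te, ], labels[te])
  expect_lt(abs(ev$test_ba - 1 / 3), 0.2)
})
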