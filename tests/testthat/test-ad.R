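test_that("leverages match the hat-matrix hand computation", {
  x <- matrix(c(0, 1, 2), ncol = 1, dimnames = list(NULL, "f"))
  model <- fit_global_ad(x)
  expect_equal(unname(model$train_leverage), c(0.5, 0, 0.5))
  expect_equal(sum(model$train_leverage), model$p)  # p = 1
})

test_that("training leverages sum to the effective dimension", {
  set.seed(23)
  x <- matrix(stats::rnorm(60), 20, 3,
              dimnames = list(NULL, paste0("f", 1:3)))
  model <- fit_global_ad(x)
  expect_equal(model$p, 3L)
  expect_equal(sum(model$train_leverage), 3, tolerance = 1e-8)
})

test_that("centroid queries sit inside, extreme extrapolations outside", {
  set.seed(29)
  x <- matrix(stats::rnorm(100), 50, 2,
              dimnames = list(NULL, c("a", "b")))
  centroid <- matrix(colMeans(x), 1, dimnames = list(NULL, c("a", "b")))
  far <- centroid + 100 * apply(x, 2, stats::sd)
  res <- global_ad(x, rbind(centroid, far))
  expect_true(res$inside[1])
  expect_lt(res$leverage[1], 1e-10)
  expect_false(res$inside[2])
})

test_that("wide matrices fall back to a PCA projection", {
  set.seed(37)
  x <- matrix(stats::rnorm(10 * 50), 10, 50,
              dimnames = list(NULL, paste0("f", 1:50)))
  model <- fit_global_ad(x)
  expect_lte(model$p, 9L)
  res <- global_ad(model, x)
  expect_true(all(is.finite(res$leverage)))
})

test_that("Tanimoto similarity closed forms", {
  expect_equal(tanimoto_similarity(c(1, 1, 0, 1), c(1, 1, 0, 1)), 1)
  expect_equal(tanimoto_similarity(c(1, 1, 0, 0), c(0, 0, 1, 1)), 0)
  expect_equal(tanimoto_similarity(c(1, 1, 0, 0), c(1, 0, 1, 0)), 1 / 3)
  expect_equal(tanimoto_similarity(c(0, 0), c(0, 0)), 1)
  expect_error(tanimoto_similarity(c(1, 0), c(1, 0, 1)), "length")
  expect_error(tanimoto_similarity(c(2, 0), c(1, 0)), "binary")
})

test_that("local AD index hits its closed-form extremes", {
  fps <- rbind(a = c(1, 1, 0, 0), b = c(0, 0, 1, 1), c = c(1, 0, 1, 0))
  pka <- c(4, 7, 9)
  hit <- local_ad(fps, pka, c(1, 1, 0, 0), ad_params(k_neighbors = 1))
  expect_equal(hit$local_index, 1)
  expect_identical(hit$neighbors$key[1], "a")

  miss <- local_ad(rbind(a = c(1, 1, 0, 0)), 4, c(0, 0, 1, 1),
                   ad_params(k_neighbors = 1))
  expect_equal(miss$local_index, 0)
  expect_error(local_ad(fps, pka, c(1, 0, 0, 0),
                        ad_params(k_neighbors = 10)), "exceeds")
})

test_that("local AD equals a brute-force similarity sort", {
  set.seed(41)
  fps <- matrix(stats::rbinom(5 * 16, 1, 0.4), 5, 16,
                dimnames = list(paste0("s", 1:5), NULL))
  pka <- stats::runif(5, 2, 10)
  q <- stats::rbinom(16, 1, 0.4)
  res <- local_ad(fps, pka, q, ad_params(k_neighbors = 3))
  sims <- apply(fps, 1, function(r) tanimoto_similarity(r, q))
  want <- mean(sort(sims, decreasing = TRUE)[1:3])
  expect_equal(res$local_index, want)

  # invariant to training-row order
  ord <- c(3, 1, 5, 2, 4)
  res2 <- local_ad(fps[ord, ], pka[ord], q, ad_params(k_neighbors = 3))
  expect_equal(res2$local_index, res$local_index)
})

test_that("accuracy estimate weights neighbour residuals by similarity", {
  fps <- rbind(a = c(1, 1, 0, 0), b = c(1, 0, 0, 0))
  pka <- c(4, 8)
  pred <- c(5, 6)  # residuals 1 and 2
  res <- local_ad(fps, pka, c(1, 1, 0, 0), ad_params(k_neighbors = 2),
                  predicted_train = pred)
  sims <- c(1, 0.5)
  expect_equal(res$accuracy_estimate,
               sum(sims * c(1, 2)) / sum(sims))
})

test_that("predictions inside the global AD are more accurate than outside", {
  set.seed(53)
  n <- 150
  x <- matrix(stats::runif(2 * n, 0, 1), ncol = 2,
              dimnames = list(NULL, c("a", "b")))
  y <- as.numeric(3 + 2 * x[, 1] - x[, 2] + stats::rnorm(n, 0, 0.2))
  fit <- train_svm(x, y, cost_grid = 4, gamma_grid = 1,
                   epsilon_grid = 0.1)
  # queries: half interpolations, half extrapolations far outside
  q_in <- matrix(stats::runif(60, 0.1, 0.9), ncol = 2,
                 dimnames = list(NULL, c("a", "b")))
  q_out <- matrix(stats::runif(60, 2.5, 3.5), ncol = 2,
                  dimnames = list(NULL, c("a", "b")))
  q <- rbind(q_in, q_out)
  truth <- as.numeric(3 + 2 * q[, 1] - q[, 2])
  ad <- global_ad(x, q)
  expect_true(any(ad$inside) && any(!ad$inside))
  err <- (truth - predict(fit, q))^2
  expect_lte(sqrt(mean(err[ad$inside])), sqrt(mean(err[!ad$inside])))
})
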