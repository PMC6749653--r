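toy_tables <- function() {
  a <- prediction_table(c("k1", "k2", "k3"), acidic_pka = c(4.0, 4.0, 6.5),
                        source = "A")
  b <- prediction_table(c("k1", "k2", "k4"), acidic_pka = c(5.5, 7.0, 3.0),
                        source = "B")
  list(a = a, b = b)
}

test_that("pairwise concordance counts within/beyond the threshold", {
  t <- toy_tables()
  rep_ <- pairwise_concordance(t$a, t$b, "acidic", threshold = 2)
  expect_equal(rep_$n_common, 2L)
  expect_equal(rep_$n_within, 1L)
  expect_equal(rep_$n_beyond, 1L)
  expect_equal(rep_$n_within + rep_$n_beyond, rep_$n_common)
  expect_identical(rep_$concordant$structure_key, "k1")

  # a vs a: everything concordant
  self <- pairwise_concordance(t$a, t$a, "acidic")
  expect_equal(self$n_beyond, 0L)
  expect_equal(self$rmse, 0)

  # |delta| exactly at the threshold counts as concordant
  eq <- pairwise_concordance(
    prediction_table("k", acidic_pka = 4),
    prediction_table("k", acidic_pka = 6), "acidic", threshold = 2)
  expect_equal(eq$n_within, 1L)

  expect_error(pairwise_concordance(
    prediction_table("x", acidic_pka = 1),
    prediction_table("y", acidic_pka = 1), "acidic"), "no common")
})

test_that("widening the threshold never loses concordant pairs", {
  set.seed(61)
  keys <- sprintf("k%03d", 1:60)
  a <- prediction_table(keys, acidic_pka = stats::runif(60, 0, 12))
  b <- prediction_table(keys, acidic_pka = stats::runif(60, 0, 12))
  thr <- c(0.5, 1, 2, 4, 8)
  n_within <- vapply(thr, function(t) {
    pairwise_concordance(a, b, "acidic", t)$n_within
  }, integer(1))
  expect_true(all(diff(n_within) >= 0L))
})

test_that("benchmark construction averages concordant predictions", {
  bench <- build_benchmark(
    prediction_table("k", acidic_pka = 4),
    prediction_table("k", acidic_pka = 6), "acidic")
  expect_equal(bench$acidic_pka, 5)

  t <- toy_tables()
  same <- build_benchmark(t$a, t$a, "acidic")
  expect_equal(same$acidic_pka,
               t$a$acidic_pka[match(same$structure_key,
                                    t$a$structure_key)])
})

test_that("range filtering is inclusive, idempotent, and validated", {
  t <- prediction_table(sprintf("k%d", 1:5),
                        acidic_pka = c(-1, 0, 7, 14, 15))
  f <- range_filter(t, "acidic", 0, 14)
  expect_equal(nrow(f), 3L)
  expect_identical(range_filter(f, "acidic", 0, 14), f)
  expect_error(range_filter(t, "acidic", 3, 1), "lo")
})

test_that("bootstrap intervals are seeded and collapse on exact agreement", {
  set.seed(71)
  o <- stats::rnorm(40); p <- o + stats::rnorm(40, sd = 0.5)
  ci1 <- bootstrap_ci(o, p, "r2", n_boot = 200, seed = 5)
  ci2 <- bootstrap_ci(o, p, "r2", n_boot = 200, seed = 5)
  expect_identical(ci1, ci2)
  expect_lt(ci1[1], ci1[2])

  exact <- bootstrap_ci(o, o, "rmse", n_boot = 100, seed = 1)
  expect_equal(as.vector(exact), c(0, 0))
  expect_error(bootstrap_ci(1:5, 1:5, "rmse"), "at least 10")
})

test_that("bootstrap R2 interval covers the population value ~95% of the time", {
  true_r2 <- 0.75  # p = o + e with var(o) = 1, var(e) = 0.25
  hits <- 0L
  n_sim <- 120L
  for (s in seq_len(n_sim)) {
    set.seed(1000 + s)
    o <- stats::rnorm(80)
    p <- o + stats::rnorm(80, sd = 0.5)
    ci <- bootstrap_ci(o, p, "r2", n_boot = 250, seed = s)
    if (true_r2 >= ci[1] && true_r2 <= ci[2]) hits <- hits + 1L
  }
  coverage <- hits / n_sim
  expect_gt(coverage, 0.85)
  expect_lte(coverage, 1)
})
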