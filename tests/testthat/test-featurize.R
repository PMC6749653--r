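test_that("fingerprint columns are strictly binary and counts non-negative", {
  fm <- compute_features(c("CCO", "c1ccncc1", "CC(=O)Oc1ccccc1C(=O)O"),
                         families = c("maccs", "substructure_counts"))
  bits <- fm$values[, grepl("^maccs_", colnames(fm$values)), drop = FALSE]
  expect_true(all(bits %in% c(0, 1)))
  cnts <- fm$values[, grepl("^frag_", colnames(fm$values)), drop = FALSE]
  expect_true(all(cnts >= 0))
  expect_true(all(cnts == round(cnts)))
  expect_false(anyDuplicated(colnames(fm$values)) > 0)
})

test_that("substructure counts match manual enumeration", {
  fm <- compute_features(c(ethanol = "CCO", aspirin = "CC(=O)Oc1ccccc1C(=O)O"),
                         families = "substructure_counts")
  expect_equal(fm$values["ethanol", "frag_hydroxyl"], 1)
  expect_equal(fm$values["ethanol", "frag_alcohol_oh"], 1)
  expect_equal(fm$values["ethanol", "frag_carboxylic_acid"], 0)
  asp <- fm$values["aspirin", ]
  expect_equal(asp[["frag_carboxylic_acid"]], 1)
  expect_equal(asp[["frag_ester"]], 1)
  expect_equal(asp[["frag_benzene_ring"]], 1)
})

test_that("atom-pair counts match hand enumeration on ethanol", {
  fm <- compute_features(c(e = "CCO"), families = "atom_pairs")
  v <- fm$values[1, ]
  expect_equal(v[["ap_C_C_1"]], 1)
  expect_equal(v[["ap_C_O_1"]], 1)
  expect_equal(v[["ap_C_O_2"]], 1)
  expect_equal(sum(v), 3)
})

test_that("feature computation is deterministic", {
  smiles <- c("Oc1ccc(Cl)cc1", "NCC(=O)O")
  a <- compute_features(smiles, families = c("continuous_1d2d", "maccs"))
  b <- compute_features(smiles, families = c("continuous_1d2d", "maccs"))
  expect_identical(a$values, b$values)
})

test_that("reduction ladder drops constant, correlated, low-variance columns", {
  set.seed(5)
  m <- cbind(zero = 0, ones = 1,
             a = stats::rnorm(30), b = stats::rnorm(30),
             tiny = stats::rnorm(30, sd = 0.01))
  m <- cbind(m, a_copy = m[, "a"])
  fm <- pkaqsar:::new_pka_features(m, "continuous", "D0", "continuous_1d2d")

  d1 <- reduce_features(fm, "D1")
  expect_false(any(c("zero", "ones") %in% colnames(d1$values)))

  d2 <- reduce_features(fm, "D2")
  expect_equal(sum(c("a", "a_copy") %in% colnames(d2$values)), 1L)

  d3 <- reduce_features(fm, "D3", var_threshold = 0.01)
  expect_false("tiny" %in% colnames(d3$values))

  # monotone column nesting across the ladder
  expect_true(all(colnames(d3$values) %in% colnames(d2$values)))
  expect_true(all(colnames(d2$values) %in% colnames(d1$values)))
  expect_true(all(colnames(d1$values) %in% colnames(fm$values)))
  expect_identical(rownames(d3$values), rownames(fm$values))
})

test_that("D2 agrees with the exhaustive pairwise-correlation oracle", {
  set.seed(17)
  m <- matrix(stats::rnorm(20 * 10), 20, 10,
              dimnames = list(NULL, paste0("c", 1:10)))
  m[, 4] <- m[, 2] * 2 + stats::rnorm(20, sd = 0.01)  # near-duplicate
  fm <- pkaqsar:::new_pka_features(m, "continuous", "D0", "continuous_1d2d")
  d2 <- reduce_features(fm, "D2", corr_threshold = 0.9)
  expect_identical(colnames(d2$values), bf_corr_filter(m, 0.9))
})

test_that("all-constant input errors out of the reduction", {
  m <- matrix(1, 5, 3, dimnames = list(NULL, c("x", "y", "z")))
  fm <- pkaqsar:::new_pka_features(m, "continuous", "D0", "continuous_1d2d")
  expect_error(reduce_features(fm, "D1"), "all columns removed")
})

test_that("min-max scaling maps endpoints to -1/1 and inverts exactly", {
  m <- cbind(a = c(0, 5, 10), b = c(2, 2, 2), c = c(-4, 0, 8))
  spec <- fit_scaling(m)
  s <- apply_scaling(m, spec)
  expect_equal(s[, "a"], c(-1, 0, 1))
  expect_equal(s[, "b"], c(0, 0, 0))  # zero-range column maps to 0
  back <- apply_scaling(s, spec, invert = TRUE)
  expect_equal(back, m, tolerance = 1e-12)

  # spec fitted on train applies beyond [-1, 1] for out-of-range rows
  q <- cbind(a = 20, b = 2, c = 0)
  expect_gt(apply_scaling(q, spec)[, "a"], 1)
})
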