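test_that("fixture generation is deterministic and exact on composition", {
  spec <- fixture_spec(n_structures = 100L, pct_amphoteric = 0.2, seed = 19)
  f1 <- generate_fixture(spec)
  f2 <- generate_fixture(spec)
  expect_identical(as.data.frame(f1), as.data.frame(f2))

  truth <- attr(f1, "truth")
  expect_equal(nrow(truth), 100L)
  expect_equal(sum(truth$class_type == "amphoteric"), 20L)

  f3 <- generate_fixture(fixture_spec(n_structures = 100L,
                                      pct_amphoteric = 0.2, seed = 20))
  expect_false(identical(f1$pka, f3$pka))
})

test_that("infeasible specifications are rejected", {
  expect_error(fixture_spec(pct_mixtures = 0.7, pct_inorganics = 0.5),
               "infeasible")
  expect_error(fixture_spec(replicate_profile = c("1" = 0.5)),
               "sum to 1")
  expect_error(fixture_spec(sd_profile = c(low = 1, mid = 0, high = 0.5)),
               "sum to 1")
  expect_error(generate_fixture(fixture_spec(n_structures = 5000L)),
               "pool too small")
})

test_that("replicate groups realize their SD band and stay in range", {
  fix <- generate_fixture(fixture_spec(
    n_structures = 80L, seed = 57,
    replicate_profile = c("1" = 0.2, "3" = 0.5, "4" = 0.3),
    sd_profile = c(low = 0, mid = 0, high = 1),
    pct_salts = 0, pct_mixtures = 0, pct_inorganics = 0))
  truth <- attr(fix, "truth")
  high_ids <- which(truth$group_size >= 2L)
  sds <- vapply(high_ids, function(i) {
    sel <- fix$structure_id == i & fix$class == "acidic"
    if (sum(sel, na.rm = TRUE) >= 2L) stats::sd(fix$pka[which(sel)]) else NA_real_
  }, numeric(1))
  sds <- sds[!is.na(sds)]
  expect_gt(length(sds), 10L)
  expect_gte(mean(sds > 2), 0.9)

  expect_true(all(fix$pka[fix$class == "acidic"] >= 0 &
                    fix$pka[fix$class == "acidic"] <= 14))
  expect_true(all(fix$pka[fix$class == "basic"] >= -2 &
                    fix$pka[fix$class == "basic"] <= 12))
})

test_that("injected records survive or fail standardization as designed", {
  fix <- shared_fixture()
  inj <- attr(fix, "injection")
  std <- standardize_structures(fix$smiles, on_parse_error = "reject")
  expect_equal(sum(std$rejected &
                     std$rejection_reason == "mixture"), inj$n_mixtures)
  expect_equal(sum(std$rejected &
                     std$rejection_reason == "inorganic"), inj$n_inorganics)
  # salt records standardize onto a parent that already exists
  truth <- attr(fix, "truth")
  expect_true(all(std$structure_key[!std$rejected] %in%
                    truth$structure_key))
})

test_that("the group-contribution oracle is additive with signed effects", {
  base <- oracle_pka("benzoic_acid", "acidic")
  expect_equal(base, 4.2)
  # electron-withdrawing decoration strengthens the acid
  expect_lt(oracle_pka("benzoic_acid", "acidic", "nitro"), base)
  expect_lt(oracle_pka("benzoic_acid", "acidic", c("nitro", "chloro")),
            oracle_pka("benzoic_acid", "acidic", "nitro"))
  # donating decoration weakens it
  expect_gt(oracle_pka("benzoic_acid", "acidic", "methyl"), base)
  # chain growth nudges aliphatic acids upward
  expect_gt(oracle_pka("aliphatic_acid", "acidic", chain = 3L),
            oracle_pka("aliphatic_acid", "acidic", chain = 0L))
  expect_error(oracle_pka("nope", "acidic"), "unknown template")
  expect_error(oracle_pka("phenol", "basic"), "no basic")
})

test_that("a regressor trained on fixtures recovers the oracle signal", {
  bundle <- shared_bundle()
  fix <- shared_fixture()
  truth <- attr(fix, "truth")
  spec <- attr(fix, "spec")
  te <- bundle$acidic$test
  oracle <- truth$oracle_acidic[match(te$structure_key,
                                      truth$structure_key)]
  keep <- !is.na(oracle)
  expect_gt(sum(keep), 10L)
  pred <- predict(bundle$acidic$model, {
    fm <- compute_features(setNames(te$canonical_smiles,
                                    te$structure_key),
                           families = bundle$config$regressor_families)
    pkaqsar:::align_features(fm$values, bundle$acidic$columns)
  })
  rmse <- sqrt(mean((oracle[keep] - pred[keep])^2))
  expect_lt(rmse, 2 * spec$noise_sd)
})
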