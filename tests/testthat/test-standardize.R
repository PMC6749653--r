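key_of <- function(smiles) pkaqsar:::ob_inchikey(smiles)

test_that("counterions and solvents are stripped to the organic parent", {
  res <- standardize_structure("CC(=O)[O-].[Na+]")
  expect_false(res$rejected)
  expect_identical(res$structure_key, key_of("CC(=O)O"))

  # solvent stripped only when another organic fragment is present
  res2 <- standardize_structure("CCO.OC(=O)C")
  expect_identical(res2$structure_key, key_of("CC(=O)O"))

  # a lone allow-listed organic is the parent, not a solvent
  res3 <- standardize_structure("CCO")
  expect_false(res3$rejected)
  expect_identical(res3$structure_key, key_of("CCO"))

  # hydrochloride salt of a base
  res4 <- standardize_structure("NCCc1ccccc1.Cl")
  expect_identical(res4$structure_key, key_of("NCCc1ccccc1"))
})

test_that("identity case leaves simple organics untouched", {
  res <- standardize_structure("c1ccccc1")
  expect_false(res$rejected)
  expect_identical(res$canonical_smiles, "c1ccccc1")
})

test_that("mixtures, inorganics and fully stripped inputs are rejected", {
  res <- standardize_structures(
    c("c1ccccc1.CCN",       # two distinct organics
      "CCN.CCN",            # duplicated organic collapses to one parent
      "[Na+].[Cl-]",        # no carbon anywhere
      "O",                  # water
      "CCO.CO"))            # only allow-listed organics
  expect_identical(res$rejection_reason[1], "mixture")
  expect_false(res$rejected[2])
  expect_identical(res$structure_key[2], key_of("CCN"))
  expect_identical(res$rejection_reason[3], "inorganic")
  expect_identical(res$rejection_reason[4], "inorganic")
  expect_identical(res$rejection_reason[5], "empty_after_stripping")
})

test_that("nitro mesomers and terminal enols map to one canonical form", {
  res <- standardize_structures(c("O=N(=O)c1ccccc1",
                                  "[O-][N+](=O)c1ccccc1"))
  expect_identical(res$structure_key[1], res$structure_key[2])
  expect_true(grepl("[N+]", res$canonical_smiles[1], fixed = TRUE))

  # but-1-en-2-ol tautomerizes to butan-2-one
  enol <- standardize_structure("C=C(O)CC")
  expect_identical(enol$structure_key, key_of("CCC(C)=O"))
})

test_that("zwitterions are kept unmodified while salt anions are neutralized", {
  zwit <- standardize_structure("C(C(=O)[O-])[NH3+]")
  expect_true(grepl("[NH3+]", zwit$canonical_smiles, fixed = TRUE))
  # normalization still deduplicates the zwitterion with neutral glycine
  expect_identical(zwit$structure_key, key_of("NCC(=O)O"))

  # nitro groups must not fool the net-charge rule
  salt <- standardize_structure(
    "[O-]C(=O)c1ccc([N+](=O)[O-])c([N+](=O)[O-])c1.[Na+]")
  expect_false(grepl("C(=O)[O-]", salt$canonical_smiles, fixed = TRUE))
  expect_identical(
    salt$structure_key,
    key_of("OC(=O)c1ccc([N+](=O)[O-])c([N+](=O)[O-])c1"))
})

test_that("standardization is idempotent on the structure key", {
  pool <- pkaqsar:::fixture_pool()
  set.seed(42)
  smiles <- sample(pool$smiles, 15L)
  first <- standardize_structures(smiles)
  second <- standardize_structures(first$canonical_smiles)
  expect_identical(second$structure_key, first$structure_key)
  expect_identical(second$canonical_smiles, first$canonical_smiles)
})

test_that("unparsable SMILES error or reject according to the mode", {
  expect_error(standardize_structure("xyzzy"), "unparsable")
  res <- standardize_structures(c("CCO", "xyzzy"),
                                on_parse_error = "reject")
  expect_false(res$rejected[1])
  expect_identical(res$rejection_reason[2], "parse_error")
})
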