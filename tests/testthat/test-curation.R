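test_that("replicate grouping computes per-class sample SDs", {
  rec <- pka_records(c("CC(=O)O", "CC(=O)O"), c(4.0, 4.2),
                     c("acidic", "acidic"))
  g <- group_replicates(rec)
  expect_equal(nrow(g), 1L)
  expect_equal(g$acidic_sd, 0.1414214, tolerance = 1e-6)
  expect_true(is.na(g$basic_sd))
  expect_false(g$amphoteric)

  rec2 <- pka_records(c("Nc1ccc(O)cc1", "Nc1ccc(O)cc1"), c(10.1, 4.5),
                      c("acidic", "basic"))
  g2 <- group_replicates(rec2)
  expect_true(g2$amphoteric)
  expect_true(is.na(g2$acidic_sd))  # singleton per class
})

test_that("option rules select, average, or take the strongest value", {
  groups <- make_groups(
    acidic = list(c(2, 6),        # SD ~2.83: opt3 takes the minimum
                  c(4, 4.5),      # SD ~0.35: opt2/3 average
                  c(3, 4.8),      # SD ~1.27: opt2 mean, opt3 minimum
                  5.1,            # singleton
                  numeric(0)),
    basic = list(numeric(0), numeric(0), numeric(0), numeric(0),
                 c(7, 11)))       # SD ~2.83: opt3 takes the maximum

  o1 <- build_option_dataset(groups, 1)
  expect_setequal(o1$acidic$structure_key, "KEY004")
  expect_equal(o1$acidic$pka, 5.1)

  o2 <- build_option_dataset(groups, 2)
  expect_setequal(o2$acidic$structure_key,
                  c("KEY002", "KEY003", "KEY004"))
  expect_equal(o2$acidic$pka[o2$acidic$structure_key == "KEY002"], 4.25)
  expect_equal(o2$acidic$pka[o2$acidic$structure_key == "KEY003"], 3.9)

  o3 <- build_option_dataset(groups, 3)
  expect_equal(o3$acidic$pka[o3$acidic$structure_key == "KEY001"], 2)
  expect_equal(o3$acidic$pka[o3$acidic$structure_key == "KEY003"], 3)
  expect_equal(o3$basic$pka[o3$basic$structure_key == "KEY005"], 11)
  expect_null(o3$combined)

  expect_error(build_option_dataset(groups, 4), "option")
})

test_that("option-3 values follow the min/max/mean rule on random groups", {
  set.seed(11)
  acid_vals <- lapply(1:50, function(i) {
    stats::runif(sample(1:5, 1), 1, 9)
  })
  groups <- make_groups(acid_vals, rep(list(numeric(0)), 50))
  o3 <- build_option_dataset(groups, 3)
  for (j in seq_len(nrow(o3$acidic))) {
    key <- o3$acidic$structure_key[j]
    v <- acid_vals[[match(key, groups$structure_key)]]
    expected <- if (length(v) == 1L || stats::sd(v) <= 1) mean(v) else min(v)
    expect_equal(o3$acidic$pka[j], expected)
  }
})

test_that("option coverage is nested and combined sets exclude amphoterics", {
  rep <- shared_curation()
  ds <- attr(rep, "datasets")
  for (sub in c("acidic", "basic")) {
    k1 <- ds$option1[[sub]]$structure_key
    k2 <- ds$option2[[sub]]$structure_key
    k3 <- ds$option3[[sub]]$structure_key
    expect_true(all(k1 %in% k2))
    expect_true(all(k2 %in% k3))
  }
  groups <- attr(rep, "groups")
  amph <- groups$structure_key[groups$amphoteric]
  for (op in c("option1", "option2")) {
    expect_length(intersect(ds[[op]]$combined$structure_key, amph), 0L)
  }
})

test_that("train/test split is exact, stratified and reproducible", {
  ds <- make_dataset(stats::runif(100, 2, 9))
  sp <- split_train_test(ds, 0.75, seed = 1)
  expect_equal(sum(sp$split == "train"), 75L)
  expect_equal(sum(sp$split == "test"), 25L)
  expect_equal(sum(sp$split %in% c("train", "test")), nrow(ds))

  sp2 <- split_train_test(ds, 0.75, seed = 1)
  expect_identical(sp$split, sp2$split)
  sp3 <- split_train_test(ds, 0.75, seed = 2)
  expect_false(identical(sp$split, sp3$split))

  expect_error(split_train_test(ds, 1.2), "frac_train")
  expect_error(split_train_test(ds, 0), "frac_train")
})

test_that("split preserves a bimodal pKa distribution", {
  set.seed(7)
  pka <- c(stats::rnorm(220, 4, 0.8), stats::rnorm(180, 9.5, 0.8))
  ds <- make_dataset(pka)
  sp <- split_train_test(ds, 0.75, seed = 13)
  tr <- sp$pka[sp$split == "train"]
  te <- sp$pka[sp$split == "test"]
  ks <- suppressWarnings(stats::ks.test(tr, te))
  expect_lt(unname(ks$statistic), 0.1)
})
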