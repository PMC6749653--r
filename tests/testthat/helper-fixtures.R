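# shared fixtures and independent oracles used across test files; heavy
# objects are built once per session and cached

.test_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  got <- get0(name, envir = .test_cache)
  if (!is.null(got)) return(got)
  val <- builder()
  assign(name, val, envir = .test_cache)
  val
}

shared_fixture <- function() {
  cached("fixture", function() {
    generate_fixture(fixture_spec(n_structures = 150L, seed = 3L))
  })
}

shared_curation <- function() {
  cached("curation", function() {
    cmd_curate(shared_fixture(), output_dir = NULL, options = 1:3)
  })
}

# one trained SVM bundle reused by pipeline, AD and recovery tests;
# compact hyperparameter grids keep the runtime low
shared_bundle <- function() {
  cached("bundle", function() {
    cfg <- run_config(
      option = 2L, algorithm = "svm", seed = 5L,
      regressor_args = list(cost_grid = 2^c(0, 4, 8),
                            gamma_grid = 2^c(-6, -3),
                            epsilon_grid = 0.1))
    cmd_train(shared_fixture(), cfg)
  })
}

# construct a replicate_groups table directly from value lists
make_groups <- function(acidic, basic, keys = NULL) {
  n <- length(acidic)
  stopifnot(length(basic) == n)
  keys <- keys %||% sprintf("KEY%03d", seq_len(n))
  out <- data.frame(structure_key = keys,
                    canonical_smiles = paste0("SMI", seq_len(n)),
                    stringsAsFactors = FALSE)
  out$acidic_values <- acidic
  out$basic_values <- basic
  sd_or_na <- function(v) if (length(v) >= 2L) stats::sd(v) else NA_real_
  out$acidic_sd <- vapply(acidic, sd_or_na, numeric(1))
  out$basic_sd <- vapply(basic, sd_or_na, numeric(1))
  out$amphoteric <- lengths(acidic) > 0L & lengths(basic) > 0L
  class(out) <- c("replicate_groups", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# construct a pka_dataset directly
make_dataset <- function(pka, class = "acidic", replicate = FALSE,
                         amphoteric = FALSE, option = 1L,
                         subset = class[1]) {
  n <- length(pka)
  out <- data.frame(structure_key = sprintf("KEY%04d", seq_len(n)),
                    canonical_smiles = sprintf("SMI%04d", seq_len(n)),
                    pka = pka, class = rep_len(class, n),
                    n_values = 1L,
                    replicate = rep_len(replicate, n),
                    amphoteric = rep_len(amphoteric, n),
                    stringsAsFactors = FALSE)
  attr(out, "option") <- option
  attr(out, "subset") <- subset
  class(out) <- c("pka_dataset", "data.frame")
  out
}

# brute-force kNN oracle: plain distance sort + majority vote with the
# nearest-neighbour tie-break, written independently of the package path
bf_knn <- function(train_x, train_labels, query, k) {
  d <- sqrt(colSums((t(train_x) - query)^2))
  ord <- order(d, seq_along(d))
  nn <- ord[seq_len(k)]
  votes <- table(train_labels[nn])
  top <- names(votes)[votes == max(votes)]
  if (length(top) == 1L) top else train_labels[ord[1]]
}

# brute-force pairwise-correlation filter oracle (keep-first convention)
bf_corr_filter <- function(m, threshold) {
  kept <- 1L
  for (j in 2:ncol(m)) {
    ok <- TRUE
    for (i in kept) {
      r <- suppressWarnings(stats::cor(m[, i], m[, j]))
      if (!is.na(r) && abs(r) >= threshold) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, j)
  }
  colnames(m)[kept]
}
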