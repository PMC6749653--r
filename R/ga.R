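#' Genetic-algorithm configuration
#'
#' Defaults: population 100, 200 generations, tournament selection of
#' size 3, one-point crossover at rate 0.8, per-bit mutation at 1/n
#' features, single-individual elitism, fivefold cross-validation, and a
#' soft subset-size penalty (0.001 per selected descriptor) that biases
#' the search toward compact descriptor sets.
#'
#' @param population_size Number of chromosomes per generation (>= 2).
#' @param generations Number of generations (>= 1).
#' @param crossover_rate Probability of one-point crossover.
#' @param mutation_rate Per-bit mutation probability; `NULL` means
#'   1 / n_features.
#' @param max_subset_size Upper bound on selected descriptors per
#'   chromosome (enforced by seeded truncation).
#' @param cv_folds Cross-validation folds used by the fitness function.
#' @param seed Integer seed.
#' @param tournament_size Tournament size for parent selection.
#' @param elitism Number of elite chromosomes copied unchanged.
#' @param size_penalty Fitness penalty per selected descriptor.
#' @return A `ga_config` list.
#' @export
ga_config <- function(population_size = 100L, generations = 200L,
                      crossover_rate = 0.8, mutation_rate = NULL,
                      max_subset_size = 30L, cv_folds = 5L, seed = 1L,
                      tournament_size = 3L, elitism = 1L,
                      size_penalty = 0.001) {
  stopifnot(population_size >= 2L, generations >= 1L,
            crossover_rate >= 0, crossover_rate <= 1,
            is.null(mutation_rate) ||
              (mutation_rate >= 0 && mutation_rate <= 1))
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate,
                 max_subset_size = as.integer(max_subset_size),
                 cv_folds = as.integer(cv_folds),
                 seed = as.integer(seed),
                 tournament_size = as.integer(tournament_size),
                 elitism = as.integer(elitism),
                 size_penalty = size_penalty),
            class = "ga_config")
}

# cross-validated balanced accuracy of a kNN classifier restricted to the
# columns flagged in `chrom`; folds are fixed up front so every chromosome
# is scored on the same partition (paired comparisons)
ga_cv_fitness <- function(chrom, x, labels, folds, k, size_penalty) {
  cols <- which(chrom)
  if (length(cols) == 0L) return(-Inf)
  xs <- x[, cols, drop = FALSE]
  # z-score on the full matrix; per-fold standardization would leak less
  # but kNN geometry must be identical across chromosomes for pairing
  mu <- colMeans(xs); sg <- apply(xs, 2, stats::sd); sg[sg == 0] <- 1
  xs <- sweep(sweep(xs, 2, mu), 2, sg, "/")
  pred <- character(nrow(xs))
  for (f in sort(unique(folds))) {
    te <- folds == f
    kf <- min(k, sum(!te))
    pred[te] <- knn_predict(xs[!te, , drop = FALSE], labels[!te],
                            xs[te, , drop = FALSE], kf)
  }
  ba <- balanced_accuracy(labels, pred)
  ba - size_penalty * length(cols)
}

#' Genetic-algorithm descriptor selection
#'
#' Evolves binary chromosomes (presence/absence of each descriptor) to
#' maximize the cross-validated multiclass balanced accuracy of a kNN
#' classifier restricted to the selected descriptors, minus a small
#' subset-size penalty. Selection is by tournament, variation by
#' one-point crossover and per-bit mutation, and the elite chromosome is
#' carried over unchanged, so the best penalized fitness never decreases.
#'
#' @param fm A `pka_features` object or numeric matrix of continuous
#'   descriptors.
#' @param labels Class labels (acidic/basic/amphoteric) per row.
#' @param cfg A [ga_config()].
#' @param k Neighbours used by the kNN fitness classifier (default 5).
#' @return A `ga_result` list: `selected_descriptors`, `fitness`
#'   (balanced accuracy of the elite, unpenalized), `penalized_fitness`,
#'   `history` (per-generation elite penalized fitness), `folds`.
#' @export
ga_select <- function(fm, labels, cfg = ga_config(), k = 5L) {
  x <- if (inherits(fm, "pka_features")) fm$values else fm
  stopifnot(is.matrix(x), nrow(x) == length(labels))
  labels <- as.character(labels)
  if (length(unique(labels)) < 3L) {
    stop("descriptor selection expects at least 3 classes")
  }
  nf <- ncol(x)
  if (cfg$max_subset_size >= nf) {
    warning("max_subset_size >= number of descriptors; search is degenerate")
  }
  mut <- cfg$mutation_rate %||% (1 / nf)
  folds <- make_folds(nrow(x), cfg$cv_folds,
                      seed = derive_seed(cfg$seed, "ga-folds"),
                      strata = labels)
  cache <- new.env(parent = emptyenv())
  score <- function(chrom) {
    key <- paste(which(chrom), collapse = ",")
    got <- get0(key, envir = cache)
    if (!is.null(got)) return(got)
    val <- ga_cv_fitness(chrom, x, labels, folds, k, cfg$size_penalty)
    assign(key, val, envir = cache)
    val
  }
  clamp <- function(chrom) {
    on <- which(chrom)
    if (length(on) > cfg$max_subset_size) {
      off <- sample(on, length(on) - cfg$max_subset_size)
      chrom[off] <- FALSE
    }
    if (!any(chrom)) chrom[sample.int(nf, 1L)] <- TRUE
    chrom
  }

  local_seed(cfg$seed, {
    pop <- lapply(seq_len(cfg$population_size), function(i) {
      size <- sample.int(min(cfg$max_subset_size, nf), 1L)
      chrom <- rep(FALSE, nf)
      chrom[sample.int(nf, size)] <- TRUE
      chrom
    })
    fit <- vapply(pop, score, numeric(1))
    history <- numeric(cfg$generations)
    for (g in seq_len(cfg$generations)) {
      elite_idx <- order(fit, decreasing = TRUE)[seq_len(cfg$elitism)]
      newpop <- pop[elite_idx]
      while (length(newpop) < cfg$population_size) {
        pick <- function() {
          cand <- sample.int(cfg$population_size, cfg$tournament_size)
          cand[which.max(fit[cand])]
        }
        p1 <- pop[[pick()]]; p2 <- pop[[pick()]]
        if (stats::runif(1) < cfg$crossover_rate && nf > 1L) {
          cut <- sample.int(nf - 1L, 1L)
          c1 <- c(p1[seq_len(cut)], p2[(cut + 1L):nf])
          c2 <- c(p2[seq_len(cut)], p1[(cut + 1L):nf])
        } else {
          c1 <- p1; c2 <- p2
        }
        for (child in list(c1, c2)) {
          flip <- stats::runif(nf) < mut
          child <- xor(child, flip)
          child <- clamp(child)
          if (length(newpop) < cfg$population_size) {
            newpop[[length(newpop) + 1L]] <- child
          }
        }
      }
      pop <- newpop
      fit <- vapply(pop, score, numeric(1))
      history[g] <- max(fit)
    }
    best <- pop[[which.max(fit)]]
    sel <- colnames(x)[best] %||% which(best)
    structure(list(selected_descriptors = colnames(x)[which(best)],
                   selected_idx = which(best),
                   fitness = score(best) + cfg$size_penalty * sum(best),
                   penalized_fitness = score(best),
                   history = history, folds = folds, config = cfg),
              class = "ga_result")
  })
}

#' @export
print.ga_result <- function(x, ...) {
  cat(sprintf("ga_result: %d descriptors, balanced accuracy %.3f\n",
              length(x$selected_idx), x$fitness))
  if (length(x$selected_descriptors)) {
    cat(paste(x$selected_descriptors, collapse = ", "), "\n")
  }
  invisible(x)
}
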