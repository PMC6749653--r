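# align a feature matrix onto a model's training columns, zero-filling
# columns the query set did not produce (e.g. unseen atom-pair types)
align_features <- function(mat, columns) {
  out <- matrix(0, nrow(mat), length(columns),
                dimnames = list(rownames(mat), columns))
  shared <- intersect(colnames(mat), columns)
  out[, shared] <- mat[, shared, drop = FALSE]
  out
}

#' Pipeline run configuration
#'
#' Collects every knob of a train/predict run so that a run is
#' reproducible from its configuration and seed alone. Serializable to
#' JSON via [jsonlite::toJSON()].
#'
#' @param option Replicate-handling option (1, 2 or 3; default 2).
#' @param frac_train Training fraction (default 0.75).
#' @param algorithm Regressor branch: `"svm"`, `"xgb"` or `"dnn"`.
#' @param regressor_families Feature families for the regressors
#'   (default MACCS + fragment counts).
#' @param router_families Feature families for the router (continuous).
#' @param reduction Feature-reduction level for the regressor matrix
#'   (`"D0"` to skip, default `"D1"`).
#' @param use_ga Run GA descriptor selection for the router (default
#'   `FALSE`; with `TRUE` supply `ga` as a [ga_config()]).
#' @param ga Optional [ga_config()].
#' @param router_k Router neighbour count (`NULL` = CV-selected).
#' @param ad An [ad_params()].
#' @param seed Master seed; child seeds are derived per stage.
#' @param regressor_args Named list of extra arguments passed to the
#'   training function of the chosen branch.
#' @return A `run_config` list.
#' @export
run_config <- function(option = 2L, frac_train = 0.75,
                       algorithm = c("svm", "xgb", "dnn"),
                       regressor_families = c("maccs",
                                              "substructure_counts"),
                       router_families = "continuous_1d2d",
                       reduction = "D1", use_ga = FALSE, ga = NULL,
                       router_k = NULL, ad = ad_params(), seed = 1L,
                       regressor_args = list()) {
  algorithm <- match.arg(algorithm)
  structure(list(option = as.integer(option), frac_train = frac_train,
                 algorithm = algorithm,
                 regressor_families = regressor_families,
                 router_families = router_families,
                 reduction = reduction, use_ga = use_ga, ga = ga,
                 router_k = router_k, ad = ad, seed = as.integer(seed),
                 regressor_args = regressor_args),
            class = "run_config")
}

#' Curate a raw record file into per-option modeling datasets
#'
#' Reads records, standardizes structures, groups replicates, builds the
#' requested option datasets and writes curated CSVs plus a JSON
#' curation report (record counts, rejection reasons, replicate-SD
#' histogram, per-option set sizes).
#'
#' @param input Path to a records file (CSV/TSV/SDF) or a `pka_records`
#'   data.frame.
#' @param output_dir Output directory (created if needed); `NULL` skips
#'   writing.
#' @param options Integer vector of options to build (default 1:3).
#' @return The curation report (list), invisibly the file paths as an
#'   attribute.
#' @export
cmd_curate <- function(input, output_dir = NULL, options = 1:3) {
  records <- if (is.character(input)) read_pka_records(input) else input
  stopifnot(is.data.frame(records))
  std <- standardize_structures(records$smiles, on_parse_error = "reject")
  groups <- group_replicates(records, std)

  rej <- table(std$rejection_reason[std$rejected])
  sd_all <- c(groups$acidic_sd[lengths(groups$acidic_values) >= 3L],
              groups$basic_sd[lengths(groups$basic_values) >= 3L])
  sd_hist <- if (length(sd_all)) {
    breaks <- seq(0, ceiling(max(sd_all)) + 1)
    counts <- as.integer(table(cut(sd_all, breaks, include.lowest = TRUE)))
    list(breaks = breaks, counts = counts)
  } else list(breaks = numeric(0), counts = integer(0))

  report <- list(
    n_records = nrow(records),
    n_rejected = sum(std$rejected),
    rejections = as.list(setNames(as.integer(rej), names(rej))),
    n_unique_structures = nrow(groups),
    n_amphoteric = sum(groups$amphoteric),
    n_acidic_structures = sum(lengths(groups$acidic_values) > 0L),
    n_basic_structures = sum(lengths(groups$basic_values) > 0L),
    replicate_sd_histogram = sd_hist,
    options = list()
  )
  datasets <- list()
  for (op in options) {
    ds <- build_option_dataset(groups, op)
    datasets[[paste0("option", op)]] <- ds
    report$options[[paste0("option", op)]] <-
      lapply(ds, nrow)
  }
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- character(0)
    cur <- groups
    cur$acidic_values <- vapply(cur$acidic_values, paste, character(1),
                                collapse = ";")
    cur$basic_values <- vapply(cur$basic_values, paste, character(1),
                               collapse = ";")
    p <- file.path(output_dir, "curated_structures.csv")
    utils::write.csv(cur, p, row.names = FALSE, na = "")
    paths <- c(paths, p)
    for (op_name in names(datasets)) {
      for (sub in names(datasets[[op_name]])) {
        p <- file.path(output_dir, paste0(op_name, "_", sub, ".csv"))
        utils::write.csv(as.data.frame(datasets[[op_name]][[sub]]), p,
                         row.names = FALSE)
        paths <- c(paths, p)
      }
    }
    jsonlite::write_json(report,
                         file.path(output_dir, "curation_report.json"),
                         auto_unbox = TRUE, digits = NA)
    attr(report, "paths") <- paths
  }
  attr(report, "datasets") <- datasets
  attr(report, "groups") <- groups
  invisible(report)
}

#' Train the full pKa prediction bundle
#'
#' Orchestrates curation outputs into a deployable bundle: stratified
#' split, router training (optionally GA descriptor selection) on the
#' acidic/basic/amphoteric labels of the chosen option's structures,
#' one regressor per class, and applicability-domain models (global
#' leverage on the router descriptors, local Tanimoto on MACCS keys).
#'
#' @param records A `pka_records` data.frame (raw; curated internally),
#'   or a curation report from [cmd_curate()].
#' @param config A [run_config()].
#' @return A `pka_model_bundle` list.
#' @export
cmd_train <- function(records, config = run_config()) {
  report <- if (is.data.frame(records)) {
    cmd_curate(records, output_dir = NULL, options = config$option)
  } else records
  groups <- attr(report, "groups")
  ds <- attr(report, "datasets")[[paste0("option", config$option)]]

  acidic <- split_train_test(ds$acidic, config$frac_train,
                             seed = derive_seed(config$seed, "split-a"))
  basic <- split_train_test(ds$basic, config$frac_train,
                            seed = derive_seed(config$seed, "split-b"))

  # router training set: one row per structure in either dataset
  keys <- unique(c(acidic$structure_key, basic$structure_key))
  in_a <- keys %in% acidic$structure_key
  in_b <- keys %in% basic$structure_key
  router_labels <- ifelse(in_a & in_b, "amphoteric",
                          ifelse(in_a, "acidic", "basic"))
  smiles_of <- groups$canonical_smiles[match(keys, groups$structure_key)]
  router_fm <- compute_features(setNames(smiles_of, keys),
                                families = config$router_families)
  rkeys <- rownames(router_fm$values)
  rlabels <- router_labels[match(rkeys, keys)]

  subset <- NULL
  ga_result <- NULL
  if (isTRUE(config$use_ga)) {
    cfg <- config$ga %||% ga_config(seed = derive_seed(config$seed, "ga"))
    ga_result <- ga_select(router_fm, rlabels, cfg)
    subset <- ga_result$selected_descriptors
  }
  router <- fit_router(router_fm, rlabels, k = config$router_k,
                       descriptor_subset = subset,
                       seed = derive_seed(config$seed, "router"))

  train_branch <- function(ds_cls, label) {
    tr <- ds_cls[ds_cls$split == "train", ]
    te <- ds_cls[ds_cls$split == "test", ]
    fm <- compute_features(
      setNames(c(tr$canonical_smiles, te$canonical_smiles),
               c(tr$structure_key, te$structure_key)),
      families = config$regressor_families)
    if (config$reduction != "D0") {
      fm <- reduce_features(fm, config$reduction)
    }
    xtr <- fm$values[tr$structure_key, , drop = FALSE]
    xte <- fm$values[te$structure_key, , drop = FALSE]
    scaling <- NULL
    if (config$algorithm == "dnn") {
      scaling <- fit_scaling(xtr)
      xtr <- apply_scaling(xtr, scaling)
      xte <- apply_scaling(xte, scaling)
    }
    seed_b <- derive_seed(config$seed, paste0("reg-", label))
    args <- c(list(xtr, tr$pka, seed = seed_b), config$regressor_args)
    model <- switch(config$algorithm,
                    svm = do.call(train_svm, args),
                    xgb = do.call(train_xgb, args),
                    dnn = do.call(train_dnn, args))
    test_pred <- predict(model, xte)
    test_metrics <- compute_metrics(te$pka, test_pred)
    # AD: global on the regressor features, local on MACCS keys
    fp <- compute_features(
      setNames(tr$canonical_smiles, tr$structure_key),
      families = "maccs")
    global_model <- fit_global_ad(xtr, config$ad)
    list(model = model, scaling = scaling,
         train = tr, test = te,
         train_pred = predict(model, xtr),
         test_metrics = test_metrics,
         global_ad = global_model,
         local_fps = fp$values[tr$structure_key, , drop = FALSE],
         columns = colnames(xtr))
  }

  branch_a <- train_branch(acidic, "acidic")
  branch_b <- train_branch(basic, "basic")

  structure(list(config = config, router = router,
                 ga_result = ga_result,
                 acidic = branch_a, basic = branch_b,
                 groups_n = nrow(groups)),
            class = "pka_model_bundle")
}

#' @export
print.pka_model_bundle <- function(x, ...) {
  cat(sprintf("pka_model_bundle [%s, option %d]\n", x$config$algorithm,
              x$config$option))
  cat(sprintf("  acidic: n=%d test RMSE %.2f | basic: n=%d test RMSE %.2f\n",
              nrow(x$acidic$train), x$acidic$test_metrics$rmse,
              nrow(x$basic$train), x$basic$test_metrics$rmse))
  invisible(x)
}

#' Predict pKa for new structures through the full routing flow
#'
#' Standardizes each input, checks ionizability, routes through the kNN
#' classifier, applies the acidic and/or basic regressor, and attaches
#' applicability-domain fields (global leverage flag, local Tanimoto
#' index, accuracy estimate, nearest-neighbour keys) per predicted
#' class.
#'
#' @param bundle A `pka_model_bundle` from [cmd_train()].
#' @param smiles Character vector of query SMILES.
#' @return A data.frame with one row per input: standardization status,
#'   ionizability, routed class, per-class predictions and AD fields.
#' @export
cmd_predict <- function(bundle, smiles) {
  stopifnot(inherits(bundle, "pka_model_bundle"))
  std <- standardize_structures(smiles, on_parse_error = "reject")
  n <- nrow(std)
  out <- data.frame(smiles = smiles,
                    canonical_smiles = std$canonical_smiles,
                    structure_key = std$structure_key,
                    status = ifelse(std$rejected,
                                    paste0("rejected:",
                                           std$rejection_reason), "ok"),
                    ionizable = NA, class = NA_character_,
                    pka_acidic = NA_real_, pka_basic = NA_real_,
                    stringsAsFactors = FALSE)
  ad_cols <- c("global_inside", "leverage", "local_index",
               "accuracy_estimate", "neighbor_keys")
  for (cls in c("acidic", "basic")) {
    for (col in ad_cols) out[[paste0(cls, "_", col)]] <- NA
  }
  ok <- which(!std$rejected)
  if (!length(ok)) return(out)
  out$ionizable[ok] <- is_ionizable(std$canonical_smiles[ok])
  idx <- ok[which(out$ionizable[ok])]
  if (!length(idx)) return(out)

  rq <- compute_features(setNames(std$canonical_smiles[idx],
                                  std$structure_key[idx]),
                         families = bundle$config$router_families)
  # router applies its stored training scaling to raw descriptor values
  qx_raw <- align_features(rq$values, names(bundle$router$center))
  out$class[idx] <- predict(bundle$router, qx_raw)

  fq <- compute_features(setNames(std$canonical_smiles[idx],
                                  std$structure_key[idx]),
                         families = bundle$config$regressor_families)
  fp <- compute_features(setNames(std$canonical_smiles[idx],
                                  std$structure_key[idx]),
                         families = "maccs")
  for (cls in c("acidic", "basic")) {
    branch <- bundle[[cls]]
    want <- idx[out$class[idx] %in% c(cls, "amphoteric")]
    if (!length(want)) next
    keys <- std$structure_key[want]
    x <- align_features(fq$values, branch$columns)[keys, , drop = FALSE]
    if (!is.null(branch$scaling)) x <- apply_scaling(x, branch$scaling)
    pred <- predict(branch$model, x)
    out[[paste0("pka_", cls)]][want] <- pred
    gad <- global_ad(branch$global_ad, x)
    out[[paste0(cls, "_global_inside")]][want] <- gad$inside
    out[[paste0(cls, "_leverage")]][want] <- gad$leverage
    qfp <- align_features(fp$values, colnames(branch$local_fps))
    for (j in seq_along(want)) {
      lad <- local_ad(branch$local_fps, branch$train$pka,
                      qfp[keys[j], ], bundle$config$ad,
                      predicted_train = branch$train_pred)
      out[[paste0(cls, "_local_index")]][want[j]] <- lad$local_index
      out[[paste0(cls, "_accuracy_estimate")]][want[j]] <-
        lad$accuracy_estimate
      out[[paste0(cls, "_neighbor_keys")]][want[j]] <-
        paste(lad$neighbors$key, collapse = ";")
    }
  }
  out
}

#' Concordance benchmarking between two prediction tables
#'
#' Runs the pairwise +/-threshold concordance analysis for one class,
#' builds the averaged benchmark table, optionally applies a pKa range
#' filter, and attaches bootstrap confidence intervals.
#'
#' @param a,b `prediction_table` objects or CSV paths.
#' @param cls `"acidic"` or `"basic"`.
#' @param threshold Concordance threshold (default 2 pKa units).
#' @param range Optional `c(lo, hi)` range filter for the benchmark.
#' @param n_boot Bootstrap resamples for the CIs (default 5000).
#' @param seed Seed for the bootstrap.
#' @param output Optional path for a JSON report.
#' @return A list: `report` (`concordance_report`), `benchmark`
#'   (`prediction_table`), `benchmark_filtered` (if `range` given),
#'   `ci_r2`, `ci_rmse`.
#' @export
cmd_benchmark <- function(a, b, cls = c("acidic", "basic"),
                          threshold = 2.0, range = NULL, n_boot = 5000L,
                          seed = 1L, output = NULL) {
  cls <- match.arg(cls)
  if (is.character(a)) a <- read_prediction_table(a)
  if (is.character(b)) b <- read_prediction_table(b)
  rep_ <- pairwise_concordance(a, b, cls, threshold)
  bench <- build_benchmark(a, b, cls, threshold)
  res <- list(report = rep_, benchmark = bench)
  if (!is.null(range)) {
    res$benchmark_filtered <- range_filter(bench, cls, range[1], range[2])
  }
  if (rep_$n_common >= 10L) {
    common <- intersect(a$structure_key, b$structure_key)
    va <- pick_class_column(a, cls)[match(common, a$structure_key)]
    vb <- pick_class_column(b, cls)[match(common, b$structure_key)]
    keep <- !is.na(va) & !is.na(vb)
    res$ci_r2 <- bootstrap_ci(va[keep], vb[keep], "r2", n_boot = n_boot,
                              seed = seed)
    res$ci_rmse <- bootstrap_ci(va[keep], vb[keep], "rmse",
                                n_boot = n_boot, seed = seed)
  }
  if (!is.null(output)) {
    payload <- list(
      class = cls, threshold = threshold,
      n_common = rep_$n_common, n_within = rep_$n_within,
      n_beyond = rep_$n_beyond, r2 = rep_$r2,
      pearson_r2 = rep_$pearson_r2, rmse = rep_$rmse,
      n_benchmark = nrow(bench),
      n_benchmark_filtered = if (!is.null(res$benchmark_filtered)) {
        nrow(res$benchmark_filtered)
      } else NULL,
      ci_r2 = res$ci_r2, ci_rmse = res$ci_rmse)
    jsonlite::write_json(payload, output, auto_unbox = TRUE, digits = NA)
  }
  res
}

#' Save / load a trained model bundle
#'
#' The bundle directory holds a JSON metadata file (algorithm, option,
#' feature families, seeds) and the serialized model objects. Reloaded
#' bundles reproduce predictions exactly.
#'
#' @param bundle A `pka_model_bundle`.
#' @param dir Bundle directory.
#' @return `save_model_bundle` returns `dir` invisibly;
#'   `load_model_bundle` returns the bundle.
#' @export
save_model_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "pka_model_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(algorithm = bundle$config$algorithm,
               option = bundle$config$option,
               regressor_families = bundle$config$regressor_families,
               router_families = bundle$config$router_families,
               reduction = bundle$config$reduction,
               seed = bundle$config$seed,
               package_version = as.character(utils::packageVersion("pkaqsar")))
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  for (cls in c("acidic", "basic")) {
    br <- bundle[[cls]]
    if (br$model$algorithm == "xgb") {
      raw <- xgboost::xgb.save.raw(br$model$fit)
      br$model$fit <- NULL
      br$model$fit_raw <- raw
      bundle[[cls]] <- br
    }
  }
  saveRDS(bundle, file.path(dir, "bundle.rds"))
  invisible(dir)
}

#' @param dir Bundle directory written by [save_model_bundle()].
#' @rdname save_model_bundle
#' @export
load_model_bundle <- function(dir) {
  bundle <- readRDS(file.path(dir, "bundle.rds"))
  for (cls in c("acidic", "basic")) {
    br <- bundle[[cls]]
    if (br$model$algorithm == "xgb" && !is.null(br$model$fit_raw)) {
      br$model$fit <- xgboost::xgb.load.raw(br$model$fit_raw)
      br$model$fit_raw <- NULL
      bundle[[cls]] <- br
    }
  }
  bundle
}
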