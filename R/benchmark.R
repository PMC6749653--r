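#' Construct a prediction table
#'
#' One row per structure with the strongest acidic and/or strongest basic
#' macroscopic pKa predicted (or measured) by one source. Every retained
#' row must carry at least one of the two values.
#'
#' @param structure_key Character vector of standardized structure keys.
#' @param acidic_pka,basic_pka Numeric vectors (NA when absent).
#' @param source Label of the predictor/data source.
#' @param smiles Optional SMILES column.
#' @return A `prediction_table` data.frame.
#' @export
prediction_table <- function(structure_key, acidic_pka = NULL,
                             basic_pka = NULL, source = "unknown",
                             smiles = NULL) {
  n <- length(structure_key)
  acidic_pka <- if (is.null(acidic_pka)) rep(NA_real_, n) else as.numeric(acidic_pka)
  basic_pka <- if (is.null(basic_pka)) rep(NA_real_, n) else as.numeric(basic_pka)
  stopifnot(length(acidic_pka) == n, length(basic_pka) == n)
  if (any(is.na(acidic_pka) & is.na(basic_pka))) {
    stop("every row needs at least one of acidic_pka / basic_pka")
  }
  if (anyDuplicated(structure_key)) stop("duplicate structure keys")
  out <- data.frame(structure_key = as.character(structure_key),
                    acidic_pka = acidic_pka, basic_pka = basic_pka,
                    source = source, stringsAsFactors = FALSE)
  if (!is.null(smiles)) out$smiles <- smiles
  class(out) <- c("prediction_table", "data.frame")
  out
}

#' Read a prediction table from CSV
#'
#' Expects columns `structure_key` (or `smiles`, standardized on the
#' fly), `acidic_pka`, `basic_pka`, optionally `source`.
#' @param path CSV path.
#' @param source Source label override.
#' @export
read_prediction_table <- function(path, source = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  if (!"structure_key" %in% names(df)) {
    if (!"smiles" %in% names(df)) {
      stop("prediction table needs structure_key or smiles")
    }
    std <- standardize_structures(df$smiles, on_parse_error = "reject")
    df$structure_key <- std$structure_key
    df <- df[!std$rejected, , drop = FALSE]
  }
  prediction_table(df$structure_key,
                   df[["acidic_pka"]], df[["basic_pka"]],
                   source = source %||% (df[["source"]][1] %||% "file"),
                   smiles = df[["smiles"]])
}

pick_class_column <- function(t, cls) {
  if (cls == "acidic") t$acidic_pka else t$basic_pka
}

#' Pairwise prediction concordance within a pKa threshold
#'
#' Joins two prediction tables on the structure key, keeps rows where
#' both carry a value for the requested class, and counts predictions
#' agreeing within the threshold (|delta| <= threshold counts as
#' concordant). Metrics are computed on the common rows with table `a`
#' as the reference: `r2` is the coefficient of determination of b
#' against a, `pearson_r2` the squared correlation, `rmse` the root mean
#' squared difference.
#'
#' @param a,b `prediction_table` objects.
#' @param cls `"acidic"` or `"basic"`.
#' @param threshold Concordance threshold in pKa units (default 2).
#' @return A `concordance_report` list with counts, metrics, and the
#'   concordant subset (`$concordant`, a data.frame with both values).
#' @export
pairwise_concordance <- function(a, b, cls = c("acidic", "basic"),
                                 threshold = 2.0) {
  cls <- match.arg(cls)
  stopifnot(inherits(a, "prediction_table"), inherits(b, "prediction_table"))
  assert_scalar_number(threshold, "threshold", lo = 0)
  common <- intersect(a$structure_key, b$structure_key)
  va <- pick_class_column(a, cls)[match(common, a$structure_key)]
  vb <- pick_class_column(b, cls)[match(common, b$structure_key)]
  ok <- !is.na(va) & !is.na(vb)
  common <- common[ok]; va <- va[ok]; vb <- vb[ok]
  if (length(common) == 0L) stop("no common structures with a ", cls,
                                 " value in both tables")
  delta <- abs(va - vb)
  within <- delta <= threshold
  metrics <- if (length(common) >= 2L && stats::var(va) > 0) {
    m <- compute_metrics(va, vb)
    list(r2 = m$r2, pearson_r2 = suppressWarnings(stats::cor(va, vb))^2,
         rmse = m$rmse)
  } else {
    list(r2 = NA_real_, pearson_r2 = NA_real_,
         rmse = sqrt(mean((va - vb)^2)))
  }
  concordant <- data.frame(structure_key = common[within],
                           value_a = va[within], value_b = vb[within],
                           stringsAsFactors = FALSE)
  structure(list(class = cls, threshold = threshold,
                 source_a = a$source[1], source_b = b$source[1],
                 n_common = length(common),
                 n_within = sum(within), n_beyond = sum(!within),
                 r2 = metrics$r2, pearson_r2 = metrics$pearson_r2,
                 rmse = metrics$rmse, concordant = concordant),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("concordance [%s, |delta| <= %g]: %s vs %s\n", x$class,
              x$threshold, x$source_a, x$source_b))
  cat(sprintf("  common %d | within %d | beyond %d\n", x$n_common,
              x$n_within, x$n_beyond))
  cat(sprintf("  R2 %.3f | r2 %.3f | RMSE %.3f\n", x$r2, x$pearson_r2,
              x$rmse))
  invisible(x)
}

#' Build a benchmark table by averaging concordant predictions
#'
#' Structures whose two predictions agree within the threshold get the
#' mean of the two values; provenance is recorded in the source label.
#'
#' @inheritParams pairwise_concordance
#' @return A `prediction_table` carrying the averaged class values.
#' @export
build_benchmark <- function(a, b, cls = c("acidic", "basic"),
                            threshold = 2.0) {
  cls <- match.arg(cls)
  rep_ <- pairwise_concordance(a, b, cls, threshold)
  cc <- rep_$concordant
  avg <- (cc$value_a + cc$value_b) / 2
  prediction_table(cc$structure_key,
                   acidic_pka = if (cls == "acidic") avg else NULL,
                   basic_pka = if (cls == "basic") avg else NULL,
                   source = paste0("mean(", rep_$source_a, ",",
                                   rep_$source_b, ")"))
}

#' Filter a prediction table to a pKa range
#'
#' Rows whose value for the requested class lies in \[lo, hi\] are kept;
#' rows lacking that class value are dropped.
#'
#' @param t A `prediction_table`.
#' @param cls `"acidic"` or `"basic"`.
#' @param lo,hi Range bounds (inclusive).
#' @return The filtered `prediction_table`.
#' @export
range_filter <- function(t, cls = c("acidic", "basic"), lo, hi) {
  cls <- match.arg(cls)
  stopifnot(inherits(t, "prediction_table"))
  if (lo > hi) stop("`lo` must not exceed `hi`")
  v <- pick_class_column(t, cls)
  keep <- !is.na(v) & v >= lo & v <= hi
  out <- t[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("prediction_table", "data.frame")
  out
}

#' Percentile bootstrap confidence interval for concordance metrics
#'
#' Paired resampling with replacement; the metric is recomputed on each
#' resample and the interval taken from the percentiles. Resamples on
#' which the metric is undefined (zero variance in the observed draw)
#' are redrawn; the number of redraws is reported as an attribute.
#'
#' @param observed,predicted Paired numeric vectors (n >= 10).
#' @param metric `"r2"`, `"pearson_r2"` or `"rmse"`.
#' @param n_boot Number of bootstrap resamples (default 5000).
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed; intervals are reproducible per seed.
#' @return Numeric vector `c(lo, hi)` with attribute `"redraws"`.
#' @export
bootstrap_ci <- function(observed, predicted,
                         metric = c("r2", "pearson_r2", "rmse"),
                         n_boot = 5000L, level = 0.95, seed = 1L) {
  metric <- match.arg(metric)
  stopifnot(length(observed) == length(predicted))
  if (length(observed) < 10L) stop("need at least 10 pairs")
  n <- length(observed)
  stat <- function(o, p) {
    switch(metric,
           r2 = { if (stats::var(o) == 0) return(NA_real_)
                  1 - sum((o - p)^2) / sum((o - mean(o))^2) },
           pearson_r2 = { if (stats::var(o) == 0 || stats::var(p) == 0)
                            return(NA_real_)
                          stats::cor(o, p)^2 },
           rmse = sqrt(mean((o - p)^2)))
  }
  vals <- numeric(n_boot)
  redraws <- 0L
  local_seed(seed, {
    for (b in seq_len(n_boot)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        v <- stat(observed[idx], predicted[idx])
        if (!is.na(v)) break
        redraws <- redraws + 1L
        if (redraws > 100L * n_boot) stop("metric undefined on resamples")
      }
      vals[b] <- v
    }
  })
  alpha <- (1 - level) / 2
  ci <- unname(stats::quantile(vals, c(alpha, 1 - alpha)))
  attr(ci, "redraws") <- redraws
  ci
}
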