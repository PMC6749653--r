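#' Group standardized records into per-structure replicate groups
#'
#' Records sharing a structure key are collapsed into one replicate group,
#' with acidic and basic measurements kept separately (deduplication is
#' performed per class). A group holding both an acidic and a basic value
#' is amphoteric. Sample standard deviations (n-1 denominator) are
#' reported per class whenever a class has two or more values.
#'
#' @param records A `pka_records` data.frame (see [pka_records()]).
#' @param standardized Optional result of [standardize_structures()] on
#'   `records$smiles`; computed if omitted. Rejected rows are excluded.
#' @return A data.frame of class `replicate_groups` with one row per
#'   structure key: `structure_key`, `canonical_smiles`, list columns
#'   `acidic_values` and `basic_values`, `acidic_sd`, `basic_sd`
#'   (`NA` unless >= 2 values), and `amphoteric`.
#' @export
group_replicates <- function(records, standardized = NULL) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0L) {
    out <- data.frame(structure_key = character(0),
                      canonical_smiles = character(0),
                      amphoteric = logical(0))
    out$acidic_values <- list(); out$basic_values <- list()
    out$acidic_sd <- numeric(0); out$basic_sd <- numeric(0)
    class(out) <- c("replicate_groups", "data.frame")
    return(out)
  }
  if (is.null(standardized)) {
    standardized <- standardize_structures(records$smiles,
                                           on_parse_error = "reject")
  }
  stopifnot(nrow(standardized) == nrow(records))
  ok <- !standardized$rejected
  key <- standardized$structure_key[ok]
  smi <- standardized$canonical_smiles[ok]
  pka <- records$pka[ok]
  cls <- records$class[ok]

  ukeys <- unique(key)
  acidic_values <- vector("list", length(ukeys))
  basic_values <- vector("list", length(ukeys))
  can <- character(length(ukeys))
  for (j in seq_along(ukeys)) {
    sel <- key == ukeys[j]
    can[j] <- smi[sel][1]
    acidic_values[[j]] <- pka[sel & cls == "acidic"]
    basic_values[[j]] <- pka[sel & cls == "basic"]
  }
  sd_or_na <- function(v) if (length(v) >= 2L) stats::sd(v) else NA_real_
  out <- data.frame(structure_key = ukeys, canonical_smiles = can,
                    stringsAsFactors = FALSE)
  out$acidic_values <- acidic_values
  out$basic_values <- basic_values
  out$acidic_sd <- vapply(acidic_values, sd_or_na, numeric(1))
  out$basic_sd <- vapply(basic_values, sd_or_na, numeric(1))
  out$amphoteric <- lengths(acidic_values) > 0L & lengths(basic_values) > 0L
  class(out) <- c("replicate_groups", "data.frame")
  out
}

# resolve one class of one group under a given option; returns numeric(0)
# when the group is not admitted
resolve_class_value <- function(values, sdv, option, cls) {
  n <- length(values)
  if (n == 0L) return(numeric(0))
  if (option == 1L) {
    if (n == 1L) return(values) else return(numeric(0))
  }
  if (option == 2L) {
    if (n == 1L) return(values)
    if (!is.na(sdv) && sdv < 2) return(mean(values))
    return(numeric(0))
  }
  # option 3: average when SD <= 1, otherwise strongest value
  if (n == 1L) return(values)
  if (!is.na(sdv) && sdv <= 1) return(mean(values))
  if (cls == "acidic") min(values) else max(values)
}

#' Build per-option modeling datasets from replicate groups
#'
#' Three replicate-handling policies are supported. Option 1 keeps only
#' groups whose present classes are singletons (one acidic and/or one
#' basic value). Option 2 additionally admits replicate groups whose
#' per-class sample SD is below 2 pKa units, using the mean. Option 3
#' admits every group: values are averaged when the SD is at most 1 pKa
#' unit, otherwise the strongest value is taken (minimum for acidic,
#' maximum for basic). For Options 1-2 a combined dataset is also built
#' from the non-amphoteric admitted groups.
#'
#' @param groups A `replicate_groups` data.frame from [group_replicates()].
#' @param option Integer 1, 2 or 3.
#' @return A list with elements `acidic`, `basic` and (Options 1-2)
#'   `combined`, each a `pka_dataset` data.frame with columns
#'   `structure_key`, `canonical_smiles`, `pka`, `class`, `n_values`,
#'   `replicate`, `amphoteric`.
#' @export
build_option_dataset <- function(groups, option) {
  stopifnot(inherits(groups, "replicate_groups"))
  if (!option %in% 1:3) stop("`option` must be 1, 2 or 3")
  option <- as.integer(option)

  if (option == 1L) {
    # only singleton-per-class groups are admitted at all
    admit <- lengths(groups$acidic_values) <= 1L &
      lengths(groups$basic_values) <= 1L
    groups <- groups[admit, , drop = FALSE]
  }

  make_ds <- function(cls) {
    vals <- if (cls == "acidic") groups$acidic_values else groups$basic_values
    sds <- if (cls == "acidic") groups$acidic_sd else groups$basic_sd
    pka <- numeric(0); idx <- integer(0)
    for (j in seq_len(nrow(groups))) {
      v <- resolve_class_value(vals[[j]], sds[j], option, cls)
      if (length(v) == 1L) { pka <- c(pka, v); idx <- c(idx, j) }
    }
    out <- data.frame(structure_key = groups$structure_key[idx],
                      canonical_smiles = groups$canonical_smiles[idx],
                      pka = pka, class = rep(cls, length(idx)),
                      n_values = lengths(vals[idx]),
                      replicate = lengths(vals[idx]) > 1L,
                      amphoteric = groups$amphoteric[idx],
                      stringsAsFactors = FALSE)
    attr(out, "option") <- option
    attr(out, "subset") <- cls
    class(out) <- c("pka_dataset", "data.frame")
    out
  }

  acidic <- make_ds("acidic")
  basic <- make_ds("basic")
  res <- list(acidic = acidic, basic = basic)
  if (option %in% c(1L, 2L)) {
    comb <- rbind(acidic[!acidic$amphoteric, , drop = FALSE],
                  basic[!basic$amphoteric, , drop = FALSE])
    rownames(comb) <- NULL
    attr(comb, "option") <- option
    attr(comb, "subset") <- "combined"
    class(comb) <- c("pka_dataset", "data.frame")
    res$combined <- comb
  }
  res
}

#' Stratified train/test split preserving the pKa distribution
#'
#' Entries are stratified on 1-pKa-unit bins crossed with the replicate
#' and amphoteric flags (and the acidic/basic class for combined sets),
#' then allocated to train/test within each stratum by a seeded shuffle.
#' A largest-remainder allocation makes the overall training fraction
#' exact (up to rounding) while every stratum stays close to it.
#'
#' @param ds A `pka_dataset` data.frame.
#' @param frac_train Training fraction in (0, 1); default 0.75.
#' @param seed Integer seed; the split is reproducible per seed.
#' @return `ds` with an added `split` column (`"train"`/`"test"`).
#' @export
split_train_test <- function(ds, frac_train = 0.75, seed = 1L) {
  stopifnot(inherits(ds, "pka_dataset"))
  if (nrow(ds) == 0L) stop("dataset is empty")
  assert_scalar_number(frac_train, "frac_train")
  if (frac_train <= 0 || frac_train >= 1) {
    stop("`frac_train` must be strictly between 0 and 1")
  }
  strata <- paste(floor(ds$pka), ds$replicate, ds$amphoteric, ds$class,
                  sep = "|")
  n <- nrow(ds)
  n_train_total <- round(frac_train * n)
  tab <- table(strata)
  raw <- as.numeric(tab) * frac_train
  base <- floor(raw)
  rem <- raw - base
  shortfall <- n_train_total - sum(base)
  # distribute leftovers to strata with the largest fractional parts
  # (name order breaks exact ties deterministically)
  ord <- order(rem, names(tab), decreasing = TRUE)
  extra <- integer(length(tab))
  if (shortfall > 0) extra[ord[seq_len(shortfall)]] <- 1L
  alloc <- setNames(base + extra, names(tab))

  split <- rep("test", n)
  local_seed(seed, {
    for (s in names(tab)) {
      idx <- which(strata == s)
      idx <- idx[sample.int(length(idx))]
      split[idx[seq_len(alloc[[s]])]] <- "train"
    }
  })
  ds$split <- split
  ds
}
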