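#' Applicability-domain parameters
#'
#' @param k_neighbors Neighbours used by the local index (default 5).
#' @param leverage_threshold_multiplier Multiplier m in the global
#'   leverage threshold h* = m * p / n (default 3, the classical rule).
#' @param similarity_floor Neighbours with Tanimoto similarity below this
#'   floor are ignored by the local index (default 0).
#' @return An `ad_params` list.
#' @export
ad_params <- function(k_neighbors = 5L, leverage_threshold_multiplier = 3,
                      similarity_floor = 0) {
  stopifnot(k_neighbors >= 1L, leverage_threshold_multiplier > 0,
            similarity_floor >= 0, similarity_floor <= 1)
  structure(list(k_neighbors = as.integer(k_neighbors),
                 leverage_threshold_multiplier = leverage_threshold_multiplier,
                 similarity_floor = similarity_floor),
            class = "ad_params")
}

#' Fit the global (leverage-based) applicability domain
#'
#' Leverages are hat-matrix diagonals h = x (X'X)^-1 x' on the centered
#' training design. When the feature count exceeds the row count (or X'X
#' is otherwise ill-conditioned) the design is first projected onto
#' principal components retaining `var_explained` of the variance, and a
#' pseudo-inverse is used as a fallback. A query is inside the domain
#' when h <= h* = multiplier * p / n with p the effective dimension.
#'
#' @param train_fm Training features (`pka_features` or matrix).
#' @param params An [ad_params()] object.
#' @param var_explained Variance retained by the PCA projection when
#'   p > n (default 0.95).
#' @return A `global_ad_model` with elements `center`, `rotation`
#'   (possibly identity), `xtx_inv`, `h_star`, `p`, `n`,
#'   `train_leverage`.
#' @export
fit_global_ad <- function(train_fm, params = ad_params(),
                          var_explained = 0.95) {
  x <- as_feature_matrix(train_fm)
  n <- nrow(x)
  center <- colMeans(x)
  xc <- sweep(x, 2, center)
  rotation <- NULL
  if (ncol(xc) >= n) {
    pc <- stats::prcomp(xc, center = FALSE)
    cum <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
    keep <- max(1L, min(which(cum >= var_explained)))
    keep <- min(keep, n - 1L)
    rotation <- pc$rotation[, seq_len(keep), drop = FALSE]
    xc <- xc %*% rotation
  }
  xtx <- crossprod(xc)
  xtx_inv <- tryCatch(solve(xtx), error = function(e) MASS::ginv(xtx))
  p <- qr(xc)$rank
  h_star <- params$leverage_threshold_multiplier * p / n
  train_lev <- rowSums((xc %*% xtx_inv) * xc)
  structure(list(center = center, rotation = rotation,
                 xtx_inv = xtx_inv, p = p, n = n, h_star = h_star,
                 train_leverage = train_lev),
            class = "global_ad_model")
}

#' Global applicability-domain check for query structures
#'
#' @param model A `global_ad_model` from [fit_global_ad()], or a training
#'   feature matrix (in which case the model is fit on the fly).
#' @param query_fm Query features on the same columns.
#' @param params An [ad_params()]; used only when `model` is a matrix.
#' @return A data.frame with `leverage` and `inside` per query row.
#' @export
global_ad <- function(model, query_fm, params = ad_params()) {
  if (!inherits(model, "global_ad_model")) {
    model <- fit_global_ad(model, params)
  }
  q <- as_feature_matrix(query_fm)
  qc <- sweep(q, 2, model$center)
  if (!is.null(model$rotation)) qc <- qc %*% model$rotation
  lev <- rowSums((qc %*% model$xtx_inv) * qc)
  data.frame(leverage = lev, inside = lev <= model$h_star)
}

#' Jaccard-Tanimoto similarity between two binary fingerprints
#'
#' Intersection over union of on-bits. By convention two all-zero
#' fingerprints have similarity 1.
#'
#' @param fp_a,fp_b Equal-length binary (0/1) vectors.
#' @return Similarity in \[0, 1\].
#' @export
tanimoto_similarity <- function(fp_a, fp_b) {
  if (length(fp_a) != length(fp_b)) {
    stop("fingerprints differ in length (", length(fp_a), " vs ",
         length(fp_b), ")")
  }
  if (!all(fp_a %in% c(0, 1)) || !all(fp_b %in% c(0, 1))) {
    stop("fingerprints must be binary 0/1 vectors")
  }
  inter <- sum(fp_a == 1 & fp_b == 1)
  union <- sum(fp_a == 1 | fp_b == 1)
  if (union == 0L) return(1)
  inter / union
}

# similarity of one query against all rows of a binary matrix
tanimoto_to_all <- function(train_fps, query_fp) {
  inter <- as.numeric(train_fps %*% query_fp)
  union <- rowSums(train_fps) + sum(query_fp) - inter
  sim <- ifelse(union == 0, 1, inter / union)
  sim
}

#' Local (similarity-based) applicability domain and accuracy estimate
#'
#' The local index is the mean Tanimoto similarity of the k most similar
#' training fingerprints (after applying the similarity floor). The
#' accuracy estimate is the similarity-weighted mean absolute residual
#' (experimental minus predicted) of those neighbours, in pKa units; it
#' requires `predicted_train`.
#'
#' @param train_fps Binary fingerprint matrix of the training set
#'   (`pka_features` or matrix; rows named by structure key).
#' @param train_pka Experimental pKa of each training row.
#' @param query_fp Binary fingerprint vector of the query.
#' @param params An [ad_params()].
#' @param predicted_train Optional model predictions for the training
#'   rows; without them the accuracy estimate is `NA`.
#' @return A list: `local_index`, `accuracy_estimate`, `neighbors`
#'   (data.frame with key, similarity, pka).
#' @export
local_ad <- function(train_fps, train_pka, query_fp,
                     params = ad_params(), predicted_train = NULL) {
  m <- as_feature_matrix(train_fps)
  stopifnot(length(train_pka) == nrow(m))
  if (params$k_neighbors > nrow(m)) {
    stop("k_neighbors exceeds training size")
  }
  sim <- tanimoto_to_all(m, query_fp)
  ord <- order(sim, -seq_along(sim), decreasing = TRUE)
  nn <- ord[seq_len(params$k_neighbors)]
  keep <- sim[nn] >= params$similarity_floor
  nn_used <- nn[keep]
  local_index <- if (length(nn_used)) mean(sim[nn_used]) else 0
  acc <- NA_real_
  if (!is.null(predicted_train) && length(nn_used)) {
    resid <- abs(train_pka[nn_used] - predicted_train[nn_used])
    w <- sim[nn_used]
    acc <- if (sum(w) > 0) sum(w * resid) / sum(w) else mean(resid)
  }
  neighbors <- data.frame(
    key = if (!is.null(rownames(m))) rownames(m)[nn] else as.character(nn),
    similarity = sim[nn], pka = train_pka[nn],
    stringsAsFactors = FALSE)
  list(local_index = local_index, accuracy_estimate = acc,
       neighbors = neighbors)
}
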