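#' Ionizability check from hydrogen-bond donor/acceptor sites
#'
#' A structure is considered ionizable when it carries at least one
#' hydrogen-bond donor (any O-H or N-H) or acceptor site; pKa prediction
#' is only meaningful for such structures. Donor and acceptor counts come
#' from OpenBabel's Lipinski-style typing.
#'
#' @param smiles Character vector of (standardized) SMILES.
#' @return Logical vector; errors on unparsable input.
#' @export
is_ionizable <- function(smiles) {
  stopifnot(is.character(smiles))
  vapply(smiles, function(s) {
    pr <- tryCatch(
      ChemmineOB::forEachMol("SMILES", s, function(m) {
        ChemmineOB::prop_OB(list(m))
      })[[1]],
      error = function(e) NULL)
    if (is.null(pr)) stop("unparsable SMILES: ", s)
    (pr$HBD + pr$HBA1) > 0
  }, logical(1), USE.NAMES = FALSE)
}

#' Fit the kNN acid/base/amphoteric router
#'
#' Stores z-scored training descriptors restricted to `descriptor_subset`
#' and classifies queries by the majority vote of the k nearest training
#' structures under Euclidean distance, with ties broken by the class of
#' the single nearest neighbour. When `k` is `NULL` it is chosen from
#' `k_grid` by cross-validated balanced accuracy.
#'
#' @param fm A `pka_features` object or numeric matrix (training rows).
#' @param labels Class labels per row (`acidic`, `basic`, `amphoteric`).
#' @param k Number of neighbours, or `NULL` to select by CV.
#' @param descriptor_subset Columns to use (default: all).
#' @param k_grid Candidate k values when `k` is `NULL`.
#' @param cv_folds,seed Cross-validation controls for the k search.
#' @return A `router_model` object.
#' @export
fit_router <- function(fm, labels, k = NULL, descriptor_subset = NULL,
                       k_grid = c(1L, 3L, 5L, 7L, 9L), cv_folds = 5L,
                       seed = 1L) {
  x <- if (inherits(fm, "pka_features")) fm$values else fm
  stopifnot(is.matrix(x), nrow(x) == length(labels))
  labels <- as.character(labels)
  if (length(unique(labels)) < 2L) {
    stop("router training data must contain at least two classes")
  }
  if (!is.null(descriptor_subset)) {
    missing_cols <- setdiff(descriptor_subset, colnames(x))
    if (length(missing_cols)) {
      stop("descriptor_subset not in features: ",
           paste(missing_cols, collapse = ", "))
    }
    x <- x[, descriptor_subset, drop = FALSE]
  }
  center <- colMeans(x)
  scale_ <- apply(x, 2, stats::sd); scale_[scale_ == 0] <- 1
  xs <- sweep(sweep(x, 2, center), 2, scale_, "/")

  if (is.null(k)) {
    folds <- make_folds(nrow(xs), cv_folds,
                        seed = derive_seed(seed, "router-k"),
                        strata = labels)
    cv_ba <- vapply(k_grid, function(kk) {
      pred <- character(nrow(xs))
      for (f in sort(unique(folds))) {
        te <- folds == f
        pred[te] <- knn_predict(xs[!te, , drop = FALSE], labels[!te],
                                xs[te, , drop = FALSE],
                                min(kk, sum(!te)))
      }
      balanced_accuracy(labels, pred)
    }, numeric(1))
    k <- k_grid[which.max(cv_ba)]
  }
  if (k > nrow(xs)) stop("k exceeds training size")
  structure(list(k = as.integer(k),
                 descriptor_subset = colnames(xs),
                 center = center, scale = scale_,
                 training_features = xs,
                 training_labels = labels),
            class = "router_model")
}

#' @param object A `router_model`.
#' @param newdata A `pka_features` object or numeric matrix of query rows
#'   on the same descriptor columns (unscaled; the stored training
#'   scaling is applied).
#' @param ... Unused.
#' @rdname fit_router
#' @export
predict.router_model <- function(object, newdata, ...) {
  x <- if (inherits(newdata, "pka_features")) newdata$values else newdata
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L,
                                   dimnames = list(NULL, names(x)))
  if (!is.null(colnames(x))) {
    missing_cols <- setdiff(object$descriptor_subset, colnames(x))
    if (length(missing_cols)) {
      stop("query lacks router descriptors: ",
           paste(missing_cols, collapse = ", "))
    }
    x <- x[, object$descriptor_subset, drop = FALSE]
  }
  xs <- sweep(sweep(x, 2, object$center), 2, object$scale, "/")
  knn_predict(object$training_features, object$training_labels, xs,
              object$k)
}

#' Evaluate a router on training, cross-validation and test data
#'
#' @param model A `router_model`.
#' @param test_fm,test_labels Held-out features and labels (optional).
#' @param cv_folds,seed Cross-validation controls.
#' @return A list with `train_ba`, `cv_ba`, `test_ba` (NA if no test
#'   data), and `k`.
#' @export
evaluate_router <- function(model, test_fm = NULL, test_labels = NULL,
                            cv_folds = 5L, seed = 1L) {
  stopifnot(inherits(model, "router_model"))
  xs <- model$training_features
  labels <- model$training_labels
  train_pred <- knn_predict(xs, labels, xs, model$k)
  train_ba <- balanced_accuracy(labels, train_pred)
  folds <- make_folds(nrow(xs), cv_folds,
                      seed = derive_seed(seed, "router-eval"),
                      strata = labels)
  cv_pred <- character(nrow(xs))
  for (f in sort(unique(folds))) {
    te <- folds == f
    cv_pred[te] <- knn_predict(xs[!te, , drop = FALSE], labels[!te],
                               xs[te, , drop = FALSE],
                               min(model$k, sum(!te)))
  }
  cv_ba <- balanced_accuracy(labels, cv_pred)
  test_ba <- NA_real_
  if (!is.null(test_fm)) {
    test_pred <- predict(model, test_fm)
    test_ba <- balanced_accuracy(test_labels, test_pred)
  }
  list(k = model$k, train_ba = train_ba, cv_ba = cv_ba, test_ba = test_ba)
}
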