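#' Regression performance metrics
#'
#' RMSE is the root of the mean squared error; the coefficient of
#' determination is computed about the observed mean,
#' R2 = 1 - SS_res / SS_tot. When the predictions come from
#' cross-validated (out-of-fold) estimates the same quantity is the
#' cross-validated Q2.
#'
#' @param observed,predicted Equal-length numeric vectors (n >= 2).
#' @return A list with `rmse`, `r2` and `n`.
#' @export
compute_metrics <- function(observed, predicted) {
  stopifnot(is.numeric(observed), is.numeric(predicted),
            length(observed) == length(predicted))
  if (length(observed) < 2L) stop("need at least two observations")
  if (anyNA(observed) || anyNA(predicted)) stop("missing values in input")
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) stop("observed values have zero variance; R2 undefined")
  ss_res <- sum((observed - predicted)^2)
  list(rmse = sqrt(mean((observed - predicted)^2)),
       r2 = 1 - ss_res / ss_tot,
       n = length(observed))
}

#' Multiclass balanced accuracy
#'
#' The mean of per-class recalls. With `n_classes` given, every one of
#' the first `n_classes` levels must appear among the true labels.
#'
#' @param true,predicted Equal-length label vectors (factor or character).
#' @param n_classes Optional expected number of classes; an error is
#'   raised if a class is absent from `true`.
#' @return Balanced accuracy in \[0, 1\].
#' @export
balanced_accuracy <- function(true, predicted, n_classes = NULL) {
  stopifnot(length(true) == length(predicted))
  lev <- sort(unique(c(as.character(true), as.character(predicted))))
  true <- factor(as.character(true), levels = lev)
  predicted <- factor(as.character(predicted), levels = lev)
  present <- levels(true)[table(true) > 0L]
  if (!is.null(n_classes) && length(present) < n_classes) {
    stop("a class is absent from the true labels (",
         length(present), " present, ", n_classes, " expected)")
  }
  recalls <- vapply(present, function(cl) {
    sel <- true == cl
    mean(predicted[sel] == cl)
  }, numeric(1))
  mean(recalls)
}
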