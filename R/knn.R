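# shared kNN engine: Euclidean distances, majority vote, ties broken by
# the class of the single nearest neighbour (distance ties by lowest row
# index, making the result invariant to training-row permutations up to
# exact duplicates)

knn_predict <- function(train_x, train_labels, test_x, k) {
  stopifnot(is.matrix(train_x), is.matrix(test_x),
            ncol(train_x) == ncol(test_x))
  n_train <- nrow(train_x)
  if (k > n_train) stop("k (", k, ") exceeds training size (", n_train, ")")
  train_labels <- as.character(train_labels)
  # squared distances via the expansion |a-b|^2 = |a|^2 + |b|^2 - 2ab
  d2 <- outer(rowSums(test_x^2), rep(1, n_train)) +
    outer(rep(1, nrow(test_x)), rowSums(train_x^2)) -
    2 * tcrossprod(test_x, train_x)
  d2[d2 < 0] <- 0
  out <- character(nrow(test_x))
  for (i in seq_len(nrow(test_x))) {
    ord <- order(d2[i, ], seq_len(n_train))
    nn <- ord[seq_len(k)]
    votes <- table(train_labels[nn])
    top <- names(votes)[votes == max(votes)]
    out[i] <- if (length(top) == 1L) top else train_labels[ord[1]]
  }
  out
}
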