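# Feed-forward multilayer perceptron for pKa regression, implemented on
# base matrix operations: fully connected hidden layers, each followed by
# batch normalization and (inverted) dropout, ReLU activations, a single
# linear output, mean-squared-error loss and Adam updates. Inference uses
# batch-norm running statistics and no dropout, so predictions are
# deterministic functions of the stored weights.

relu <- function(x) (x > 0) * x

mlp_init <- function(d_in, hidden, batchnorm, seed) {
  local_seed(seed, {
    dims <- c(d_in, hidden)
    layers <- vector("list", length(hidden))
    for (l in seq_along(hidden)) {
      fan_in <- dims[l]
      layers[[l]] <- list(
        W = matrix(stats::rnorm(fan_in * dims[l + 1], 0,
                                sqrt(2 / fan_in)),
                   fan_in, dims[l + 1]),
        b = rep(0, dims[l + 1]),
        gamma = rep(1, dims[l + 1]),
        beta = rep(0, dims[l + 1]),
        run_mean = rep(0, dims[l + 1]),
        run_var = rep(1, dims[l + 1])
      )
    }
    out <- list(W = matrix(stats::rnorm(dims[length(dims)], 0,
                                        sqrt(1 / dims[length(dims)])),
                           dims[length(dims)], 1),
                b = 0)
    list(layers = layers, out = out, batchnorm = batchnorm,
         hidden = hidden)
  })
}

# forward pass in training mode; returns caches for backprop
mlp_forward_train <- function(net, x, dropout, bn_momentum = 0.9,
                              eps = 1e-5) {
  m <- nrow(x)
  caches <- vector("list", length(net$layers))
  a <- x
  for (l in seq_along(net$layers)) {
    ly <- net$layers[[l]]
    z <- sweep(a %*% ly$W, 2, ly$b, "+")
    if (net$batchnorm && m > 1) {
      mu <- colMeans(z)
      v <- colMeans(sweep(z, 2, mu)^2)
      zh <- sweep(sweep(z, 2, mu), 2, sqrt(v + eps), "/")
      zt <- sweep(sweep(zh, 2, ly$gamma, "*"), 2, ly$beta, "+")
      net$layers[[l]]$run_mean <- bn_momentum * ly$run_mean +
        (1 - bn_momentum) * mu
      net$layers[[l]]$run_var <- bn_momentum * ly$run_var +
        (1 - bn_momentum) * v
    } else {
      mu <- NULL; v <- NULL; zh <- NULL; zt <- z
    }
    h <- relu(zt)
    if (dropout > 0) {
      keep <- 1 - dropout
      mask <- matrix((stats::runif(length(h)) < keep) / keep,
                     nrow(h), ncol(h))
      a_next <- h * mask
    } else {
      mask <- NULL
      a_next <- h
    }
    caches[[l]] <- list(a_prev = a, z = z, mu = mu, v = v, zh = zh,
                        zt = zt, h = h, mask = mask)
    a <- a_next
  }
  yhat <- as.numeric(a %*% net$out$W + net$out$b)
  list(net = net, yhat = yhat, a_last = a, caches = caches, eps = eps)
}

mlp_backward <- function(fwd, y, dropout, l2) {
  net <- fwd$net
  m <- length(y)
  grads <- list(layers = vector("list", length(net$layers)), out = NULL)
  dyhat <- matrix(2 * (fwd$yhat - y) / m, ncol = 1)
  grads$out <- list(W = crossprod(fwd$a_last, dyhat) + 2 * l2 * net$out$W,
                    b = sum(dyhat))
  da <- dyhat %*% t(net$out$W)
  for (l in rev(seq_along(net$layers))) {
    cache <- fwd$caches[[l]]
    ly <- net$layers[[l]]
    dh <- if (!is.null(cache$mask)) da * cache$mask else da
    dzt <- dh * (cache$zt > 0)
    if (net$batchnorm && !is.null(cache$mu)) {
      dgamma <- colSums(dzt * cache$zh)
      dbeta <- colSums(dzt)
      inv_sd <- 1 / sqrt(cache$v + fwd$eps)
      mb <- nrow(dzt)
      dz <- sweep(
        dzt - matrix(dbeta / mb, mb, length(dbeta), byrow = TRUE) -
          cache$zh * matrix(dgamma / mb, mb, length(dgamma), byrow = TRUE),
        2, ly$gamma * inv_sd, "*")
    } else {
      dgamma <- rep(0, length(ly$gamma)); dbeta <- rep(0, length(ly$beta))
      dz <- dzt
    }
    grads$layers[[l]] <- list(
      W = crossprod(cache$a_prev, dz) + 2 * l2 * ly$W,
      b = colSums(dz), gamma = dgamma, beta = dbeta)
    da <- dz %*% t(ly$W)
  }
  grads
}

adam_state_init <- function(net) {
  zero_like <- function(p) lapply(p, function(q) q * 0)
  list(m = list(layers = lapply(net$layers, zero_like),
                out = zero_like(net$out)),
       v = list(layers = lapply(net$layers, zero_like),
                out = zero_like(net$out)),
       t = 0L)
}

adam_update <- function(net, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  state$t <- state$t + 1L
  upd <- function(param, grad, m, v) {
    m <- beta1 * m + (1 - beta1) * grad
    v <- beta2 * v + (1 - beta2) * grad^2
    mhat <- m / (1 - beta1^state$t)
    vhat <- v / (1 - beta2^state$t)
    list(param = param - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
  }
  for (l in seq_along(net$layers)) {
    for (nm in c("W", "b", "gamma", "beta")) {
      u <- upd(net$layers[[l]][[nm]], grads$layers[[l]][[nm]],
               state$m$layers[[l]][[nm]], state$v$layers[[l]][[nm]])
      net$layers[[l]][[nm]] <- u$param
      state$m$layers[[l]][[nm]] <- u$m
      state$v$layers[[l]][[nm]] <- u$v
    }
  }
  for (nm in c("W", "b")) {
    u <- upd(net$out[[nm]], grads$out[[nm]],
             state$m$out[[nm]], state$v$out[[nm]])
    net$out[[nm]] <- u$param
    state$m$out[[nm]] <- u$m
    state$v$out[[nm]] <- u$v
  }
  list(net = net, state = state)
}

# inference-mode forward pass (running batch-norm stats, no dropout)
mlp_forward_predict <- function(net, x) {
  a <- x
  for (l in seq_along(net$layers)) {
    ly <- net$layers[[l]]
    z <- sweep(a %*% ly$W, 2, ly$b, "+")
    if (net$batchnorm) {
      zh <- sweep(sweep(z, 2, ly$run_mean), 2,
                  sqrt(ly$run_var + 1e-5), "/")
      z <- sweep(sweep(zh, 2, ly$gamma, "*"), 2, ly$beta, "+")
    }
    a <- relu(z)
  }
  as.numeric(a %*% net$out$W + net$out$b)
}

#' Fit a multilayer-perceptron regressor
#'
#' Architecture: fully connected hidden layers (`hidden`), each followed
#' by batch normalization and a dropout layer, ReLU activations, single
#' linear output. Trained with Adam on mean squared error, seeded
#' He-normal initialization, mini-batches, and optional early stopping on
#' an internal validation split. Given the same data and seed, training
#' is fully deterministic.
#'
#' @param x Numeric feature matrix (pre-scaled; see [fit_scaling()]).
#' @param y Numeric targets.
#' @param hidden Integer vector of hidden-layer widths
#'   (default `c(256, 256, 256)`).
#' @param dropout Dropout rate after each hidden layer (default 0.25).
#' @param batchnorm Use batch normalization (default `TRUE`).
#' @param epochs Maximum training epochs (default 500).
#' @param batch_size Mini-batch size (default 32).
#' @param lr Adam learning rate (default 1e-3).
#' @param l2 L2 weight penalty (default 0).
#' @param val_frac Fraction of rows held out for early stopping
#'   (0 disables; default 0.1).
#' @param patience Early-stopping patience in epochs (default 20).
#' @param seed Integer seed.
#' @return A fitted network (list) usable via [predict.pka_regressor()]
#'   when wrapped by [train_dnn()], or directly with the internal
#'   forward pass.
#' @keywords internal
mlp_fit <- function(x, y, hidden = c(256L, 256L, 256L), dropout = 0.25,
                    batchnorm = TRUE, epochs = 500L, batch_size = 32L,
                    lr = 1e-3, l2 = 0, val_frac = 0.1, patience = 20L,
                    seed = 1L) {
  stopifnot(is.matrix(x), nrow(x) == length(y))
  net <- mlp_init(ncol(x), hidden, batchnorm, derive_seed(seed, "init"))
  state <- adam_state_init(net)
  best <- list(net = net, score = Inf, epoch = 0L)
  local_seed(derive_seed(seed, "train"), {
    n <- nrow(x)
    if (val_frac > 0 && n >= 20L) {
      n_val <- max(2L, floor(val_frac * n))
      val_idx <- sample.int(n, n_val)
    } else {
      val_idx <- integer(0)
    }
    tr_idx <- setdiff(seq_len(n), val_idx)
    xtr <- x[tr_idx, , drop = FALSE]; ytr <- y[tr_idx]
    wait <- 0L
    for (ep in seq_len(epochs)) {
      ord <- sample.int(length(ytr))
      starts <- seq(1L, length(ytr), by = batch_size)
      for (s in starts) {
        idx <- ord[s:min(s + batch_size - 1L, length(ytr))]
        if (length(idx) < 2L) next
        fwd <- mlp_forward_train(net, xtr[idx, , drop = FALSE], dropout)
        net <- fwd$net  # running batch-norm statistics
        grads <- mlp_backward(fwd, ytr[idx], dropout, l2)
        u <- adam_update(net, grads, state, lr)
        net <- u$net; state <- u$state
      }
      if (length(val_idx)) {
        val_pred <- mlp_forward_predict(net, x[val_idx, , drop = FALSE])
        score <- sqrt(mean((y[val_idx] - val_pred)^2))
        if (score < best$score - 1e-6) {
          best <- list(net = net, score = score, epoch = ep)
          wait <- 0L
        } else {
          wait <- wait + 1L
          if (wait >= patience) break
        }
      } else {
        best <- list(net = net, score = NA_real_, epoch = ep)
      }
    }
  })
  best$net
}

#' Train the neural-network pKa regressor
#'
#' Wraps [mlp_fit()] with learning-rate selection by cross-validated
#' RMSE (shorter tuning runs), out-of-fold Q2 estimation for the chosen
#' rate, and a final fit on all training rows.
#'
#' @param fm Training features (`pka_features` or matrix), already scaled
#'   (see [fit_scaling()]); columns with missing values must have been
#'   dropped upstream.
#' @param y Numeric pKa targets.
#' @param cv_folds Cross-validation folds (default 5).
#' @param lr_grid Candidate Adam learning rates.
#' @param hidden,dropout,batchnorm,epochs,batch_size,l2 Network and
#'   training controls passed to [mlp_fit()].
#' @param tune_epochs Epoch cap during learning-rate tuning.
#' @param seed Integer seed; identical seeds give identical predictions.
#' @return A `pka_regressor` (algorithm `"dnn"`).
#' @export
train_dnn <- function(fm, y, cv_folds = 5L, lr_grid = c(1e-2, 1e-3, 1e-4),
                      hidden = c(256L, 256L, 256L), dropout = 0.25,
                      batchnorm = TRUE, epochs = 500L, batch_size = 32L,
                      l2 = 0, tune_epochs = 100L, seed = 1L) {
  x <- as_feature_matrix(fm)
  check_target(y, nrow(x))
  folds <- make_folds(nrow(x), cv_folds, seed = derive_seed(seed, "dnn"))
  best <- NULL
  for (lr in lr_grid) {
    pred <- oof_predictions(x, y, folds,
      function(xt, yt) mlp_fit(xt, yt, hidden = hidden, dropout = dropout,
                               batchnorm = batchnorm,
                               epochs = tune_epochs,
                               batch_size = batch_size, lr = lr, l2 = l2,
                               seed = derive_seed(seed, paste0("lr", lr))),
      mlp_forward_predict)
    rmse <- sqrt(mean((y - pred)^2))
    if (is.null(best) || rmse < best$rmse) {
      best <- list(rmse = rmse, pred = pred, lr = lr)
    }
  }
  cv <- compute_metrics(y, best$pred)
  fit <- mlp_fit(x, y, hidden = hidden, dropout = dropout,
                 batchnorm = batchnorm, epochs = epochs,
                 batch_size = batch_size, lr = best$lr, l2 = l2,
                 seed = derive_seed(seed, "final"))
  train_pred <- mlp_forward_predict(fit, x)
  tr <- compute_metrics(y, train_pred)
  new_pka_regressor("dnn", fit, colnames(x),
                    list(lr = best$lr, hidden = hidden, dropout = dropout,
                         batchnorm = batchnorm, epochs = epochs,
                         batch_size = batch_size, l2 = l2, seed = seed),
                    list(r2_fit = tr$r2, rmse_fit = tr$rmse,
                         q2_cv = cv$r2, rmse_cv = cv$rmse,
                         n = length(y)))
}
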