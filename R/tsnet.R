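# The time-series feed-forward network: three time-lagged 11-feature input
# vectors are projected by ONE shared 11x8 weight matrix into hidden layers
# 1, 3 and 5 of a tanh chain 8-10-8-10-8-10-5, topped by a Softmax head
# (10 respiratory phases) or a ReLU head (tumor displacement). Forward,
# loss, analytic backpropagation and mini-batch gradient descent are all
# explicit; no autodiff.

.hidden_widths <- c(8L, 10L, 8L, 10L, 8L, 10L, 5L)
.input_width <- 11L

head_out_dim <- function(head) {
  switch(head, classifier = 10L, regressor = 1L,
    abort("`head` must be 'classifier' or 'regressor'.")
  )
}

glorot <- function(n_in, n_out) {
  a <- sqrt(6 / (n_in + n_out))
  matrix(runif(n_in * n_out, -a, a), n_in, n_out)
}

#' Initialise network parameters
#'
#' Weights are Glorot-uniform (symmetric, fan-based, keeping the tanh
#' pre-activations away from saturation); biases start at zero, except the
#' regressor's output bias which starts at 0.5, the midpoint of the min-max
#' target range, so the ReLU output unit is active from the first epoch.
#' The layer-1/3/5 input projections are one shared object: `W_in`/`B_in`
#' appear once in the parameter list and are used at all three injection
#' sites.
#'
#' @param head `"classifier"` or `"regressor"`.
#' @param seed Optional integer seed; same seed, same parameters.
#' @return A list of class `tsnet_params` with elements `head`, `W_in`
#'   (11x8), `B_in` (8), and lists `W`, `B` of the seven maps along
#'   8-10-8-10-8-10-5-out (the seventh is the output map, 5x10 or 5x1).
#' @export
init_params <- function(head = c("classifier", "regressor"), seed = NULL) {
  head <- match.arg(head)
  if (!is.null(seed)) withr::local_seed(seed)
  widths <- c(.hidden_widths, head_out_dim(head))
  W <- purrr::map(seq_len(7), ~ glorot(widths[.x], widths[.x + 1]))
  B <- purrr::map(seq_len(7), ~ numeric(widths[.x + 1]))
  if (head == "regressor") B[[7]] <- 0.5
  structure(
    list(
      head = head,
      W_in = glorot(.input_width, widths[1]),
      B_in = numeric(widths[1]),
      W = W, B = B
    ),
    class = "tsnet_params"
  )
}

zero_like_params <- function(params) {
  g <- params
  g$W_in[] <- 0
  g$B_in[] <- 0
  for (k in seq_len(7)) {
    g$W[[k]][] <- 0
    g$B[[k]][] <- 0
  }
  g
}

add_bias <- function(z, b) z + matrix(b, nrow(z), length(b), byrow = TRUE)

softmax_rows <- function(z) {
  e <- exp(z - apply(z, 1, max))
  e / rowSums(e)
}

split_steps <- function(x) {
  x <- as_feature_matrix(x)
  if (ncol(x) != 33) {
    abort(sprintf("Expected 33 feature columns (3 x 11), got %d.", ncol(x)))
  }
  list(tm2 = x[, 1:11, drop = FALSE],
       tm1 = x[, 12:22, drop = FALSE],
       t0 = x[, 23:33, drop = FALSE])
}

#' Forward pass
#'
#' Computes all pre-activations and activations for a batch. The T-2 block
#' enters hidden layer 1 (`Z1 = X(T-2) W_in + B_in`); the T-1 and T0 blocks
#' are added into the layer-3 and layer-5 pre-activations through the same
#' shared `W_in` (no extra bias); every other layer is a standard affine map
#' of the previous activation. tanh links the hidden layers; the output is
#' Softmax (classifier) or ReLU (regressor).
#'
#' @param params A `tsnet_params`.
#' @param x Batch feature matrix, N x 33, already normalized, columns in
#'   [feature_cols()] order.
#' @return List with `Z` (pre-activations, 8 elements), `A` (activations;
#'   `A[[8]]` is the network output) and the three input blocks.
#' @export
tsnet_forward <- function(params, x) {
  xs <- split_steps(x)
  Z <- vector("list", 8)
  A <- vector("list", 8)
  Z[[1]] <- add_bias(xs$tm2 %*% params$W_in, params$B_in)
  A[[1]] <- tanh(Z[[1]])
  for (k in 2:7) {
    Z[[k]] <- add_bias(A[[k - 1]] %*% params$W[[k - 1]], params$B[[k - 1]])
    if (k == 3) Z[[k]] <- Z[[k]] + xs$tm1 %*% params$W_in
    if (k == 5) Z[[k]] <- Z[[k]] + xs$t0 %*% params$W_in
    A[[k]] <- tanh(Z[[k]])
  }
  Z[[8]] <- add_bias(A[[7]] %*% params$W[[7]], params$B[[7]])
  A[[8]] <- if (params$head == "classifier") {
    softmax_rows(Z[[8]])
  } else {
    pmax(Z[[8]], 0)
  }
  list(Z = Z, A = A, x = xs)
}

l1_penalty <- function(params, lambda) {
  if (lambda == 0) return(0)
  lambda * (sum(abs(params$W_in)) + sum(vapply(params$W, function(w) sum(abs(w)), numeric(1))))
}

#' Batch loss
#'
#' Classifier: mean cross-entropy between one-hot targets and Softmax
#' probabilities (probabilities clamped at 1e-12 inside the log only).
#' Regressor: mean squared error on the normalized scale. Either way an L1
#' penalty `lambda * sum(|weights|)` is added; biases are not penalised and
#' the shared input weights are counted once.
#'
#' @param params A `tsnet_params`.
#' @param x N x 33 feature matrix.
#' @param y Targets: N x 10 one-hot matrix (classifier) or length-N numeric
#'   (regressor, normalized scale).
#' @param l1_lambda L1 coefficient (>= 0).
#' @param fwd Optional precomputed [tsnet_forward()] result.
#' @return List with `loss` (data + penalty), `data_loss` and `fwd`.
#' @export
tsnet_loss <- function(params, x, y, l1_lambda = 0, fwd = NULL) {
  fwd <- fwd %||% tsnet_forward(params, x)
  yhat <- fwd$A[[8]]
  n <- nrow(yhat)
  if (n == 0) abort("Batch must be non-empty.")
  data_loss <- if (params$head == "classifier") {
    y <- as_feature_matrix(y)
    stopifnot(ncol(y) == 10, nrow(y) == n)
    -sum(y * log(pmax(yhat, 1e-12))) / n
  } else {
    y <- as.numeric(y)
    stopifnot(length(y) == n)
    mean((y - yhat[, 1])^2)
  }
  list(loss = data_loss + l1_penalty(params, l1_lambda),
       data_loss = data_loss, fwd = fwd)
}

#' Analytic gradients
#'
#' Backpropagates the batch loss through the network. The gradient of the
#' shared `W_in` is the sum of the contributions from its three injection
#' sites (layers 1, 3 and 5); `B_in` receives only the layer-1 term, where
#' it is applied. The L1 subgradient `lambda * sign(W)` is added to every
#' weight gradient (not to biases).
#'
#' @inheritParams tsnet_loss
#' @return A `tsnet_params`-shaped list of gradients.
#' @export
tsnet_backward <- function(params, x, y, l1_lambda = 0, fwd = NULL) {
  fwd <- fwd %||% tsnet_forward(params, x)
  yhat <- fwd$A[[8]]
  n <- nrow(yhat)
  g <- zero_like_params(params)

  dZ <- vector("list", 8)
  if (params$head == "classifier") {
    y <- as_feature_matrix(y)
    dZ[[8]] <- (yhat - y) / n # Softmax + cross-entropy
  } else {
    y <- as.numeric(y)
    relu_active <- fwd$Z[[8]] >= 0
    dZ[[8]] <- (2 / n) * (yhat[, 1] - y) * relu_active
    dim(dZ[[8]]) <- c(n, 1)
  }

  g$W[[7]] <- crossprod(fwd$A[[7]], dZ[[8]])
  g$B[[7]] <- colSums(dZ[[8]])
  dA <- dZ[[8]] %*% t(params$W[[7]])
  for (k in 7:2) {
    dZ[[k]] <- dA * (1 - fwd$A[[k]]^2) # tanh'(z) = 1 - tanh(z)^2
    g$W[[k - 1]] <- crossprod(fwd$A[[k - 1]], dZ[[k]])
    g$B[[k - 1]] <- colSums(dZ[[k]])
    if (k == 3) g$W_in <- g$W_in + crossprod(fwd$x$tm1, dZ[[k]])
    if (k == 5) g$W_in <- g$W_in + crossprod(fwd$x$t0, dZ[[k]])
    dA <- dZ[[k]] %*% t(params$W[[k - 1]])
  }
  dZ[[1]] <- dA * (1 - fwd$A[[1]]^2)
  g$W_in <- g$W_in + crossprod(fwd$x$tm2, dZ[[1]])
  g$B_in <- colSums(dZ[[1]])

  if (l1_lambda > 0) {
    g$W_in <- g$W_in + l1_lambda * sign(params$W_in)
    for (k in seq_len(7)) {
      g$W[[k]] <- g$W[[k]] + l1_lambda * sign(params$W[[k]])
    }
  }
  g
}

#' Training configuration
#'
#' @param head `"classifier"` or `"regressor"`.
#' @param learning_rate Gradient-descent step size (default 0.1).
#' @param max_epochs Upper bound on training epochs; defaults to 1000 for
#'   the classifier and 5000 for the regressor.
#' @param l1_lambda L1 regularization coefficient (weights only).
#' @param patience Consecutive divergent epochs tolerated before training
#'   stops, where an epoch counts as divergent when the test loss exceeds
#'   its running minimum by more than `min_delta` (relative).
#' @param min_delta Relative margin above the running test-loss minimum
#'   below which an epoch is treated as a plateau rather than divergence.
#' @param batch_size Samples per gradient step within an epoch (default 32);
#'   `NULL` for full-batch descent. Every sample is visited once per epoch
#'   in a seeded shuffled order.
#' @param seed Seed for parameter initialisation.
#' @return A list of class `tsnet_config`.
#' @export
tsnet_config <- function(head = c("classifier", "regressor"),
                         learning_rate = 0.1,
                         max_epochs = NULL,
                         l1_lambda = 1e-4,
                         patience = 25,
                         min_delta = 1e-3,
                         batch_size = 32,
                         seed = 1) {
  head <- match.arg(head)
  max_epochs <- max_epochs %||% switch(head, classifier = 1000, regressor = 5000)
  if (learning_rate <= 0) abort("`learning_rate` must be > 0.")
  if (max_epochs < 1) abort("`max_epochs` must be >= 1.")
  if (l1_lambda < 0) abort("`l1_lambda` must be >= 0.")
  if (patience < 1) abort("`patience` must be >= 1.")
  if (min_delta < 0) abort("`min_delta` must be >= 0.")
  if (!is.null(batch_size) && batch_size < 1) {
    abort("`batch_size` must be >= 1 (or NULL for full batch).")
  }
  structure(
    list(head = head, learning_rate = learning_rate, max_epochs = max_epochs,
         l1_lambda = l1_lambda, patience = patience, min_delta = min_delta,
         batch_size = batch_size, seed = seed),
    class = "tsnet_config"
  )
}

update_params <- function(params, grads, lr) {
  params$W_in <- params$W_in - lr * grads$W_in
  params$B_in <- params$B_in - lr * grads$B_in
  for (k in seq_len(7)) {
    params$W[[k]] <- params$W[[k]] - lr * grads$W[[k]]
    params$B[[k]] <- params$B[[k]] - lr * grads$B[[k]]
  }
  params
}

#' Train by gradient descent
#'
#' Plain gradient descent at a fixed learning rate. Each epoch visits every
#' training sample once, in mini-batches of `batch_size` drawn in a seeded
#' shuffled order (set `batch_size = NULL` for classical full-batch
#' descent). Losses on the full train and test partitions are recorded
#' every epoch; training stops early once the test loss has sat more than
#' `min_delta` (relative) above its running minimum for `patience`
#' consecutive epochs (train/test divergence), and the parameters at the
#' test-loss minimum are returned. Deterministic given the config seed.
#'
#' @param x_train,y_train,x_test,y_test Normalized feature matrices and
#'   matching targets (one-hot matrix or numeric vector per the head).
#' @param config A [tsnet_config()].
#' @param params Optional starting parameters (default: fresh
#'   [init_params()] with the config seed).
#' @return List of class `tsnet_trained`: `params` (at the test-loss
#'   minimum), `history` (tibble: epoch, train_loss, test_loss),
#'   `best_epoch`, `stopped_early`, `config`.
#' @export
tsnet_train <- function(x_train, y_train, x_test, y_test, config,
                        params = NULL) {
  stopifnot(inherits(config, "tsnet_config"))
  if (nrow(as_feature_matrix(x_train)) == 0 ||
      nrow(as_feature_matrix(x_test)) == 0) {
    abort("Both the training and testing partitions must be non-empty.")
  }
  params <- params %||% init_params(config$head, seed = config$seed)
  stopifnot(identical(params$head, config$head))

  epochs <- integer()
  tr_loss <- te_loss <- numeric()
  best <- Inf
  best_params <- params
  best_epoch <- 0L
  above <- 0L
  stopped_early <- FALSE

  # epoch 0: losses at initialisation
  l_tr <- tsnet_loss(params, x_train, y_train, config$l1_lambda)
  l_te <- tsnet_loss(params, x_test, y_test, config$l1_lambda)
  epochs <- 0L
  tr_loss <- l_tr$loss
  te_loss <- l_te$loss
  best <- l_te$loss

  x_train <- as_feature_matrix(x_train)
  n_train <- nrow(x_train)
  y_is_matrix <- config$head == "classifier"
  if (y_is_matrix) y_train <- as_feature_matrix(y_train)
  bs <- config$batch_size %||% n_train
  withr::local_seed(config$seed + 1L)

  for (e in seq_len(config$max_epochs)) {
    ord <- if (bs >= n_train) seq_len(n_train) else sample.int(n_train)
    for (b in split(ord, ceiling(seq_along(ord) / bs))) {
      g <- tsnet_backward(
        params,
        x_train[b, , drop = FALSE],
        if (y_is_matrix) y_train[b, , drop = FALSE] else y_train[b],
        config$l1_lambda
      )
      params <- update_params(params, g, config$learning_rate)
    }
    l_tr <- tsnet_loss(params, x_train, y_train, config$l1_lambda)
    l_te <- tsnet_loss(params, x_test, y_test, config$l1_lambda)
    epochs <- c(epochs, e)
    tr_loss <- c(tr_loss, l_tr$loss)
    te_loss <- c(te_loss, l_te$loss)

    if (!is.finite(l_tr$loss) || !is.finite(l_te$loss)) {
      abort(
        "Training diverged to a non-finite loss.",
        class = "respnet_divergence",
        history = tibble::tibble(
          epoch = epochs, train_loss = tr_loss, test_loss = te_loss
        )
      )
    }
    if (l_te$loss < best) {
      best <- l_te$loss
      best_params <- params
      best_epoch <- e
    }
    # divergence = materially above the running minimum, not plateau jitter
    margin <- best + max(config$min_delta * abs(best), 1e-10)
    if (l_te$loss > margin) {
      above <- above + 1L
      if (above >= config$patience) {
        stopped_early <- TRUE
        break
      }
    } else {
      above <- 0L
    }
  }

  list(
    params = best_params,
    history = tibble::tibble(
      epoch = epochs, train_loss = tr_loss, test_loss = te_loss
    ),
    best_epoch = best_epoch,
    stopped_early = stopped_early,
    config = config
  ) |>
    structure(class = "tsnet_trained")
}

#' Raw network predictions
#'
#' @param params A `tsnet_params`.
#' @param x N x 33 normalized feature matrix.
#' @return Classifier: N x 10 matrix of phase probabilities (rows sum to 1).
#'   Regressor: length-N vector on the normalized scale.
#' @export
tsnet_predict <- function(params, x) {
  out <- tsnet_forward(params, x)$A[[8]]
  if (params$head == "classifier") out else out[, 1]
}
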