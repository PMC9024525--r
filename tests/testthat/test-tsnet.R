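test_that("parameter shapes follow the mandated topology", {
  for (head in c("classifier", "regressor")) {
    p <- init_params(head, seed = 1)
    expect_equal(dim(p$W_in), c(11, 8))
    expect_length(p$B_in, 8)
    widths <- c(8, 10, 8, 10, 8, 10, 5, if (head == "classifier") 10 else 1)
    for (k in 1:7) {
      expect_equal(dim(p$W[[k]]), c(widths[k], widths[k + 1]))
      expect_length(p$B[[k]], widths[k + 1])
    }
  }
  expect_identical(init_params("regressor", seed = 5),
                   init_params("regressor", seed = 5))
  expect_error(init_params("autoencoder"))
})

test_that("forward pass honours the activation ranges and the Softmax law", {
  b <- random_batch("classifier", n = 8, seed = 2)
  p <- init_params("classifier", seed = 2)
  fwd <- tsnet_forward(p, b$x)
  for (k in 1:7) {
    expect_true(all(fwd$A[[k]] >= -1 & fwd$A[[k]] <= 1))
  }
  expect_equal(rowSums(fwd$A[[8]]), rep(1, 8), tolerance = 1e-12)
  expect_true(all(fwd$A[[8]] > 0 & fwd$A[[8]] < 1))

  r <- init_params("regressor", seed = 2)
  out <- tsnet_predict(r, b$x)
  expect_true(all(out >= 0)) # ReLU head
})

test_that("zero weights give the uniform Softmax and a zero ReLU output", {
  b <- random_batch("classifier", n = 3, seed = 3)
  p <- init_params("classifier", seed = 3)
  z <- respnet:::zero_like_params(p)
  expect_equal(
    tsnet_predict(z, b$x),
    matrix(0.1, 3, 10),
    ignore_attr = TRUE, tolerance = 1e-15
  )
  r <- respnet:::zero_like_params(init_params("regressor", seed = 3))
  expect_equal(tsnet_predict(r, b$x), rep(0, 3))
})

test_that("cross-entropy reproduces closed forms and the L1 switch", {
  b <- random_batch("classifier", n = 5, seed = 4)
  p <- respnet:::zero_like_params(init_params("classifier", seed = 4))
  # uniform 0.1 prediction on any one-hot target: loss = ln 10 per sample
  expect_equal(tsnet_loss(p, b$x, b$y)$loss, log(10), tolerance = 1e-12)
  # l1_lambda = 0 leaves the pure data loss
  pr <- init_params("classifier", seed = 4)
  expect_equal(
    tsnet_loss(pr, b$x, b$y, l1_lambda = 0)$loss,
    tsnet_loss(pr, b$x, b$y, l1_lambda = 0)$data_loss
  )
  # the penalty adds exactly lambda * sum(|weights|), biases excluded
  lam <- 1e-3
  expect_equal(
    tsnet_loss(pr, b$x, b$y, l1_lambda = lam)$loss -
      tsnet_loss(pr, b$x, b$y, l1_lambda = 0)$loss,
    lam * (sum(abs(pr$W_in)) + sum(purrr::map_dbl(pr$W, ~ sum(abs(.x)))))
  )
})

test_that("analytic gradients match central finite differences", {
  for (head in c("classifier", "regressor")) {
    b <- random_batch(head, n = 4, seed = 5)
    p <- init_params(head, seed = 6)
    for (lam in c(0, 1e-4)) {
      g <- tsnet_backward(p, b$x, b$y, l1_lambda = lam)
      analytic <- flatten_params(g)
      numeric <- numeric_gradient(p, b$x, b$y, lam)
      rel <- abs(analytic - numeric) / pmax(abs(analytic), abs(numeric), 1e-4)
      expect_lt(max(rel), 1e-5)
    }
  }
})

test_that("the shared gradient equals the sum over an untied network's copies", {
  b <- random_batch("classifier", n = 4, seed = 7)
  p <- init_params("classifier", seed = 8)
  lam <- 0

  # untied oracle: loss as a function of three independent injection
  # matrices, evaluated by finite differences at the tied point
  untied_loss <- function(W1, W2, W3) {
    xs <- respnet:::split_steps(b$x)
    A <- tanh(respnet:::add_bias(xs$tm2 %*% W1, p$B_in))
    for (k in 2:7) {
      Z <- respnet:::add_bias(A %*% p$W[[k - 1]], p$B[[k - 1]])
      if (k == 3) Z <- Z + xs$tm1 %*% W2
      if (k == 5) Z <- Z + xs$t0 %*% W3
      A <- tanh(Z)
    }
    Z <- respnet:::add_bias(A %*% p$W[[7]], p$B[[7]])
    yhat <- respnet:::softmax_rows(Z)
    -sum(b$y * log(pmax(yhat, 1e-12))) / nrow(b$y)
  }

  h <- 1e-5
  fd_sum <- matrix(0, 11, 8)
  for (site in 1:3) {
    for (i in 1:11) {
      for (j in 1:8) {
        Ws <- list(p$W_in, p$W_in, p$W_in)
        Ws[[site]][i, j] <- Ws[[site]][i, j] + h
        up <- untied_loss(Ws[[1]], Ws[[2]], Ws[[3]])
        Ws <- list(p$W_in, p$W_in, p$W_in)
        Ws[[site]][i, j] <- Ws[[site]][i, j] - h
        dn <- untied_loss(Ws[[1]], Ws[[2]], Ws[[3]])
        fd_sum[i, j] <- fd_sum[i, j] + (up - dn) / (2 * h)
      }
    }
  }
  g <- tsnet_backward(p, b$x, b$y, l1_lambda = lam)
  expect_equal(g$W_in, fd_sum, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("the output-bias gradient vanishes at a constructed minimum", {
  # one sample per class, network output forced to the exact one-hot
  # targets via a saturating output map on a diagonal feature pattern is
  # hard to construct; instead use the regressor at a perfect fit
  withr::local_seed(9)
  x <- matrix(rnorm(4 * 33), 4, 33)
  p <- init_params("regressor", seed = 9)
  y <- tsnet_predict(p, x) # targets = current predictions, data loss 0
  g <- tsnet_backward(p, x, y, l1_lambda = 0)
  expect_equal(g$B[[7]], 0, tolerance = 1e-14, ignore_attr = TRUE)
  expect_equal(tsnet_loss(p, x, y)$loss, 0, tolerance = 1e-14)
})

test_that("training descends, records history, and runs its full budget", {
  w <- small_windows(seed = 21)
  fit <- fit_phase_classifier(w, max_epochs = 40, patience = 40, seed = 1)
  h <- fit$history
  expect_equal(h$epoch, 0:40) # no divergence: full budget + the init row
  expect_lt(h$train_loss[nrow(h)], h$train_loss[1])
})

test_that("a constructed overfit trap triggers the divergence stop", {
  withr::local_seed(10)
  # train: clean pattern; test: an unrelated distribution whose loss climbs
  x_tr <- matrix(rnorm(20 * 33), 20, 33)
  y_tr <- respnet:::one_hot(rep(0:9, 2))
  x_te <- matrix(rnorm(20 * 33, mean = 3), 20, 33)
  y_te <- respnet:::one_hot(rep(c(9:0), 2))
  cfg <- tsnet_config("classifier",
    max_epochs = 1000, patience = 10,
    batch_size = NULL, seed = 11
  )
  tr <- tsnet_train(x_tr, y_tr, x_te, y_te, cfg)
  expect_true(tr$stopped_early)
  expect_lt(max(tr$history$epoch), 1000)
  # returned parameters are the ones at the test-loss minimum
  best <- min(tr$history$test_loss)
  expect_equal(
    tsnet_loss(tr$params, x_te, y_te, cfg$l1_lambda)$loss, best
  )
})

test_that("training is bitwise reproducible under a fixed seed", {
  w <- small_windows(seed = 22)
  f1 <- fit_phase_classifier(w, max_epochs = 15, seed = 3)
  f2 <- fit_phase_classifier(w, max_epochs = 15, seed = 3)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$history, f2$history)
})

test_that("prediction applies the argmax rule and the inverse target scale", {
  # argmax with ties toward the lower phase index
  probs <- matrix(0.05, 2, 10)
  probs[1, 4] <- 0.55
  probs[2, c(3, 8)] <- 0.275
  idx <- apply(probs, 1, which.max)
  expect_equal(idx - 1L, c(3L, 2L))

  # regressor: normalized 0.5 under a (0, 10) mm target scale is 5 mm
  sc <- fit_minmax(cbind(disp_mm = c(0, 10)))
  expect_equal(unname(scaler_invert(sc, cbind(disp_mm = 0.5))[, 1]), 5)
})

test_that("a clean training run at protocol settings classifies held-out data", {
  w <- small_windows(n_subjects = 6, repeats = 6, seed = 23)
  fit <- fit_phase_classifier(w, seed = 2) # alpha 0.1, <= 1000 epochs
  rep <- evaluate_classifier(fit, dplyr::filter(w, split == "test"))
  expect_gte(rep$total_accuracy, 99)
})
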