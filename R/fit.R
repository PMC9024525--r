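# Data-frame-first model fitting on windowed cohorts: scaling, target
# encoding, training and prediction in physical units.

check_windows <- function(windows, need_split = TRUE) {
  if (!is.data.frame(windows)) abort("`windows` must be a data frame.")
  if (need_split) {
    if (!"split" %in% names(windows)) {
      abort("`windows` must carry a `split` column ('train'/'test').")
    }
    if (!all(c("train", "test") %in% windows$split)) {
      abort("Both 'train' and 'test' rows are required in `windows`.")
    }
  }
  invisible(windows)
}

#' Fit the respiratory-phase classifier
#'
#' Standardizes the 33 window features (z-score fitted on the training
#' partition; set `joint_normalization = TRUE` to fit on train and test
#' pooled), one-hot encodes the 10 phase targets, and trains the
#' shared-injection network with a Softmax head by mini-batch gradient
#' descent.
#'
#' @param windows Windowed samples from [phase_cohort()] or
#'   [build_windows()], with a `split` column and a `phase` target.
#' @param learning_rate,max_epochs,l1_lambda,patience,min_delta,batch_size,seed
#'   Passed to [tsnet_config()].
#' @param joint_normalization Fit the feature scaler on train and test
#'   jointly instead of train only.
#' @return An object of class `tsnet_fit`.
#' @export
#' @examples
#' co <- generate_cohort(3, 0, repeats = 3, seed = 1)
#' w <- phase_cohort(co)
#' fit <- fit_phase_classifier(w, max_epochs = 50, seed = 1)
#' glance(fit)
fit_phase_classifier <- function(windows, learning_rate = 0.1,
                                 max_epochs = 1000, l1_lambda = 1e-4,
                                 patience = 25, min_delta = 1e-3,
                                 batch_size = 32, seed = 1,
                                 joint_normalization = FALSE) {
  check_windows(windows)
  config <- tsnet_config("classifier",
    learning_rate = learning_rate, max_epochs = max_epochs,
    l1_lambda = l1_lambda, patience = patience, min_delta = min_delta,
    batch_size = batch_size, seed = seed
  )
  x_all <- window_matrix(windows)
  is_train <- windows$split == "train"
  scaler <- fit_standardizer(if (joint_normalization) x_all else x_all[is_train, , drop = FALSE])
  x <- scaler_apply(scaler, x_all)
  y <- one_hot(windows$phase)
  trained <- tsnet_train(
    x[is_train, , drop = FALSE], y[is_train, , drop = FALSE],
    x[!is_train, , drop = FALSE], y[!is_train, , drop = FALSE],
    config
  )
  structure(
    list(
      head = "classifier", params = trained$params,
      history = trained$history, best_epoch = trained$best_epoch,
      stopped_early = trained$stopped_early, config = config,
      x_scaler = scaler, y_scaler = NULL,
      n_train = sum(is_train), n_test = sum(!is_train)
    ),
    class = "tsnet_fit"
  )
}

#' Fit the tumor-displacement regressor
#'
#' Min-max scales the 33 window features and the displacement target (both
#' fitted on the training partition), and trains the shared-injection
#' network with a ReLU output by mini-batch gradient descent. Predictions
#' are inverse-transformed back to millimetres.
#'
#' @inheritParams fit_phase_classifier
#' @param max_epochs Upper bound on epochs (default 5000).
#' @return An object of class `tsnet_fit`.
#' @export
fit_disp_regressor <- function(windows, learning_rate = 0.1,
                               max_epochs = 5000, l1_lambda = 1e-4,
                               patience = 25, min_delta = 1e-3,
                               batch_size = 32, seed = 1,
                               joint_normalization = FALSE) {
  check_windows(windows)
  if (!"disp_mm" %in% names(windows) || anyNA(windows$disp_mm)) {
    abort("`windows` must carry a complete `disp_mm` target (couple the tumor first).")
  }
  config <- tsnet_config("regressor",
    learning_rate = learning_rate, max_epochs = max_epochs,
    l1_lambda = l1_lambda, patience = patience, min_delta = min_delta,
    batch_size = batch_size, seed = seed
  )
  x_all <- window_matrix(windows)
  is_train <- windows$split == "train"
  fit_rows <- if (joint_normalization) rep(TRUE, nrow(x_all)) else is_train
  x_scaler <- fit_minmax(x_all[fit_rows, , drop = FALSE])
  y_scaler <- fit_minmax(cbind(disp_mm = windows$disp_mm[fit_rows]))
  x <- suppressWarnings(scaler_apply(x_scaler, x_all))
  y <- suppressWarnings(scaler_apply(y_scaler, cbind(disp_mm = windows$disp_mm)))[, 1]
  trained <- tsnet_train(
    x[is_train, , drop = FALSE], y[is_train],
    x[!is_train, , drop = FALSE], y[!is_train],
    config
  )
  structure(
    list(
      head = "regressor", params = trained$params,
      history = trained$history, best_epoch = trained$best_epoch,
      stopped_early = trained$stopped_early, config = config,
      x_scaler = x_scaler, y_scaler = y_scaler,
      n_train = sum(is_train), n_test = sum(!is_train)
    ),
    class = "tsnet_fit"
  )
}

#' @export
print.tsnet_fit <- function(x, ...) {
  cat(sprintf(
    "<tsnet_fit> %s head | %d train / %d test windows | best epoch %d/%d%s\n",
    x$head, x$n_train, x$n_test, x$best_epoch, max(x$history$epoch),
    if (x$stopped_early) " (early stop)" else ""
  ))
  invisible(x)
}

#' Predict from a fitted network
#'
#' @param object A `tsnet_fit`.
#' @param newdata Window tibble with the 33 feature columns.
#' @param ... Unused.
#' @return Classifier: the input with `.pred_phase` (argmax phase, ties to
#'   the lower index) and `.pred_prob` (its probability). Regressor: the
#'   input with `.pred_mm` (displacement in millimetres) and `.pred_norm`.
#' @export
predict.tsnet_fit <- function(object, newdata, ...) {
  if (is.null(object$x_scaler)) abort("Fitted scaler missing from the model.")
  x <- suppressWarnings(scaler_apply(object$x_scaler, window_matrix(newdata)))
  out <- tsnet_predict(object$params, x)
  if (object$head == "classifier") {
    idx <- apply(out, 1, which.max) # first maximum: ties go to the lower phase
    dplyr::mutate(
      tibble::as_tibble(newdata),
      .pred_phase = as.integer(idx - 1L),
      .pred_prob = out[cbind(seq_len(nrow(out)), idx)]
    )
  } else {
    if (is.null(object$y_scaler)) abort("Fitted target scaler missing from the model.")
    mm <- scaler_invert(object$y_scaler, cbind(disp_mm = out))[, 1]
    dplyr::mutate(
      tibble::as_tibble(newdata),
      .pred_norm = out,
      .pred_mm = mm
    )
  }
}

#' @method tidy tsnet_fit
#' @export
tidy.tsnet_fit <- function(x, ...) x$history

#' @method glance tsnet_fit
#' @export
glance.tsnet_fit <- function(x, ...) {
  tibble::tibble(
    head = x$head,
    epochs = max(x$history$epoch),
    best_epoch = x$best_epoch,
    stopped_early = x$stopped_early,
    train_loss = x$history$train_loss[x$history$epoch == x$best_epoch],
    test_loss = x$history$test_loss[x$history$epoch == x$best_epoch],
    n_train = x$n_train,
    n_test = x$n_test
  )
}

#' Evaluate the classifier on a set of windows
#'
#' @param fit A classifier `tsnet_fit`.
#' @param windows Windows to score (typically the held-out partition).
#' @return A [classification_report()].
#' @export
evaluate_classifier <- function(fit, windows) {
  stopifnot(fit$head == "classifier")
  preds <- predict(fit, windows)
  classification_report(windows$phase, preds$.pred_phase)
}

#' Evaluate the regressor on a set of windows
#'
#' Scores on both the normalized scale (where the percent figures live:
#' MSE and MAE times 100) and the physical millimetre scale.
#'
#' @param fit A regressor `tsnet_fit`.
#' @param windows Windows to score, with a `disp_mm` target.
#' @return A [regression_report()].
#' @export
evaluate_regressor <- function(fit, windows) {
  stopifnot(fit$head == "regressor")
  preds <- predict(fit, windows)
  truth_norm <- suppressWarnings(
    scaler_apply(fit$y_scaler, cbind(disp_mm = windows$disp_mm))
  )[, 1]
  regression_report(
    truth_norm = truth_norm, pred_norm = preds$.pred_norm,
    truth_mm = windows$disp_mm, pred_mm = preds$.pred_mm
  )
}
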