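# Feature scaling: z-score standardization (classification pipeline) and
# min-max scaling (regression pipeline), with exact inverses. Scalers are
# fitted on the training partition only and never refit on application.

as_feature_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x)) x <- matrix(x, ncol = 1)
  storage.mode(x) <- "double"
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  x
}

#' Fit a z-score standardizer
#'
#' Stores the per-feature mean and standard deviation of the training data;
#' [scaler_apply()] maps to zero mean, unit sd and [scaler_invert()] is its
#' exact inverse. Constant features are rejected by name, since a zero sd
#' admits no z-score.
#'
#' @param x Training feature matrix or data frame (>= 2 rows).
#' @return An object of class `standardizer`.
#' @export
#' @examples
#' sc <- fit_standardizer(cbind(a = c(1, 2, 3)))
#' scaler_apply(sc, cbind(a = c(1, 2, 3)))
fit_standardizer <- function(x) {
  x <- as_feature_matrix(x)
  if (nrow(x) < 2) abort("Need at least 2 rows to fit a standardizer.")
  mu <- colMeans(x)
  sdev <- apply(x, 2, sd)
  bad <- colnames(x)[sdev < 1e-12 | !is.finite(sdev)]
  if (length(bad)) {
    abort(paste0(
      "Constant feature(s) cannot be standardized: ",
      paste(bad, collapse = ", ")
    ))
  }
  structure(
    list(mean = mu, sd = sdev, features = colnames(x)),
    class = "standardizer"
  )
}

#' Fit a min-max scaler
#'
#' Stores per-feature training minima and maxima; [scaler_apply()] maps the
#' training range onto `[0, 1]` (values outside the fitted range map outside
#' `[0, 1]` and are reported via a warning). Degenerate features with
#' `max == min` are rejected by name.
#'
#' @param x Training feature matrix or data frame (>= 2 rows).
#' @return An object of class `minmax_scaler`.
#' @export
#' @examples
#' sc <- fit_minmax(cbind(a = c(2, 4, 6)))
#' scaler_apply(sc, cbind(a = c(2, 4, 6)))
fit_minmax <- function(x) {
  x <- as_feature_matrix(x)
  if (nrow(x) < 2) abort("Need at least 2 rows to fit a min-max scaler.")
  lo <- apply(x, 2, min)
  hi <- apply(x, 2, max)
  bad <- colnames(x)[(hi - lo) < 1e-12 | !is.finite(hi - lo)]
  if (length(bad)) {
    abort(paste0(
      "Degenerate feature(s) with max == min cannot be min-max scaled: ",
      paste(bad, collapse = ", ")
    ))
  }
  structure(
    list(min = lo, max = hi, features = colnames(x)),
    class = "minmax_scaler"
  )
}

check_scaler_input <- function(scaler, x) {
  x <- as_feature_matrix(x)
  if (ncol(x) != length(scaler$features)) {
    abort(sprintf(
      "Scaler was fitted on %d feature(s) but received %d.",
      length(scaler$features), ncol(x)
    ))
  }
  x
}

#' Apply a fitted scaler
#'
#' Transforms new data with the parameters fixed at fit time (no refit, so
#' applying to a test partition cannot leak its statistics).
#'
#' @param scaler A `standardizer` or `minmax_scaler`.
#' @param x Feature matrix with the same columns as the fit data.
#' @return The transformed matrix.
#' @export
scaler_apply <- function(scaler, x) {
  x <- check_scaler_input(scaler, x)
  out <- if (inherits(scaler, "standardizer")) {
    sweep(sweep(x, 2, scaler$mean), 2, scaler$sd, "/")
  } else if (inherits(scaler, "minmax_scaler")) {
    z <- sweep(sweep(x, 2, scaler$min), 2, scaler$max - scaler$min, "/")
    n_out <- sum(z < 0 | z > 1)
    if (n_out > 0) {
      warn(sprintf(
        "%d value(s) fall outside the fitted min-max range and map outside [0, 1].",
        n_out
      ))
    }
    z
  } else {
    abort("`scaler` must be a standardizer or minmax_scaler.")
  }
  out
}

#' Invert a fitted scaler
#'
#' Exact algebraic inverse of [scaler_apply()], used to bring regression
#' predictions back to millimetres.
#'
#' @inheritParams scaler_apply
#' @param z Transformed matrix.
#' @return The matrix on the original scale.
#' @export
scaler_invert <- function(scaler, z) {
  z <- check_scaler_input(scaler, z)
  if (inherits(scaler, "standardizer")) {
    sweep(sweep(z, 2, scaler$sd, "*"), 2, scaler$mean, "+")
  } else if (inherits(scaler, "minmax_scaler")) {
    sweep(sweep(z, 2, scaler$max - scaler$min, "*"), 2, scaler$min, "+")
  } else {
    abort("`scaler` must be a standardizer or minmax_scaler.")
  }
}

one_hot <- function(phase, n_classes = 10) {
  phase <- as.integer(phase)
  if (any(is.na(phase)) || any(phase < 0 | phase >= n_classes)) {
    abort(sprintf("Phase labels must lie in 0..%d.", n_classes - 1))
  }
  m <- matrix(0, length(phase), n_classes)
  m[cbind(seq_along(phase), phase + 1L)] <- 1
  colnames(m) <- paste0("Y", 0:(n_classes - 1))
  m
}
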