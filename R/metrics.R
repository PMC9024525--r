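# Evaluation formulas: per-phase one-vs-rest confusion counts, precision /
# recall / F1 in percent, total accuracy (the macro mean of the ten F1
# scores), and MSE / MAE / R-squared for regression.

check_phase_labels <- function(x, what) {
  x <- as.integer(x)
  if (anyNA(x) || any(x < 0 | x > 9)) {
    abort(sprintf("`%s` must contain integer phases in 0..9.", what))
  }
  x
}

#' Per-phase confusion counts
#'
#' One-vs-rest counts for each of the 10 phases: TP = correctly returned
#' phase p, FP = phase p returned for a sample of another phase, FN = a
#' sample of phase p returned as another phase.
#'
#' @param truth,estimate Equal-length integer vectors of phases 0-9.
#' @return Tibble with columns `phase`, `tp`, `fp`, `fn`.
#' @export
#' @examples
#' confusion_counts(rep(0:9, each = 10), rep(0:9, each = 10))
confusion_counts <- function(truth, estimate) {
  truth <- check_phase_labels(truth, "truth")
  estimate <- check_phase_labels(estimate, "estimate")
  if (length(truth) != length(estimate)) {
    abort("`truth` and `estimate` must have the same length.")
  }
  purrr::map_dfr(0:9, function(p) {
    tibble::tibble(
      phase = p,
      tp = sum(truth == p & estimate == p),
      fp = sum(truth != p & estimate == p),
      fn = sum(truth == p & estimate != p)
    )
  })
}

f1_from_pr <- function(precision, recall) {
  ifelse(precision + recall == 0, 0, 2 * precision * recall / (precision + recall))
}

#' Precision, recall and F1 from confusion counts
#'
#' Precision = TP/(TP+FP), Recall = TP/(TP+FN), F1 their harmonic mean, all
#' in percent. A phase with no true positives and an empty denominator is
#' scored 0% with a warning (the convention for degenerate one-vs-rest
#' cells).
#'
#' @param counts Tibble from [confusion_counts()] (columns `tp`, `fp`, `fn`).
#' @return The input with `precision`, `recall`, `f1` columns (percent).
#' @export
precision_recall_f1 <- function(counts) {
  stopifnot(all(c("tp", "fp", "fn") %in% names(counts)))
  if (any(counts$tp < 0 | counts$fp < 0 | counts$fn < 0)) {
    abort("Confusion counts must be non-negative.")
  }
  if (any(counts$tp == 0 & (counts$fp > 0 | counts$fn > 0))) {
    warn("Phase(s) with no true positives scored F1 = 0%.")
  }
  prec <- ifelse(counts$tp + counts$fp == 0, 0, counts$tp / (counts$tp + counts$fp))
  rec <- ifelse(counts$tp + counts$fn == 0, 0, counts$tp / (counts$tp + counts$fn))
  dplyr::mutate(
    counts,
    precision = 100 * prec,
    recall = 100 * rec,
    f1 = 100 * f1_from_pr(prec, rec)
  )
}

#' Total accuracy: the macro mean of the ten per-phase F1 scores
#'
#' @param f1_scores Exactly 10 per-phase F1 percentages.
#' @return A single percentage.
#' @export
#' @examples
#' total_accuracy(rep(100, 10))
total_accuracy <- function(f1_scores) {
  if (length(f1_scores) != 10 || anyNA(f1_scores)) {
    abort("`f1_scores` must be exactly 10 non-missing values.")
  }
  mean(f1_scores)
}

#' Classification report
#'
#' Bundles the per-phase confusion counts, precision/recall/F1 (percent)
#' and the total accuracy for a set of predictions.
#'
#' @param truth,estimate Integer phase vectors (0-9).
#' @return Object of class `classification_report` with elements `table`,
#'   `total_accuracy`, `n`.
#' @export
classification_report <- function(truth, estimate) {
  tab <- precision_recall_f1(confusion_counts(truth, estimate))
  structure(
    list(
      table = tab,
      total_accuracy = total_accuracy(tab$f1),
      n = length(truth),
      truth = as.integer(truth),
      estimate = as.integer(estimate)
    ),
    class = "classification_report"
  )
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf(
    "<classification_report> %d samples, total accuracy %.2f%%\n",
    x$n, x$total_accuracy
  ))
  print(x$table, ...)
  invisible(x)
}

#' @method tidy classification_report
#' @export
tidy.classification_report <- function(x, ...) x$table

#' @method glance classification_report
#' @export
glance.classification_report <- function(x, ...) {
  tibble::tibble(
    total_accuracy = x$total_accuracy,
    n = x$n,
    n_errors = sum(x$truth != x$estimate)
  )
}

#' MSE, MAE and R-squared
#'
#' Mean squared error, mean absolute error, and the coefficient of
#' determination computed as (Var(Y) - MSE) / Var(Y) with the population
#' (divide-by-n) variance of the true values, matching the 1/n convention
#' of the error terms.
#'
#' @param truth,estimate Equal-length numeric vectors.
#' @return Tibble with columns `mse`, `mae`, `r2`.
#' @export
#' @examples
#' regression_metrics(c(0, 0.5, 1), c(0.1, 0.5, 0.9))
regression_metrics <- function(truth, estimate) {
  truth <- as.numeric(truth)
  estimate <- as.numeric(estimate)
  if (length(truth) == 0 || length(truth) != length(estimate)) {
    abort("`truth` and `estimate` must be equal-length, non-empty vectors.")
  }
  v <- mean((truth - mean(truth))^2)
  if (v < 1e-15) {
    abort("R-squared is undefined for a constant `truth` sequence.")
  }
  mse <- mean((truth - estimate)^2)
  tibble::tibble(
    mse = mse,
    mae = mean(abs(truth - estimate)),
    r2 = (v - mse) / v
  )
}

#' Regression report on the normalized and millimetre scales
#'
#' The percent error figures customary for min-max-normalized targets are
#' the normalized-scale MSE and MAE times 100 (e.g. MSE 1.3% is 0.013 on
#' the `[0, 1]` scale); the millimetre scale is reported alongside to avoid
#' ambiguity. R-squared is scale-invariant under the affine min-max map, so
#' a single value is reported.
#'
#' @param truth_norm,pred_norm Target and prediction on the normalized scale.
#' @param truth_mm,pred_mm The same on the millimetre scale (optional).
#' @return Object of class `regression_report`.
#' @export
regression_report <- function(truth_norm, pred_norm,
                              truth_mm = NULL, pred_mm = NULL) {
  norm <- regression_metrics(truth_norm, pred_norm)
  mm <- if (!is.null(truth_mm)) regression_metrics(truth_mm, pred_mm) else NULL
  structure(
    list(
      mse_pct = 100 * norm$mse,
      mae_pct = 100 * norm$mae,
      r2 = norm$r2,
      normalized = norm,
      mm = mm,
      n = length(truth_norm),
      data = tibble::tibble(
        truth_norm = as.numeric(truth_norm),
        pred_norm = as.numeric(pred_norm),
        truth_mm = if (is.null(truth_mm)) NA_real_ else as.numeric(truth_mm),
        pred_mm = if (is.null(pred_mm)) NA_real_ else as.numeric(pred_mm)
      )
    ),
    class = "regression_report"
  )
}

#' @export
print.regression_report <- function(x, ...) {
  cat(sprintf(
    "<regression_report> %d samples | MSE %.3f%% MAE %.3f%% R^2 %.4f\n",
    x$n, x$mse_pct, x$mae_pct, x$r2
  ))
  if (!is.null(x$mm)) {
    cat(sprintf(
      "  millimetre scale: MSE %.4f mm^2, MAE %.4f mm\n",
      x$mm$mse, x$mm$mae
    ))
  }
  invisible(x)
}

#' @method tidy regression_report
#' @export
tidy.regression_report <- function(x, ...) {
  out <- tibble::tibble(
    scale = "normalized",
    mse = x$normalized$mse, mae = x$normalized$mae, r2 = x$normalized$r2
  )
  if (!is.null(x$mm)) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      scale = "mm", mse = x$mm$mse, mae = x$mm$mae, r2 = x$mm$r2
    ))
  }
  out
}

#' @method glance regression_report
#' @export
glance.regression_report <- function(x, ...) {
  tibble::tibble(
    mse_pct = x$mse_pct, mae_pct = x$mae_pct, r2 = x$r2, n = x$n
  )
}
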