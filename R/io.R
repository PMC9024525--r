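# File formats: trace CSV, profile / manifest YAML, and JSON model
# checkpoints sufficient for bit-exact reload.

.trace_required <- c("time_s", "marker_x_mm", "marker_y_mm", "marker_z_mm")
.trace_optional <- c("tumor_disp_mm", "phase")

#' Write a motion trace to CSV
#'
#' Columns: `time_s, marker_x_mm, marker_y_mm, marker_z_mm, tumor_disp_mm,
#' phase`; the last two are written empty when absent. Generator-internal
#' ground truth (the clean surrogate, cycle-start indices) is not part of
#' the interchange format.
#'
#' @param trace A `motion_trace`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  out <- tibble::as_tibble(trace)[, intersect(
    c(.trace_required, .trace_optional), names(trace)
  )]
  for (col in .trace_optional) {
    if (!col %in% names(out)) out[[col]] <- NA
  }
  readr::write_csv(out[, c(.trace_required, .trace_optional)], path, na = "")
  invisible(path)
}

#' Read a motion trace from CSV
#'
#' Validates the schema (missing required columns are reported by name),
#' strictly increasing uniform time, and drops optional columns that are
#' entirely empty.
#'
#' @param path CSV file written by [write_trace()] (or matching its dialect).
#' @param subject_id Identifier to attach.
#' @return A `motion_trace`.
#' @export
read_trace <- function(path, subject_id = basename(path)) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  miss <- setdiff(.trace_required, names(df))
  if (length(miss)) {
    abort(paste0(
      "Trace file is missing required column(s): ",
      paste(miss, collapse = ", ")
    ))
  }
  dt <- diff(df$time_s)
  if (any(dt <= 0)) abort("`time_s` must be strictly increasing.")
  if (diff(range(dt)) > 1e-6 * stats::median(dt) + 1e-12) {
    abort("`time_s` must be uniformly sampled.")
  }
  for (col in .trace_optional) {
    if (col %in% names(df) && all(is.na(df[[col]]))) df[[col]] <- NULL
  }
  if ("phase" %in% names(df)) {
    ok <- is.na(df$phase) | (df$phase %in% 0:9)
    if (!all(ok)) abort("`phase` values must lie in 0..9 where present.")
    df$phase <- as.integer(df$phase)
  }
  new_motion_trace(df, subject_id, 1 / stats::median(dt))
}

#' Write / read a subject profile as YAML
#'
#' @param profile One-row profile tibble from [sample_profile()].
#' @param path File path.
#' @return `path` invisibly; [read_profile()] returns the profile tibble.
#' @export
write_profile <- function(profile, path) {
  yaml::write_yaml(as.list(profile[1, ]), path, precision = 15)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  tibble::as_tibble(yaml::read_yaml(path))
}

#' Write a cohort manifest as YAML
#'
#' Records the seed, cohort parameters, per-subject generator parameters and
#' the train/test split of a [generate_cohort()] result.
#'
#' @param cohort A `motion_cohort`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(cohort, path) {
  m <- attr(cohort, "manifest")
  m$subjects <- lapply(seq_len(nrow(m$subjects)), function(i) as.list(m$subjects[i, ]))
  m$split <- lapply(seq_len(nrow(m$split)), function(i) as.list(m$split[i, ]))
  yaml::write_yaml(m, path, precision = 15)
  invisible(path)
}

mat_to_list <- function(m) {
  list(dim = dim(m), data = as.numeric(t(unname(m)))) # row-major
}

list_to_mat <- function(l) {
  matrix(l$data, l$dim[1], l$dim[2], byrow = TRUE)
}

scaler_to_list <- function(s) {
  if (is.null(s)) return(NULL)
  c(list(type = class(s)[1]), unclass(s))
}

#' Save a fitted model checkpoint
#'
#' Serializes head kind, layer widths, every weight and bias array
#' (row-major with declared shapes), the fitted scalers and the training
#' configuration as JSON at full double precision, sufficient for bit-exact
#' reload with [read_model()].
#'
#' @param fit A `tsnet_fit`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_model <- function(fit, path) {
  p <- fit$params
  obj <- list(
    format = "respnet-model-1",
    head = fit$head,
    widths = .hidden_widths,
    W_in = mat_to_list(p$W_in),
    B_in = as.numeric(p$B_in),
    W = lapply(p$W, mat_to_list),
    B = lapply(p$B, as.numeric),
    x_scaler = scaler_to_list(fit$x_scaler),
    y_scaler = scaler_to_list(fit$y_scaler),
    config = unclass(fit$config),
    best_epoch = fit$best_epoch,
    stopped_early = fit$stopped_early,
    n_train = fit$n_train,
    n_test = fit$n_test,
    history = as.list(fit$history)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Load a fitted model checkpoint
#'
#' @param path File written by [write_model()].
#' @return A `tsnet_fit`.
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$format, "respnet-model-1")) {
    abort("Not a recognised model checkpoint.")
  }
  num <- function(x) vapply(x, as.numeric, numeric(1))
  from_mat <- function(l) list_to_mat(list(dim = num(l$dim), data = num(l$data)))
  from_scaler <- function(l) {
    if (is.null(l)) return(NULL)
    feats <- vapply(l$features, as.character, character(1))
    out <- list(features = feats)
    for (f in setdiff(names(l), c("type", "features"))) {
      out[[f]] <- stats::setNames(num(l[[f]]), feats)
    }
    structure(out[c(setdiff(names(out), "features"), "features")],
              class = l$type)
  }
  params <- structure(
    list(
      head = obj$head,
      W_in = from_mat(obj$W_in),
      B_in = num(obj$B_in),
      W = lapply(obj$W, from_mat),
      B = lapply(obj$B, num)
    ),
    class = "tsnet_params"
  )
  cfg <- structure(obj$config, class = "tsnet_config")
  structure(
    list(
      head = obj$head, params = params,
      history = tibble::tibble(
        epoch = num(obj$history$epoch),
        train_loss = num(obj$history$train_loss),
        test_loss = num(obj$history$test_loss)
      ),
      best_epoch = obj$best_epoch, stopped_early = obj$stopped_early,
      config = cfg,
      x_scaler = from_scaler(obj$x_scaler),
      y_scaler = from_scaler(obj$y_scaler),
      n_train = obj$n_train, n_test = obj$n_test
    ),
    class = "tsnet_fit"
  )
}
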