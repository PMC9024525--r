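# Breathing-cycle detection, ten-phase binning, and assembly of the
# time-lagged feature windows consumed by the network.

dominant_period <- function(y, sample_rate) {
  y <- y - mean(y)
  n <- length(y)
  p <- Mod(fft(y))^2
  ks <- 2:floor(n / 2)
  k <- ks[which.max(p[ks])]
  n / ((k - 1) * sample_rate)
}

#' Detect breathing cycles (end-inhale peaks)
#'
#' Finds the chest-peak sample indices that delimit breathing cycles on the
#' anterior-posterior marker channel. Local maxima are screened by
#' topographic prominence (at least `prominence` times the trace
#' peak-to-peak) and a minimum separation of half the nominal period; the
#' nominal period defaults to the dominant periodogram period.
#'
#' @param trace A `motion_trace`.
#' @param min_period Nominal breathing period in seconds; `NULL` to estimate
#'   it spectrally.
#' @param prominence Minimum prominence as a fraction of the trace
#'   peak-to-peak range.
#'
#' @return Strictly increasing integer sample indices of end-inhale peaks.
#' @export
#' @examples
#' pr <- sample_profile("regular", "normal", seed = 1)
#' tr <- generate_trace(pr, seed = 1)
#' detect_cycles(tr)
detect_cycles <- function(trace, min_period = NULL, prominence = 0.2) {
  y <- trace$marker_y_mm
  n <- length(y)
  p2p <- diff(range(y))
  if (!is.finite(p2p) || p2p < 1e-8) {
    abort("Cannot detect cycles: the AP marker channel is constant.")
  }
  sr <- attr(trace, "sample_rate") %||% (1 / stats::median(diff(trace$time_s)))
  min_period <- min_period %||% dominant_period(y, sr)
  min_sep <- max(1L, round(0.5 * min_period * sr))

  interior <- 2:(n - 1)
  cand <- interior[y[interior] > y[interior - 1] & y[interior] >= y[interior + 1]]
  # a trace that starts or ends at its summit still anchors a cycle there;
  # a merely rising edge does not count as a peak
  top <- max(y) - 1e-9 * p2p
  if (y[1] > y[2] && y[1] >= top) cand <- c(1L, cand)
  if (y[n] > y[n - 1] && y[n] >= top) cand <- c(cand, n)
  if (length(cand) == 0) abort("Cannot detect cycles: no local maxima found.")

  # topographic prominence; a boundary peak is judged by its open side only
  prom <- vapply(cand, function(i) {
    h <- y[i]
    lmin <- if (i == 1) NA_real_ else {
      left <- y[seq_len(i - 1)]
      hi <- which(left > h)
      min(left[seq.int(if (length(hi)) max(hi) else 1L, i - 1)])
    }
    rmin <- if (i == n) NA_real_ else {
      right <- y[seq.int(i + 1, n)]
      hi <- which(right > h)
      min(right[seq.int(1L, if (length(hi)) min(hi) else length(right))])
    }
    h - max(lmin, rmin, na.rm = TRUE)
  }, numeric(1))
  keep <- cand[prom >= prominence * p2p]
  if (length(keep) == 0) {
    abort("Cannot detect cycles: no sufficiently prominent peaks.")
  }

  # enforce the minimum separation, preferring taller peaks
  ord <- keep[order(-y[keep], keep)]
  kept <- integer()
  for (i in ord) {
    if (all(abs(kept - i) >= min_sep)) kept <- c(kept, i)
  }
  kept <- sort(kept)
  if (length(kept) < 2) {
    abort("Cannot detect cycles: fewer than 2 breathing cycles present.")
  }
  kept
}

#' Assign the 10 respiratory phases
#'
#' Divides each breathing cycle (the interval between consecutive end-inhale
#' peaks) into 10 equal-duration bins and labels every sample with its bin:
#' 0 = end-inhale, 1-4 mid-exhale, 5 = end-exhale, 6-9 mid-inhale. Samples
#' outside complete cycles are left `NA`. Peak times are refined to
#' sub-sample accuracy by parabolic interpolation before the bins are laid
#' out, so labels do not depend on where the true peak falls between
#' samples.
#'
#' @param trace A `motion_trace`.
#' @param cycle_starts Peak indices from [detect_cycles()] (or the generator
#'   ground truth).
#'
#' @return Integer vector of phase labels (0-9 or `NA`), one per sample.
#' @export
assign_phases <- function(trace, cycle_starts = NULL) {
  cycle_starts <- cycle_starts %||% attr(trace, "cycle_starts") %||%
    detect_cycles(trace)
  if (length(cycle_starts) < 2) {
    abort("`cycle_starts` must contain at least 2 peaks.")
  }
  t <- trace$time_s
  starts <- refine_peak_times(trace, cycle_starts)
  phase <- rep(NA_integer_, length(t))
  for (k in seq_len(length(starts) - 1)) {
    t0 <- starts[k]
    t1 <- starts[k + 1]
    in_cycle <- which(t >= t0 & t < t1)
    phase[in_cycle] <- pmin(floor(10 * (t[in_cycle] - t0) / (t1 - t0)), 9L)
  }
  as.integer(phase)
}

# sub-sample refinement of a peak time: a three-point parabola through the
# samples around the grid maximum; exact for symmetric peaks on-grid
refine_peak_times <- function(trace, idx) {
  t <- trace$time_s
  y <- trace$marker_y_mm
  n <- length(y)
  dt <- t[2] - t[1]
  vapply(idx, function(i) {
    if (i <= 1 || i >= n) return(t[i])
    denom <- y[i - 1] - 2 * y[i] + y[i + 1]
    if (abs(denom) < 1e-12) return(t[i])
    delta <- 0.5 * (y[i - 1] - y[i + 1]) / denom
    t[i] + max(-0.5, min(0.5, delta)) * dt
  }, numeric(1))
}

interp_channel <- function(trace, col, times) {
  approx(trace$time_s, trace[[col]], xout = times, rule = 1)$y
}

#' Build time-lagged feature windows
#'
#' Assembles one training record per (cycle, phase): the 11-feature vectors
#' at times t0, t0 - lag and t0 - 2 lag, where t0 is the midpoint of the
#' phase bin. Marker coordinates are read off the trace by linear
#' interpolation; the eight subject specifics are constant across the three
#' time steps. Windows whose earliest time step precedes the trace start are
#' dropped. The classification target is the bin phase; when the trace
#' carries tumor displacement, the regression target is its value at t0.
#'
#' @param trace A `motion_trace`.
#' @param profile The subject profile supplying the 8 specifics.
#' @param cycle_starts Peak indices; defaults to the trace's ground truth,
#'   falling back to [detect_cycles()].
#' @param lag Spacing between the three time steps, seconds; default one
#'   phase bin (cycle period / 10), evaluated per cycle.
#'
#' @return A tibble with identifiers (`subject_id`, `cycle_index`, `t0_s`),
#'   targets (`phase`, `disp_mm`) and the 33 feature columns of
#'   [feature_cols()].
#' @export
#' @examples
#' pr <- sample_profile("regular", "normal", seed = 1)
#' tr <- generate_trace(pr, seed = 1)
#' w <- build_windows(tr, pr)
#' dim(w)
build_windows <- function(trace, profile, cycle_starts = NULL, lag = NULL) {
  cycle_starts <- cycle_starts %||% attr(trace, "cycle_starts") %||%
    detect_cycles(trace)
  if (length(cycle_starts) < 2) {
    abort("Need at least 2 cycle starts to window a trace.")
  }
  t <- trace$time_s
  start_times <- refine_peak_times(trace, cycle_starts)
  has_tumor <- "tumor_disp_mm" %in% names(trace)
  subject <- as.numeric(profile[1, c(
    "age", "weight", "height", "bpm", "hr", "tum_x", "tum_y", "tum_z"
  )])

  rows <- purrr::map(seq_len(length(start_times) - 1), function(k) {
    ts <- start_times[k]
    te <- start_times[k + 1]
    tau <- te - ts
    lag_k <- lag %||% (tau / 10)
    if (lag_k >= tau) {
      abort(sprintf(
        "`lag` (%.3f s) must be smaller than the cycle period (%.3f s).",
        lag_k, tau
      ))
    }
    t0 <- ts + (0:9 + 0.5) * tau / 10
    keep <- (t0 - 2 * lag_k) >= t[1]
    if (!any(keep)) return(NULL)
    t0 <- t0[keep]
    feats <- purrr::map(c(2, 1, 0), function(j) {
      tt <- t0 - j * lag_k
      cbind(
        interp_channel(trace, "marker_x_mm", tt),
        interp_channel(trace, "marker_y_mm", tt),
        interp_channel(trace, "marker_z_mm", tt),
        matrix(subject, length(tt), 8, byrow = TRUE)
      )
    })
    m <- do.call(cbind, feats)
    colnames(m) <- feature_cols()
    tibble::tibble(
      subject_id = profile$subject_id,
      cycle_index = k,
      phase = (0:9)[keep],
      disp_mm = if (has_tumor) {
        interp_channel(trace, "tumor_disp_mm", t0)
      } else {
        NA_real_
      },
      t0_s = t0
    ) |>
      dplyr::bind_cols(tibble::as_tibble(m))
  })
  dplyr::bind_rows(rows)
}

#' Extract the 33-column feature matrix from a window tibble
#'
#' @param windows Tibble from [build_windows()] or [phase_cohort()].
#' @return Numeric matrix, one row per window, columns in [feature_cols()]
#'   order.
#' @export
window_matrix <- function(windows) {
  miss <- setdiff(feature_cols(), names(windows))
  if (length(miss)) {
    abort(paste0(
      "`windows` is missing feature columns: ",
      paste(miss, collapse = ", ")
    ))
  }
  as.matrix(windows[, feature_cols()])
}
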