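# Pseudopatient breathing simulation: subject profiles, chest-wall marker
# traces, and surrogate-to-tumor coupling.

#' Waveform generator configuration
#'
#' Parameters of the simulated chest-wall waveform and of the coupling from
#' the chest-wall surrogate to the longitudinal tumor displacement. The
#' breathing waveform is the standard radiotherapy surrogate model
#' \eqn{s(t) = b \cos^{2n}(\pi t / \tau)} (Lujan-type), which dwells near
#' end-exhale longer than end-inhale as real traces do. Irregular breathing
#' adds per-cycle multiplicative amplitude and period jitter, a random-walk
#' baseline drift, and occasional shallow cycles.
#'
#' Programmed phantom trajectories are exact by construction, so the default
#' anterior-posterior measurement noise is zero; set `marker_noise_sd` to
#' emulate a sensor noise floor.
#'
#' @param amplitude Peak-to-peak chest-wall excursion b, mm.
#' @param shape_exponent Cosine power n (waveform is cos^(2n)); n >= 1.
#' @param amplitude_jitter_sd Per-cycle multiplicative amplitude jitter
#'   (lognormal sd, fraction); used for irregular breathing only.
#' @param period_jitter_sd Per-cycle multiplicative period jitter (fraction).
#' @param baseline_drift_sd Random-walk baseline drift per cycle, mm.
#' @param shallow_cycle_prob Probability that a cycle is shallow.
#' @param shallow_factor Amplitude multiplier applied to shallow cycles.
#' @param marker_noise_sd Additive Gaussian noise on the AP marker channel, mm.
#' @param lateral_jitter_sd Independent jitter on the lateral and longitudinal
#'   marker channels, mm.
#' @param tumor_gain Surrogate-to-tumor gain, mm displacement per mm excursion.
#' @param tumor_lag Internal-external time lag, seconds.
#' @param tumor_noise_sd Additive Gaussian noise on the tumor displacement, mm.
#'
#' @return A list of class `waveform_config`.
#' @export
#' @examples
#' waveform_config(amplitude = 10, tumor_gain = 1.2)
waveform_config <- function(amplitude = 8,
                            shape_exponent = 2,
                            amplitude_jitter_sd = 0.3,
                            period_jitter_sd = 0.2,
                            baseline_drift_sd = 0.5,
                            shallow_cycle_prob = 0.2,
                            shallow_factor = 0.3,
                            marker_noise_sd = 0,
                            lateral_jitter_sd = 0.2,
                            tumor_gain = 1.5,
                            tumor_lag = 0.15,
                            tumor_noise_sd = 0.2) {
  cfg <- list(
    amplitude = amplitude, shape_exponent = shape_exponent,
    amplitude_jitter_sd = amplitude_jitter_sd,
    period_jitter_sd = period_jitter_sd,
    baseline_drift_sd = baseline_drift_sd,
    shallow_cycle_prob = shallow_cycle_prob,
    shallow_factor = shallow_factor,
    marker_noise_sd = marker_noise_sd,
    lateral_jitter_sd = lateral_jitter_sd,
    tumor_gain = tumor_gain, tumor_lag = tumor_lag,
    tumor_noise_sd = tumor_noise_sd
  )
  if (!is.numeric(amplitude) || amplitude <= 0) {
    abort("`amplitude` must be a positive number of millimetres.")
  }
  if (shape_exponent < 1) abort("`shape_exponent` must be >= 1.")
  for (p in c("shallow_cycle_prob", "shallow_factor")) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) {
      abort(sprintf("`%s` must lie in [0, 1].", p))
    }
  }
  sds <- c(
    "amplitude_jitter_sd", "period_jitter_sd", "baseline_drift_sd",
    "marker_noise_sd", "lateral_jitter_sd", "tumor_noise_sd"
  )
  for (p in sds) {
    if (cfg[[p]] < 0) abort(sprintf("`%s` must be >= 0.", p))
  }
  structure(cfg, class = "waveform_config")
}

.patterns <- c("regular", "irregular")
.bpm_classes <- c("low", "normal", "high")

bpm_range <- function(bpm_class) {
  switch(bpm_class,
    low = c(8, 12),
    normal = c(12, 20),
    high = c(20, 30)
  )
}

check_enum <- function(value, allowed, what) {
  if (!is.character(value) || length(value) != 1 || !value %in% allowed) {
    abort(sprintf(
      "`%s` must be one of %s, got %s.",
      what, paste0("'", allowed, "'", collapse = ", "),
      paste0("'", as.character(value), "'", collapse = "")
    ))
  }
  value
}

#' Draw a synthetic subject profile
#'
#' Samples the eight subject-specific features used as network inputs: age
#' 45-65 y, weight 50-80 kg, height 150-185 cm, heart rate 60-100 bpm, a
#' breathing rate consistent with the requested rate class (low < 12,
#' normal 12-20, high > 20 breaths/min) and a tumor midpoint uniform in a
#' lung-sized box.
#'
#' @param pattern Breathing pattern, `"regular"` or `"irregular"`.
#' @param bpm_class Breathing-rate class, `"low"`, `"normal"` or `"high"`.
#' @param seed Optional integer seed; fixing it makes the draw reproducible.
#' @param subject_id Identifier stored with the profile.
#' @param tumor_box 2x3 matrix of (min, max) tumor-midpoint coordinates, mm.
#'
#' @return A one-row tibble with the profile fields.
#' @export
#' @examples
#' sample_profile("regular", "normal", seed = 7)
sample_profile <- function(pattern, bpm_class, seed = NULL,
                           subject_id = "S01",
                           tumor_box = rbind(
                             c(-80, -120, -100),
                             c(80, 40, 100)
                           )) {
  pattern <- check_enum(pattern, .patterns, "pattern")
  bpm_class <- check_enum(bpm_class, .bpm_classes, "bpm_class")
  if (!is.null(seed)) withr::local_seed(seed)
  br <- bpm_range(bpm_class)
  # keep the draw strictly inside the open ends of the class definition
  bpm <- runif(1, br[1], br[2])
  if (bpm_class == "high") bpm <- max(bpm, br[1] + 1e-6)
  tibble::tibble(
    subject_id = subject_id,
    age = sample(45:65, 1),
    weight = runif(1, 50, 80),
    height = runif(1, 150, 185),
    bpm = bpm,
    hr = runif(1, 60, 100),
    tum_x = runif(1, tumor_box[1, 1], tumor_box[2, 1]),
    tum_y = runif(1, tumor_box[1, 2], tumor_box[2, 2]),
    tum_z = runif(1, tumor_box[1, 3], tumor_box[2, 3]),
    pattern = pattern,
    bpm_class = bpm_class
  )
}

new_motion_trace <- function(df, subject_id, sample_rate, cycle_starts = NULL) {
  structure(
    df,
    subject_id = subject_id,
    sample_rate = sample_rate,
    cycle_starts = cycle_starts,
    class = c("motion_trace", class(tibble::as_tibble(df)))
  )
}

#' @export
print.motion_trace <- function(x, ...) {
  cat(sprintf(
    "<motion_trace> subject %s, %d samples @ %g Hz, %d known cycle starts\n",
    attr(x, "subject_id") %||% "?", nrow(x),
    attr(x, "sample_rate") %||% NA_real_,
    length(attr(x, "cycle_starts"))
  ))
  NextMethod()
}

#' Simulate a chest-wall marker trace
#'
#' Emits a uniformly sampled marker-block trajectory for one subject. The
#' anterior-posterior channel (`marker_y_mm`) carries the breathing waveform
#' \eqn{b \cos^{2n}(\pi t/\tau)} with period \eqn{\tau = 60/\mathrm{bpm}} s;
#' end-inhale peaks sit at cycle starts. For irregular breathing each cycle
#' draws its own amplitude, period and baseline per the configuration, with
#' the amplitude and baseline ramped linearly across the cycle so the
#' waveform stays continuous. The lateral (`marker_x_mm`) and longitudinal
#' (`marker_z_mm`) channels carry small independent jitter.
#'
#' Generator ground truth is attached: `phase` (0-9 within complete cycles,
#' NA elsewhere), `surrogate_mm` (the noise-free excursion above baseline)
#' and the `cycle_starts` attribute (sample indices of end-inhale peaks).
#'
#' @param profile Subject profile from [sample_profile()].
#' @param config A [waveform_config()].
#' @param duration Trace length, seconds; must cover at least 3 breathing
#'   cycles at the profile's rate. Default 5 nominal cycles.
#' @param sample_rate Sampling rate, Hz (default 30, a time-of-flight camera
#'   frame rate).
#' @param seed Optional integer seed.
#'
#' @return A `motion_trace` tibble with columns `time_s`, `marker_x_mm`,
#'   `marker_y_mm`, `marker_z_mm`, `surrogate_mm`, `phase`.
#' @export
#' @examples
#' pr <- sample_profile("regular", "normal", seed = 1)
#' tr <- generate_trace(pr, waveform_config(), seed = 1)
#' head(tr)
generate_trace <- function(profile, config = waveform_config(),
                           duration = NULL, sample_rate = 30, seed = NULL) {
  stopifnot(inherits(config, "waveform_config"))
  tau <- 60 / profile$bpm
  duration <- duration %||% (5 * tau)
  if (duration < 3 * tau) {
    abort(sprintf(
      "`duration` (%.2f s) must cover at least 3 breathing cycles (%.2f s at %.1f bpm).",
      duration, 3 * tau, profile$bpm
    ))
  }
  if (!is.null(seed)) withr::local_seed(seed)
  irregular <- identical(profile$pattern, "irregular")

  # per-cycle parameters, one extra cycle so envelopes can be ramped
  starts <- 0
  amps <- numeric()
  bases <- numeric()
  periods <- numeric()
  base <- 0
  while (tail(starts, 1) <= duration) {
    if (irregular) {
      p <- tau * exp(rnorm(1, 0, config$period_jitter_sd))
      a <- config$amplitude * exp(rnorm(1, 0, config$amplitude_jitter_sd))
      if (runif(1) < config$shallow_cycle_prob) a <- a * config$shallow_factor
      base <- base + rnorm(1, 0, config$baseline_drift_sd)
    } else {
      p <- tau
      a <- config$amplitude
    }
    periods <- c(periods, p)
    amps <- c(amps, a)
    bases <- c(bases, base)
    starts <- c(starts, tail(starts, 1) + p)
  }
  n_cycles <- length(periods)

  time <- seq(0, duration, by = 1 / sample_rate)
  k <- findInterval(time, starts[seq_len(n_cycles)])
  u <- (time - starts[k]) / periods[k]
  a_next <- c(amps[-1], tail(amps, 1))
  b_next <- c(bases[-1], tail(bases, 1))
  env <- amps[k] + (a_next[k] - amps[k]) * u
  bl <- bases[k] + (b_next[k] - bases[k]) * u
  surrogate <- env * cos(pi * u)^(2 * config$shape_exponent)

  n <- length(time)
  ap <- bl + surrogate +
    if (config$marker_noise_sd > 0) rnorm(n, 0, config$marker_noise_sd) else 0
  lat <- rnorm(n, 0, config$lateral_jitter_sd)
  lon <- rnorm(n, 0, config$lateral_jitter_sd)

  # ground-truth labels only inside complete cycles
  complete <- starts[k + 1] <= duration + 1e-9
  phase <- ifelse(complete, pmin(floor(10 * u), 9L), NA_integer_)

  start_times <- starts[seq_len(n_cycles)]
  start_times <- start_times[start_times <= duration + 1e-9]
  cycle_starts <- round(start_times * sample_rate) + 1L
  cycle_starts <- cycle_starts[cycle_starts <= n]

  df <- tibble::tibble(
    time_s = time,
    marker_x_mm = lat,
    marker_y_mm = ap,
    marker_z_mm = lon,
    surrogate_mm = surrogate,
    phase = as.integer(phase)
  )
  new_motion_trace(df, profile$subject_id, sample_rate, cycle_starts)
}

# Noise-free excursion above the per-cycle baseline, recovered from the AP
# channel when the generator ground truth is not available (e.g. after a
# round-trip through the CSV format).
empirical_surrogate <- function(trace) {
  cs <- attr(trace, "cycle_starts") %||% detect_cycles(trace)
  y <- trace$marker_y_mm
  t <- trace$time_s
  n <- length(y)
  bounds <- unique(c(1L, cs, n))
  mins <- vapply(seq_len(length(bounds) - 1), function(i) {
    min(y[bounds[i]:bounds[i + 1]])
  }, numeric(1))
  mid <- (t[bounds[-length(bounds)]] + t[bounds[-1]]) / 2
  baseline <- approx(mid, mins, xout = t, rule = 2)$y
  pmax(y - baseline, 0)
}

#' Couple tumor displacement to the chest-wall surrogate
#'
#' Adds (or overwrites) the longitudinal tumor displacement as a lagged,
#' scaled copy of the chest-wall excursion:
#' \eqn{d(t) = g \, s(t - \ell) + \epsilon}, with gain g (`tumor_gain`),
#' lag \eqn{\ell} (`tumor_lag`, s) and Gaussian noise sd `tumor_noise_sd`.
#' The excursion s(t) is the generator ground truth when present, otherwise
#' the AP channel minus its per-cycle baseline.
#'
#' @param trace A `motion_trace`.
#' @param config A [waveform_config()] supplying gain, lag and noise sd.
#' @param seed Optional integer seed.
#'
#' @return The trace with a `tumor_disp_mm` column.
#' @export
#' @examples
#' pr <- sample_profile("regular", "normal", seed = 1)
#' tr <- couple_tumor(generate_trace(pr, seed = 1), waveform_config(), seed = 2)
#' range(tr$tumor_disp_mm)
couple_tumor <- function(trace, config = waveform_config(), seed = NULL) {
  stopifnot(inherits(trace, "motion_trace"))
  span <- max(trace$time_s) - min(trace$time_s)
  if (config$tumor_lag >= span) {
    abort(sprintf(
      "`tumor_lag` (%.2f s) must be smaller than the trace duration (%.2f s).",
      config$tumor_lag, span
    ))
  }
  if (!is.null(seed)) withr::local_seed(seed)
  surr <- if ("surrogate_mm" %in% names(trace)) {
    trace$surrogate_mm
  } else {
    empirical_surrogate(trace)
  }
  lagged <- approx(trace$time_s, surr,
    xout = trace$time_s - config$tumor_lag, rule = 2
  )$y
  noise <- if (config$tumor_noise_sd > 0) {
    rnorm(length(lagged), 0, config$tumor_noise_sd)
  } else {
    0
  }
  trace$tumor_disp_mm <- config$tumor_gain * lagged + noise
  trace
}
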