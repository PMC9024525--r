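# Shared fixtures, built in code at test time.

quiet_config <- function(...) {
  # deterministic waveform: no jitter, no noise; `...` overrides any field
  args <- utils::modifyList(
    list(
      amplitude_jitter_sd = 0, period_jitter_sd = 0, baseline_drift_sd = 0,
      shallow_cycle_prob = 0, marker_noise_sd = 0, lateral_jitter_sd = 0,
      tumor_noise_sd = 0
    ),
    list(...)
  )
  do.call(waveform_config, args)
}

test_profile <- function(bpm = 15, pattern = "regular", seed = 1) {
  pr <- sample_profile(pattern, "normal", seed = seed)
  pr$bpm <- bpm
  pr
}

# analytic cos^2n trace on a uniform grid, bypassing the generator
analytic_trace <- function(amplitude = 8, period = 4, n_exp = 2,
                           duration = 40, sample_rate = 30) {
  time <- seq(0, duration, by = 1 / sample_rate)
  df <- tibble::tibble(
    time_s = time,
    marker_x_mm = 0 * time,
    marker_y_mm = amplitude * cos(pi * time / period)^(2 * n_exp),
    marker_z_mm = 0 * time
  )
  respnet:::new_motion_trace(df, "analytic", sample_rate)
}

small_windows <- function(n_subjects = 3, repeats = 3, pattern = "regular",
                          seed = 7, couple = TRUE) {
  co <- generate_cohort(
    n_regular = if (pattern == "regular") n_subjects else 0,
    n_irregular = if (pattern == "irregular") n_subjects else 0,
    repeats = repeats, seed = seed, couple = couple
  )
  phase_cohort(co)
}

flatten_params <- function(p) {
  c(as.numeric(p$W_in), as.numeric(p$B_in),
    unlist(lapply(p$W, as.numeric)), unlist(lapply(p$B, as.numeric)))
}

unflatten_params <- function(template, v) {
  p <- template
  i <- 0
  take <- function(n) {
    out <- v[(i + 1):(i + n)]
    i <<- i + n
    out
  }
  p$W_in <- matrix(take(length(p$W_in)), nrow(p$W_in), ncol(p$W_in))
  p$B_in <- take(length(p$B_in))
  for (k in 1:7) {
    p$W[[k]] <- matrix(take(length(p$W[[k]])), nrow(p$W[[k]]), ncol(p$W[[k]]))
  }
  for (k in 1:7) p$B[[k]] <- take(length(p$B[[k]]))
  p
}

numeric_gradient <- function(params, x, y, l1, h = 1e-5) {
  v0 <- flatten_params(params)
  vapply(seq_along(v0), function(i) {
    vp <- v0; vp[i] <- vp[i] + h
    vm <- v0; vm[i] <- vm[i] - h
    lp <- tsnet_loss(unflatten_params(params, vp), x, y, l1)$loss
    lm <- tsnet_loss(unflatten_params(params, vm), x, y, l1)$loss
    (lp - lm) / (2 * h)
  }, numeric(1))
}

random_batch <- function(head, n = 4, seed = 1) {
  withr::local_seed(seed)
  x <- matrix(rnorm(n * 33), n, 33)
  colnames(x) <- feature_cols()
  y <- if (head == "classifier") {
    respnet:::one_hot(sample(0:9, n, replace = TRUE))
  } else {
    runif(n)
  }
  list(x = x, y = y)
}
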