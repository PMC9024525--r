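test_that("profiles respect the population ranges and the rate classes", {
  cases <- tidyr::expand_grid(
    pattern = c("regular", "irregular"),
    bpm_class = c("low", "normal", "high")
  )
  for (i in seq_len(nrow(cases))) {
    pr <- sample_profile(cases$pattern[i], cases$bpm_class[i], seed = i)
    expect_gte(pr$age, 45)
    expect_lte(pr$age, 65)
    expect_gte(pr$weight, 50)
    expect_lte(pr$weight, 80)
    expect_true(all(is.finite(c(pr$tum_x, pr$tum_y, pr$tum_z))))
    rng <- switch(cases$bpm_class[i],
      low = c(8, 12), normal = c(12, 20), high = c(20, 30)
    )
    expect_gte(pr$bpm, rng[1])
    expect_lte(pr$bpm, rng[2])
  }
  # class bounds are honoured at the open ends
  lows <- purrr::map_dbl(1:40, ~ sample_profile("regular", "low", seed = .x)$bpm)
  expect_true(all(lows < 12))
  highs <- purrr::map_dbl(1:40, ~ sample_profile("regular", "high", seed = .x)$bpm)
  expect_true(all(highs > 20))
})

test_that("profile sampling is reproducible and rejects invalid enums", {
  expect_identical(
    sample_profile("regular", "normal", seed = 7),
    sample_profile("regular", "normal", seed = 7)
  )
  expect_error(sample_profile("sideways", "normal"), "pattern")
  expect_error(sample_profile("regular", "medium"), "bpm_class")
})

test_that("regular traces carry the programmed period and amplitude", {
  pr <- test_profile(bpm = 15)
  tr <- generate_trace(pr, quiet_config(amplitude = 9), duration = 40, seed = 3)
  # spectral oracle: the dominant periodogram period equals 60/bpm = 4 s
  y <- tr$marker_y_mm - mean(tr$marker_y_mm)
  p <- Mod(fft(y))^2
  ks <- 2:floor(length(y) / 2)
  f_dom <- (ks[which.max(p[ks])] - 1) * attr(tr, "sample_rate") / length(y)
  expect_equal(1 / f_dom, 4, tolerance = 0.05)
  # noiseless waveform attains its analytic extrema
  expect_equal(diff(range(tr$marker_y_mm)), 9, tolerance = 1e-9)
  # detected ground-truth cycle starts agree with the programmed period
  expect_equal(unique(round(diff(attr(tr, "cycle_starts")))), 4 * 30)
})

test_that("trace generation enforces the 3-cycle minimum duration", {
  pr <- test_profile(bpm = 12) # 5 s period
  expect_error(generate_trace(pr, duration = 10), "3 breathing cycles")
  expect_silent(generate_trace(pr, quiet_config(), duration = 15, seed = 1))
})

test_that("irregular breathing shows larger cycle-period variability", {
  cfg <- waveform_config(marker_noise_sd = 0)
  cv <- function(pattern, seed) {
    pr <- test_profile(bpm = 15, pattern = pattern, seed = 5)
    pr$pattern <- pattern
    tr <- generate_trace(pr, cfg, duration = 60, seed = seed)
    periods <- diff(tr$time_s[attr(tr, "cycle_starts")])
    sd(periods) / mean(periods)
  }
  for (seed in 1:3) {
    expect_gt(cv("irregular", seed), cv("regular", seed))
  }
})

test_that("shallow cycles appear at the configured rate and depth", {
  pr <- test_profile(bpm = 15, pattern = "irregular", seed = 2)
  cfg <- waveform_config(
    amplitude = 8, amplitude_jitter_sd = 0, period_jitter_sd = 0,
    baseline_drift_sd = 0, shallow_cycle_prob = 0.3, shallow_factor = 0.3,
    marker_noise_sd = 0
  )
  # over 14 cycles, P(no shallow cycle) = 0.7^14 < 1%; check a seed ensemble
  found <- purrr::map_lgl(1:5, function(seed) {
    tr <- generate_trace(pr, cfg, duration = 60, seed = seed)
    cs <- attr(tr, "cycle_starts")
    # a cycle's amplitude is its end-inhale peak height above baseline
    amps <- tr$surrogate_mm[cs]
    any(amps <= 0.3 * 8 + 1e-6)
  })
  expect_true(all(found))
})

test_that("tumor coupling is an affine map of the lagged surrogate", {
  pr <- test_profile(bpm = 15)
  tr <- generate_trace(pr, quiet_config(amplitude = 6), duration = 20, seed = 4)

  ident <- couple_tumor(tr, quiet_config(tumor_gain = 1, tumor_lag = 0))
  expect_equal(ident$tumor_disp_mm, tr$surrogate_mm, tolerance = 1e-12)

  doubled <- couple_tumor(tr, quiet_config(tumor_gain = 2, tumor_lag = 0))
  expect_equal(
    diff(range(doubled$tumor_disp_mm)),
    2 * diff(range(tr$surrogate_mm)),
    tolerance = 1e-12
  )

  lagged <- couple_tumor(tr, quiet_config(tumor_gain = 1.3, tumor_lag = 0.2))
  shifted <- approx(tr$time_s, tr$surrogate_mm,
    xout = tr$time_s - 0.2, rule = 2
  )$y
  expect_equal(cor(shifted, lagged$tumor_disp_mm), 1, tolerance = 1e-12)

  expect_error(
    couple_tumor(tr, quiet_config(tumor_lag = 30)),
    "tumor_lag"
  )
})

test_that("tumor-surrogate correlation decays as coupling noise grows", {
  pr <- test_profile(bpm = 15)
  tr <- generate_trace(pr, quiet_config(amplitude = 6), duration = 20, seed = 4)
  cors <- purrr::map_dbl(c(0, 0.5, 2, 8), function(nsd) {
    # average over a small seed ensemble to smooth sampling noise
    mean(purrr::map_dbl(1:4, function(s) {
      cpl <- couple_tumor(tr, quiet_config(tumor_lag = 0, tumor_noise_sd = nsd),
        seed = s
      )
      cor(tr$surrogate_mm, cpl$tumor_disp_mm)
    }))
  })
  expect_true(all(diff(cors) < 0))
})

test_that("cohorts reproduce the stated accounting and split fractions", {
  # 20 + 20 subjects x 1 repeat -> 400 phase-level records
  co <- generate_cohort(20, 20, repeats = 1, seed = 9)
  w <- phase_cohort(co)
  expect_equal(nrow(w), 400)
  expect_equal(unname(table(w$phase)), rep(40L, 10), ignore_attr = TRUE)

  # 2/3 - 1/3 split at trace granularity, equal contribution per pattern
  counts <- dplyr::count(w, pattern, split)
  expect_equal(
    counts$n[counts$split == "train"],
    rep(10L * round(2 / 3 * 20), 2)
  )

  # scaled version of the 6000-sample pseudopatient accounting:
  # 10 phases x (3 + 3) subjects x 10 repeats
  co2 <- generate_cohort(3, 3, repeats = 10, seed = 10)
  expect_equal(nrow(phase_cohort(co2)), 600)
})

test_that("cohort generation is byte-identical under a fixed seed", {
  a <- generate_cohort(2, 2, repeats = 2, seed = 31)
  b <- generate_cohort(2, 2, repeats = 2, seed = 31)
  expect_identical(a, b)
  expect_identical(phase_cohort(a), phase_cohort(b))
})

test_that("bpm_mix is validated against the pattern group size", {
  expect_error(
    generate_cohort(4, 0, repeats = 1, bpm_mix = c(low = 1, normal = 1, high = 1)),
    "sums to 3"
  )
  co <- generate_cohort(6, 0,
    repeats = 1, seed = 2,
    bpm_mix = c(low = 2, normal = 2, high = 2)
  )
  expect_equal(unname(table(co$bpm_class)), rep(2L, 3), ignore_attr = TRUE)
})
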