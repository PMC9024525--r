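# Cohort-scale simulation: many subjects x repeats, stratified train/test
# split, and phase-level windowing with the 10-records-per-trace accounting.

even_bpm_mix <- function(n) {
  base <- n %/% 3
  mix <- c(low = base, normal = base + n %% 3, high = base)
  mix
}

check_bpm_mix <- function(bpm_mix, n, pattern) {
  if (!all(sort(names(bpm_mix)) == sort(.bpm_classes))) {
    abort("`bpm_mix` must be a named vector with entries low, normal, high.")
  }
  if (sum(bpm_mix) != n) {
    abort(sprintf(
      "`bpm_mix` sums to %d but the %s group has %d subjects.",
      sum(bpm_mix), pattern, n
    ))
  }
  bpm_mix[.bpm_classes]
}

#' Generate a pseudopatient cohort
#'
#' Simulates `n_regular + n_irregular` subjects, each contributing `repeats`
#' marker traces with coupled tumor displacement. Breathing-rate classes are
#' spread across subjects per `bpm_mix` (default: as even as possible within
#' each pattern group). Each subject draws its own chest-wall amplitude and
#' surrogate-to-tumor gain, so inter-subject variability is part of the
#' cohort. Traces are split 2/3 train, 1/3 test within each pattern group,
#' ordered by (repeat, subject), so both patterns contribute equally and
#' every subject appears in both partitions.
#'
#' Once windowed with [phase_cohort()], the cohort yields exactly
#' `10 x (n_regular + n_irregular) x repeats` phase-level samples.
#'
#' @param n_regular,n_irregular Subjects per breathing pattern.
#' @param repeats Traces per subject.
#' @param bpm_mix Named counts (`low`, `normal`, `high`) per pattern group;
#'   must sum to the group size.
#' @param config Base [waveform_config()]; per-subject amplitude and tumor
#'   gain are drawn on top of it.
#' @param duration Trace length in seconds (default 5 nominal cycles).
#' @param sample_rate Sampling rate, Hz.
#' @param amplitude_range Per-subject chest amplitude range, mm.
#' @param tumor_gain_range Per-subject surrogate-to-tumor gain range.
#' @param couple Attach tumor displacement to every trace?
#' @param seed Integer seed; the cohort is byte-identical given the seed.
#'
#' @return A tibble of class `motion_cohort`: one row per subject x repeat
#'   with columns `subject_id`, `rep`, `pattern`, `bpm_class`, `split`, and
#'   list-columns `profile` and `trace`. The `manifest` attribute records
#'   seeds, per-subject parameters and the split.
#' @export
#' @examples
#' co <- generate_cohort(2, 2, repeats = 2, seed = 1)
#' dplyr::count(co, pattern, split)
generate_cohort <- function(n_regular, n_irregular, repeats,
                            bpm_mix = NULL,
                            config = waveform_config(),
                            duration = NULL, sample_rate = 30,
                            amplitude_range = c(4, 12),
                            tumor_gain_range = c(0.8, 2),
                            couple = TRUE, seed = 1) {
  if (n_regular < 0 || n_irregular < 0 || n_regular + n_irregular < 1) {
    abort("Subject counts must be non-negative and total at least 1.")
  }
  if (repeats < 1) abort("`repeats` must be a positive count.")
  withr::local_seed(seed)

  groups <- list(regular = n_regular, irregular = n_irregular)
  subjects <- purrr::imap(groups, function(n, pattern) {
    if (n == 0) return(NULL)
    mix <- if (is.null(bpm_mix)) even_bpm_mix(n) else check_bpm_mix(bpm_mix, n, pattern)
    tibble::tibble(
      pattern = pattern,
      bpm_class = rep(.bpm_classes, times = mix)
    )
  }) |>
    dplyr::bind_rows()
  subjects$subject_id <- sprintf("S%03d", seq_len(nrow(subjects)))
  subjects$profile_seed <- sample.int(.Machine$integer.max - 1, nrow(subjects))
  subjects$amplitude <- runif(nrow(subjects), amplitude_range[1], amplitude_range[2])
  subjects$tumor_gain <- runif(nrow(subjects), tumor_gain_range[1], tumor_gain_range[2])

  traces <- tidyr::expand_grid(subjects, rep = seq_len(repeats))
  traces$trace_seed <- sample.int(.Machine$integer.max - 1, nrow(traces))
  traces$noise_seed <- sample.int(.Machine$integer.max - 1, nrow(traces))

  profiles <- purrr::pmap(
    subjects[, c("pattern", "bpm_class", "profile_seed", "subject_id")],
    function(pattern, bpm_class, profile_seed, subject_id) {
      sample_profile(pattern, bpm_class, seed = profile_seed, subject_id = subject_id)
    }
  )
  names(profiles) <- subjects$subject_id

  cohort <- traces |>
    dplyr::mutate(
      profile = profiles[.data$subject_id],
      trace = purrr::pmap(
        list(.data$subject_id, .data$amplitude, .data$tumor_gain,
             .data$trace_seed, .data$noise_seed),
        function(sid, amp, gain, tseed, nseed) {
          pr <- profiles[[sid]]
          cfg <- config
          cfg$amplitude <- amp
          cfg$tumor_gain <- gain
          tr <- generate_trace(pr, cfg, duration = duration,
                               sample_rate = sample_rate, seed = tseed)
          if (couple) tr <- couple_tumor(tr, cfg, seed = nseed)
          tr
        }
      )
    )

  # stratified 2/3 - 1/3 split within each pattern group
  cohort <- cohort |>
    dplyr::group_by(.data$pattern) |>
    dplyr::arrange(.data$rep, .data$subject_id, .by_group = TRUE) |>
    dplyr::mutate(
      split = ifelse(dplyr::row_number() <= round(2 / 3 * dplyr::n()),
                     "train", "test")
    ) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$subject_id, .data$rep)

  manifest <- list(
    seed = seed,
    n_regular = n_regular, n_irregular = n_irregular, repeats = repeats,
    sample_rate = sample_rate,
    amplitude_range = amplitude_range, tumor_gain_range = tumor_gain_range,
    subjects = as.data.frame(subjects),
    split = as.data.frame(cohort[, c("subject_id", "rep", "pattern", "split")])
  )
  structure(
    cohort[, c("subject_id", "rep", "pattern", "bpm_class", "split",
               "profile", "trace")],
    manifest = manifest,
    class = c("motion_cohort", class(tibble::tibble()))
  )
}

#' Window a cohort into phase-level samples
#'
#' Applies [build_windows()] to every trace and keeps the 10 windows of one
#' complete cycle per trace (the middle complete cycle by default), so a
#' cohort of S subjects x R repeats yields exactly 10 x S x R samples, the
#' accounting used for the pseudopatient experiments. Set `cycles = "all"`
#' to keep every complete cycle instead.
#'
#' @param cohort A `motion_cohort`.
#' @param lag Time-step spacing passed to [build_windows()].
#' @param cycles `"middle"` (one cycle per trace) or `"all"`.
#'
#' @return A tibble with cohort identifiers (`pattern`, `bpm_class`,
#'   `split`, `rep`), targets and the 33 feature columns.
#' @export
#' @examples
#' co <- generate_cohort(2, 2, repeats = 2, seed = 1)
#' nrow(phase_cohort(co)) # 10 x 4 x 2
phase_cohort <- function(cohort, lag = NULL, cycles = c("middle", "all")) {
  cycles <- match.arg(cycles)
  rows <- purrr::pmap(
    list(cohort$trace, cohort$profile, cohort$pattern, cohort$bpm_class,
         cohort$split, cohort$rep),
    function(trace, profile, pattern, bpm_class, split, rep) {
      w <- build_windows(trace, profile, lag = lag)
      if (cycles == "middle") {
        full <- w |>
          dplyr::count(.data$cycle_index) |>
          dplyr::filter(.data$n == 10)
        if (nrow(full) == 0) {
          abort(sprintf(
            "Trace for subject %s has no complete 10-window cycle.",
            profile$subject_id
          ))
        }
        mid <- full$cycle_index[ceiling(nrow(full) / 2)]
        w <- dplyr::filter(w, .data$cycle_index == mid)
      }
      dplyr::mutate(w,
        pattern = pattern, bpm_class = bpm_class, split = split, rep = rep,
        .after = "subject_id"
      )
    }
  )
  dplyr::bind_rows(rows)
}
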