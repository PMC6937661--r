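#' Configuration for a synthetic wellness cohort
#'
#' Defines the study conditions emulated by [generate_cohort()]: cohort size,
#' follow-up length, ECG acquisition parameters, and the strength of the
#' constructed link between a day's ECG and the next day's wellness condition.
#' Defaults mirror a three-month daily assessment of eleven elderly subjects
#' with 20-25 s single-lead ECG at 500 Hz.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param n_days Number of assessment days per subject (>= 2; the one-day
#'   forecast shift needs at least two days).
#' @param fs ECG sampling frequency in Hz.
#' @param duration_range Closed interval (seconds) from which each day's
#'   recording length is drawn uniformly. The minimum must not be shorter
#'   than the downstream analysis window (5 s by default).
#' @param effect_size Dimensionless separation `d >= 0` between the daily
#'   heart-rate distributions of days preceding better vs. worse conditions.
#'   The day-d mean heart rate is shifted by `effect_size * hr_shift_bpm / 2`
#'   towards tachycardia when day d+1 is a worse day, and the opposite way
#'   when it is a better day, so the one-day-forward forecasting signal
#'   exists by construction. `0` produces a null cohort with no signal.
#' @param hr_shift_bpm Heart-rate shift unit (beats/min) multiplied by
#'   `effect_size`; the full between-class separation in mean heart rate is
#'   `effect_size * hr_shift_bpm`.
#' @param noise_sd Amplitude of additive high-frequency noise relative to the
#'   clean signal's standard deviation (see [inject_noise()]).
#' @param noise_cutoff_hz Lower frequency bound of the injected noise.
#' @param wave_amp_jitter Per-recording lability of the non-R wave
#'   amplitudes (see [synthesize_ecg()]).
#' @param wander_amp Baseline-wander amplitude relative to the clean
#'   signal's standard deviation (see [add_baseline_wander()]).
#' @param hrv_sd_bpm Beat-to-beat heart-rate variability in beats/min
#'   (see [synthesize_ecg()]); elderly resting HRV is substantial, and it
#'   is what makes two same-rate windows differ in their exact beat grid.
#' @param missing_frac Fraction of subject-days deleted uniformly at random
#'   per subject, emulating missed assessments. Default 0.
#' @param seed Integer master seed. Per-subject child streams are derived
#'   from it, so adding subjects does not perturb existing ones.
#'
#' @return A list of class `wellcast_cohort_config`.
#' @seealso [generate_cohort()]
#' @export
cohort_config <- function(n_subjects = 11, n_days = 90, fs = 500,
                          duration_range = c(20, 25), effect_size = 1,
                          hr_shift_bpm = 4, noise_sd = 0.2,
                          noise_cutoff_hz = 40, wave_amp_jitter = 0.4,
                          wander_amp = 0.5, hrv_sd_bpm = 3,
                          missing_frac = 0, seed = 1) {
  cfg <- list(n_subjects = n_subjects, n_days = n_days, fs = fs,
              duration_range = duration_range, effect_size = effect_size,
              hr_shift_bpm = hr_shift_bpm, noise_sd = noise_sd,
              noise_cutoff_hz = noise_cutoff_hz,
              wave_amp_jitter = wave_amp_jitter, wander_amp = wander_amp,
              hrv_sd_bpm = hrv_sd_bpm,
              missing_frac = missing_frac, seed = seed)
  class(cfg) <- "wellcast_cohort_config"
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  chk <- function(ok, field, why) {
    if (!isTRUE(ok)) stop("invalid cohort configuration: field '", field,
                          "' ", why, call. = FALSE)
  }
  chk(is.numeric(cfg$n_subjects) && cfg$n_subjects >= 1, "n_subjects",
      "must be >= 1")
  chk(is.numeric(cfg$n_days) && cfg$n_days >= 2, "n_days",
      "must be >= 2 (one-day-forward shift needs at least 2 days)")
  chk(is.numeric(cfg$fs) && cfg$fs > 0, "fs", "must be > 0")
  chk(length(cfg$duration_range) == 2 &&
        cfg$duration_range[1] <= cfg$duration_range[2] &&
        cfg$duration_range[1] > 0, "duration_range",
      "must be a valid closed interval of positive durations")
  chk(is.numeric(cfg$effect_size) && cfg$effect_size >= 0, "effect_size",
      "must be >= 0")
  chk(is.numeric(cfg$noise_sd) && cfg$noise_sd >= 0, "noise_sd",
      "must be >= 0")
  chk(is.numeric(cfg$missing_frac) && cfg$missing_frac >= 0 &&
        cfg$missing_frac < 1, "missing_frac", "must be in [0, 1)")
  chk(is.numeric(cfg$seed) && length(cfg$seed) == 1, "seed",
      "must be a single integer")
  invisible(cfg)
}

## Ordinal cut-point geometry (latent standard-deviation units, relative to
## the subject's realized median latent wellness). The middle cut sits at the
## median itself: self-evaluated scales anchor on one's habitual feeling, so
## roughly half of a subject's days fall below their own typical wellness.
## The asymmetric outer offsets, tilted further by score_bias, produce the
## skewed raw HI marginals seen in self-evaluated scores.
.cut_z_base <- c(-1.8, 0, 0.45, 1.1)

#' Draw a subject profile
#'
#' Internal: samples the per-subject physiological and scoring parameters
#' from the current RNG stream.
#'
#' @return A list with `subject_id`, `hr_baseline` (bpm), `hrv_sd` (bpm),
#'   `hr_day_sd` (bpm day-to-day wander), `wellness_ar_coef`, `score_bias`.
#' @keywords internal
draw_subject_profile <- function(subject_id, hrv_sd = 3) {
  hr <- min(max(rnorm(1, 70, 2.5), 40), 120)
  list(subject_id = subject_id,
       hr_baseline = hr,
       hrv_sd = hrv_sd,
       hr_day_sd = 1.5,
       wellness_ar_coef = 0.5,
       score_bias = runif(1, 0.35, 0.75))
}

#' Synthesize one day's ECG trace
#'
#' Builds a quasi-periodic ECG-like signal as a sum of five Gaussian bumps
#' per beat (P, Q, R, S, T waves at fixed offsets, amplitudes and widths
#' relative to the R peak), with beat-to-beat RR intervals drawn from a
#' normal distribution around `60 / hr_bpm` seconds. The R peak dominates
#' (unit amplitude), matching the morphology of a clean limb-lead trace.
#'
#' @param hr_bpm Mean heart rate for the day in beats/min (> 0).
#' @param fs Sampling frequency in Hz.
#' @param duration_s Recording length in seconds.
#' @param hrv_sd_bpm Beat-to-beat heart-rate variability in beats/min;
#'   `0` yields exactly constant RR intervals.
#' @param wave_amp_jitter Relative day-to-day lability of the non-R wave
#'   amplitudes: each recording scales its P, Q, S and T amplitudes by an
#'   independent factor drawn from `U(1 - j, 1 + j)` (the R peak stays at
#'   unit amplitude as the morphological anchor). Electrode placement and
#'   repolarization amplitude vary between days on real recordings;
#'   `0` disables the jitter.
#' @return Numeric vector of `round(fs * duration_s)` samples. Uses the
#'   current RNG stream (seed upstream for reproducibility).
#' @export
synthesize_ecg <- function(hr_bpm, fs, duration_s, hrv_sd_bpm = 2,
                           wave_amp_jitter = 0.4) {
  if (!is.numeric(hr_bpm) || hr_bpm <= 0)
    stop("non-physiological heart rate: hr_bpm must be > 0", call. = FALSE)
  if (fs <= 0) stop("fs must be > 0", call. = FALSE)
  n <- round(fs * duration_s)
  rr_mean <- 60 / hr_bpm
  ## delta-method sd of RR for a given bpm-scale variability
  rr_sd <- hrv_sd_bpm * 60 / hr_bpm^2
  ## beat train: start one beat before t = 0 so the left edge holds a
  ## partial beat, continue past the right edge
  beats <- -runif(1, 0, rr_mean)
  while (beats[length(beats)] < duration_s + rr_mean) {
    rr <- rnorm(1, rr_mean, rr_sd)
    rr <- max(rr, 0.25 * rr_mean)  # guard against beat collisions
    beats <- c(beats, beats[length(beats)] + rr)
  }
  ## P, Q, R, S, T: offset (s), amplitude (mV-scale), width (s)
  wave_off <- c(-0.18, -0.025, 0.000, 0.025, 0.20)
  wave_amp <- c(0.12, -0.10, 1.00, -0.15, 0.30)
  wave_sd  <- c(0.025, 0.010, 0.012, 0.010, 0.055)
  if (wave_amp_jitter > 0) {
    scale5 <- 1 + runif(5, -wave_amp_jitter, wave_amp_jitter)
    scale5[3] <- 1                      # R peak anchors the amplitude scale
    wave_amp <- wave_amp * scale5
  }
  tt <- (seq_len(n) - 1) / fs
  x <- numeric(n)
  for (b in beats) {
    for (w in seq_along(wave_off)) {
      mu <- b + wave_off[w]
      lo <- max(1L, floor((mu - 5 * wave_sd[w]) * fs) + 1L)
      hi <- min(n, ceiling((mu + 5 * wave_sd[w]) * fs) + 1L)
      if (lo > hi) next
      idx <- lo:hi
      x[idx] <- x[idx] + wave_amp[w] * exp(-(tt[idx] - mu)^2 / (2 * wave_sd[w]^2))
    }
  }
  x
}

#' Add baseline wander to a signal
#'
#' Superimposes a slow baseline drift -- the respiratory/electrode artifact
#' ubiquitous in ambulatory ECG -- as a sum of three sinusoids with random
#' frequencies in `freq_range` and random phases, rescaled so the drift's
#' standard deviation is `wander_amp * sd(signal)`.
#'
#' @param signal Numeric vector of samples.
#' @param wander_amp Drift amplitude relative to `sd(signal)`; `0` returns
#'   the input unchanged.
#' @param fs Sampling frequency in Hz.
#' @param freq_range Drift frequency band in Hz (default 0.05-0.4, the
#'   respiratory range).
#' @return Numeric vector, `signal` plus drift.
#' @export
add_baseline_wander <- function(signal, wander_amp, fs = 500,
                                freq_range = c(0.05, 0.4)) {
  if (wander_amp < 0) stop("wander_amp must be >= 0", call. = FALSE)
  if (wander_amp == 0) return(signal)
  n <- length(signal)
  tt <- (seq_len(n) - 1) / fs
  drift <- numeric(n)
  for (i in 1:3) {
    f <- runif(1, freq_range[1], freq_range[2])
    drift <- drift + runif(1, 0.5, 1) * sin(2 * pi * f * tt + runif(1, 0, 2 * pi))
  }
  s <- sd(drift)
  if (s == 0) return(signal)
  signal + drift * (wander_amp * sd(signal) / s)
}

#' Add high-frequency noise to a signal
#'
#' Adds zero-mean noise whose spectral support lies entirely above
#' `cutoff_hz`: white Gaussian noise is shaped in the discrete Fourier
#' domain by zeroing all bins below the cutoff, then rescaled so its
#' standard deviation equals `noise_sd * sd(signal)`.
#'
#' @param signal Numeric vector of samples.
#' @param noise_sd Noise amplitude relative to `sd(signal)`; `0` returns the
#'   input unchanged.
#' @param cutoff_hz Lower frequency bound of the noise band.
#' @param fs Sampling frequency in Hz.
#' @return Numeric vector, `signal` plus shaped noise.
#' @export
inject_noise <- function(signal, noise_sd, cutoff_hz = 40, fs = 500) {
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (noise_sd == 0) return(signal)
  n <- length(signal)
  white <- rnorm(n)
  spec <- fft(white)
  freq <- (seq_len(n) - 1) / n * fs
  ## two-sided mask: physical frequency of bin k is min(f, fs - f)
  phys <- pmin(freq, fs - freq)
  spec[phys < cutoff_hz] <- 0 + 0i
  shaped <- Re(fft(spec, inverse = TRUE)) / n
  s <- sd(shaped)
  if (s == 0) return(signal)  # cutoff at/above Nyquist leaves nothing
  shaped <- shaped * (noise_sd * sd(signal) / s)
  signal + shaped
}

#' Generate a synthetic wellness cohort
#'
#' Produces per-subject daily records, each holding one short ECG trace and
#' one ordinal health-index (HI) score in 1-5. Per subject, a latent daily
#' wellness trajectory follows a stationary AR(1) process; HI scores are
#' ordinal bins of the latent value under subject-specific cut-points whose
#' middle cut is anchored at the subject's realized median wellness (so the
#' within-subject better/worse dichotomy is balanced) and whose asymmetric
#' outer cuts, tilted by the subject's `score_bias`, skew the raw HI
#' marginal. The ECG of day d has its mean heart rate shifted by
#' `effect_size * hr_shift_bpm / 2` towards the day-(d+1) binary condition
#' (worse -> faster), so a one-day-forward forecasting signal exists by
#' construction; `effect_size = 0` yields a null cohort.
#'
#' Randomness is organized as one master seed spawning per-subject child
#' streams: regenerating with more subjects leaves existing subjects'
#' records bit-identical.
#'
#' @param config A [cohort_config()].
#' @return An object of class `wellcast_cohort`: a list with
#'   \describe{
#'     \item{records}{list of daily records, each with `subject_id`,
#'       `day_index` (0-based), `hi_score`, `fs`, `duration_s`, `ecg`.}
#'     \item{profiles}{per-subject profiles (see [draw_subject_profile()]).}
#'     \item{truth}{per-subject data frame of the latent trajectory, HI
#'       score and generator-side binary condition for every day (including
#'       deleted ones) -- simulation ground truth for calibration checks.}
#'     \item{config}{the configuration used.}
#'   }
#' @examples
#' coh <- generate_cohort(cohort_config(n_subjects = 2, n_days = 6,
#'                                      duration_range = c(6, 7), seed = 1))
#' length(coh$records)
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  set.seed(config$seed)
  subject_seeds <- sample.int(.Machine$integer.max, config$n_subjects)
  records <- list()
  profiles <- list()
  truth <- list()
  for (j in seq_len(config$n_subjects)) {
    set.seed(subject_seeds[j])
    sid <- sprintf("S%02d", j)
    prof <- draw_subject_profile(sid, config$hrv_sd_bpm)
    nd <- config$n_days
    ## latent wellness: stationary AR(1), unit marginal variance
    ar <- prof$wellness_ar_coef
    w <- numeric(nd)
    w[1] <- rnorm(1)
    for (d in 2:nd) w[d] <- ar * w[d - 1] + rnorm(1, 0, sqrt(1 - ar^2))
    cuts <- median(w) + .cut_z_base + c(0, 0, prof$score_bias, prof$score_bias)
    hi <- 1L + findInterval(w, cuts)
    ## generator-side condition: the same rank transform the pipeline applies
    cond <- dichotomize(fisher_yates_normalize(hi))
    durations <- runif(nd, config$duration_range[1], config$duration_range[2])
    hr_noise <- rnorm(nd, 0, prof$hr_day_sd)
    for (d in seq_len(nd)) {
      shift <- 0
      if (d < nd)  # last day has no successor to encode
        shift <- ifelse(cond[d + 1] == 1, 1, -1) *
          config$effect_size * config$hr_shift_bpm / 2
      hr_d <- prof$hr_baseline + hr_noise[d] + shift
      ecg <- synthesize_ecg(hr_d, config$fs, durations[d], prof$hrv_sd,
                            config$wave_amp_jitter)
      ecg <- add_baseline_wander(ecg, config$wander_amp, config$fs)
      ecg <- inject_noise(ecg, config$noise_sd, config$noise_cutoff_hz,
                          config$fs)
      records[[length(records) + 1L]] <- list(
        subject_id = sid, day_index = d - 1L, hi_score = hi[d],
        fs = config$fs, duration_s = durations[d], ecg = ecg)
    }
    if (config$missing_frac > 0) {
      keep <- runif(nd) >= config$missing_frac
      drop_ids <- paste(sid, which(!keep) - 1L)
      records <- Filter(function(r) !(paste(r$subject_id, r$day_index)
                                      %in% drop_ids), records)
    }
    profiles[[sid]] <- prof
    truth[[sid]] <- data.frame(subject_id = sid, day_index = seq_len(nd) - 1L,
                               latent = w, hi_score = hi, condition = cond)
  }
  structure(list(records = records, profiles = profiles,
                 truth = do.call(rbind, truth), config = config),
            class = "wellcast_cohort")
}

#' Cohort manifest
#'
#' One row per daily record: subject, day, HI score and recording length.
#'
#' @param x A `wellcast_cohort`.
#' @param ... Unused.
#' @return A data frame with columns `subject_id`, `day_index`, `hi_score`,
#'   `duration_s`, `n_samples`.
#' @export
as.data.frame.wellcast_cohort <- function(x, ...) {
  do.call(rbind, lapply(x$records, function(r)
    data.frame(subject_id = r$subject_id, day_index = r$day_index,
               hi_score = r$hi_score, duration_s = r$duration_s,
               n_samples = length(r$ecg))))
}

#' @export
print.wellcast_cohort <- function(x, ...) {
  m <- as.data.frame(x)
  cat("wellcast synthetic cohort:", length(unique(m$subject_id)),
      "subjects,", nrow(m), "daily records\n")
  cat("  fs:", x$config$fs, "Hz; duration:",
      paste(x$config$duration_range, collapse = "-"), "s; effect size:",
      x$config$effect_size, "\n")
  invisible(x)
}

#' Write a cohort to disk
#'
#' Plain-text layout: `manifest.csv` (`subject_id,day_index,hi_score,signal_path`),
#' one signal file per record (one floating-point sample per line) and a JSON
#' sidecar per signal with `fs` and `duration_s`.
#'
#' @param cohort A `wellcast_cohort`.
#' @param dir Output directory (created if needed).
#' @return The manifest data frame, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "signals"), recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cohort$records, function(r) {
    rel <- file.path("signals", sprintf("%s_d%03d.txt", r$subject_id,
                                        r$day_index))
    writeLines(format(r$ecg, digits = 17, scientific = TRUE, trim = TRUE),
               file.path(dir, rel))
    jsonlite::write_json(list(fs = r$fs, duration_s = r$duration_s),
                         file.path(dir, paste0(rel, ".json")),
                         auto_unbox = TRUE, digits = NA)
    data.frame(subject_id = r$subject_id, day_index = r$day_index,
               hi_score = r$hi_score, signal_path = rel)
  })
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing `manifest.csv` and `signals/`.
#' @return A `wellcast_cohort` (without generator profiles/truth, which are
#'   simulation-side objects).
#' @export
read_cohort <- function(dir) {
  manifest <- read.csv(file.path(dir, "manifest.csv"),
                       colClasses = c(subject_id = "character"))
  records <- lapply(seq_len(nrow(manifest)), function(i) {
    rel <- manifest$signal_path[i]
    meta <- jsonlite::read_json(file.path(dir, paste0(rel, ".json")))
    list(subject_id = manifest$subject_id[i],
         day_index = manifest$day_index[i],
         hi_score = manifest$hi_score[i],
         fs = meta$fs, duration_s = meta$duration_s,
         ecg = as.numeric(readLines(file.path(dir, rel))))
  })
  structure(list(records = records, profiles = NULL, truth = NULL,
                 config = NULL), class = "wellcast_cohort")
}
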