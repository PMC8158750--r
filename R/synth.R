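# Synthetic BCG cohort simulator.
#
# Emulates the statistical structure the detection pipeline assumes in
# 125 Hz single-channel recordings: quasi-periodic sinus-rhythm (SR) beat
# clusters, aperiodic band-limited fibrillatory oscillation (VF),
# large-amplitude low-frequency motion artifacts (MA), respiration baseline,
# optional 3 s-period ventilator pulses, and per-subject morphology /
# amplitude / noise variation. It is a stated phenomenological world, not a
# hemodynamic model; all shape parameters are package defaults documented in
# the methods vignette.

BCG_FS <- 125L

#' Subject profile for the synthetic cohort
#'
#' @param subject_id character scalar.
#' @param beat_amplitude_scale positive beat amplitude, arbitrary units.
#' @param beat_morphology_seed integer controlling the per-subject beat
#'   waveform (oscillation frequency and decay).
#' @param baseline_heart_rate beats/min, must lie in \[50, 170\].
#' @param noise_sd standard deviation of additive white sensor noise.
#' @return object of class `bcg_profile`.
#' @export
subject_profile <- function(subject_id,
                            beat_amplitude_scale = 1,
                            beat_morphology_seed = 1L,
                            baseline_heart_rate = 75,
                            noise_sd = 0.15) {
  if (!is.character(subject_id) || length(subject_id) != 1L) {
    stop_invalid("subject_id must be a single string")
  }
  if (baseline_heart_rate < 50 || baseline_heart_rate > 170) {
    stop_invalid("baseline_heart_rate must lie in [50, 170] bpm")
  }
  if (beat_amplitude_scale <= 0) stop_invalid("beat_amplitude_scale must be > 0")
  if (noise_sd < 0) stop_invalid("noise_sd must be >= 0")
  structure(list(subject_id = subject_id,
                 beat_amplitude_scale = beat_amplitude_scale,
                 beat_morphology_seed = as.integer(beat_morphology_seed),
                 baseline_heart_rate = baseline_heart_rate,
                 noise_sd = noise_sd),
            class = "bcg_profile")
}

new_recording <- function(samples, subject_id, annotations, fs = BCG_FS) {
  annotations$start <- as.integer(annotations$start)
  annotations$end <- as.integer(annotations$end)
  stopifnot(all(annotations$end > annotations$start),
            all(annotations$start >= 0L),
            all(annotations$end <= length(samples)))
  structure(list(samples = as.numeric(samples), fs = as.integer(fs),
                 subject_id = subject_id, annotations = annotations),
            class = "bcg_recording")
}

#' @export
print.bcg_recording <- function(x, ...) {
  cat(sprintf("<bcg_recording> subject %s: %d samples (%.1f s at %d Hz), %d extent(s): %s\n",
              x$subject_id, length(x$samples), length(x$samples) / x$fs, x$fs,
              nrow(x$annotations),
              paste(x$annotations$label, collapse = ", ")))
  invisible(x)
}

# Per-subject beat template: a Gabor-like damped oscillation ("W-shaped"
# tri-lobe cluster) whose centre frequency and width come from the
# morphology seed. Dominant content 4-10 Hz.
beat_template <- function(profile, fs = BCG_FS) {
  with_seed(profile$beat_morphology_seed, {
    f_b <- runif(1, 5, 9)
    width <- runif(1, 0.95, 1.25) / (2 * f_b)   # ~3 visible lobes
    half <- round(3 * width * fs)
    t <- (-half:half) / fs
    sin(2 * pi * f_b * t) * exp(-t^2 / (2 * width^2))
  })
}

add_pulses <- function(sig, centres, shape) {
  n <- length(sig)
  half <- (length(shape) - 1L) %/% 2L
  for (c0 in centres) {
    idx <- (c0 - half):(c0 + half)
    ok <- idx >= 1L & idx <= n
    sig[idx[ok]] <- sig[idx[ok]] + shape[ok]
  }
  sig
}

respiration_wave <- function(n, amp, fs = BCG_FS) {
  f_r <- runif(1, 0.2, 0.4)
  phi <- runif(1, 0, 2 * pi)
  amp * sin(2 * pi * f_r * (0:(n - 1)) / fs + phi)
}

# Zero-phase band-pass via FFT masking with raised-cosine transition edges.
fft_bandpass <- function(x, f_lo, f_hi, fs = BCG_FS, trans = 1) {
  n <- length(x)
  f <- (0:(n - 1)) * fs / n
  f <- pmin(f, fs - f)                      # two-sided frequency axis
  mask <- numeric(n)
  mask[f >= f_lo & f <= f_hi] <- 1
  lo_t <- f >= f_lo - trans & f < f_lo
  mask[lo_t] <- 0.5 * (1 - cos(pi * (f[lo_t] - (f_lo - trans)) / trans))
  hi_t <- f > f_hi & f <= f_hi + trans
  mask[hi_t] <- 0.5 * (1 + cos(pi * (f[hi_t] - f_hi) / trans))
  Re(fft(fft(x) * mask, inverse = TRUE)) / n
}

check_duration <- function(duration_s) {
  if (!is.numeric(duration_s) || duration_s < 7) {
    stop_invalid("duration_s must be >= 7 s (one full analysis window)")
  }
}

#' Generate a synthetic sinus-rhythm BCG recording
#'
#' A quasi-periodic train of damped-oscillation beat clusters at the
#' profile's heart rate (timing jitter <= 4% of the beat period, amplitude
#' jitter <= 8%), over a 0.2-0.4 Hz respiration baseline, optionally with a
#' large ventilator pulse every 3.0 s, plus white sensor noise. The whole
#' extent is annotated SR.
#'
#' @param duration_s recording length in seconds, >= 7.
#' @param profile a [subject_profile()].
#' @param seed integer seed; output is a deterministic function of
#'   (arguments, seed).
#' @param ventilator add 3 s-period ventilator pulse artifacts (default
#'   FALSE).
#' @return a `bcg_recording`.
#' @export
generate_sr <- function(duration_s, profile, seed, ventilator = FALSE) {
  check_duration(duration_s)
  stopifnot(inherits(profile, "bcg_profile"))
  n <- round(duration_s * BCG_FS)
  amp <- profile$beat_amplitude_scale
  shape <- beat_template(profile)
  with_seed(seed, {
    period <- 60 / profile$baseline_heart_rate * BCG_FS      # samples
    k <- seq(0, ceiling(n / period) + 1L)
    centres <- round(k * period + runif(length(k), -0.04, 0.04) * period) + 1L
    centres <- centres[centres >= 1L & centres <= n]
    amps <- amp * (1 + runif(length(centres), -0.08, 0.08))
    sig <- numeric(n)
    for (i in seq_along(centres)) {
      sig <- add_pulses(sig, centres[i], amps[i] * shape)
    }
    sig <- sig + respiration_wave(n, 0.35 * amp)
    if (isTRUE(ventilator)) {
      vt <- seq(1L, n, by = 3L * BCG_FS)
      tv <- (-38:38) / BCG_FS                       # +/- 0.3 s support
      vshape <- 2.5 * amp * sin(2 * pi * 1.5 * tv) * exp(-tv^2 / (2 * 0.11^2))
      sig <- add_pulses(sig, vt, vshape)
    }
    sig <- sig + rnorm(n, 0, profile$noise_sd)
    new_recording(sig, profile$subject_id,
                  data.frame(start = 0L, end = n, label = "SR"))
  })
}

#' Generate a synthetic ventricular-fibrillation BCG recording
#'
#' Band-limited (3-10 Hz) Gaussian oscillation with slow random amplitude
#' modulation: aperiodic, random-amplitude, with no stable fundamental
#' period, at an amplitude comparable to the subject's SR beats. Annotated
#' VF over the full extent.
#'
#' @inheritParams generate_sr
#' @return a `bcg_recording`.
#' @export
generate_vf <- function(duration_s, profile, seed) {
  check_duration(duration_s)
  stopifnot(inherits(profile, "bcg_profile"))
  n <- round(duration_s * BCG_FS)
  amp <- profile$beat_amplitude_scale
  with_seed(seed, {
    core <- fft_bandpass(rnorm(n), 3, 10)
    slow <- fft_bandpass(rnorm(n), 0, 0.5, trans = 0.3)
    env <- pmax(1 + 0.45 * slow / max(1e-12, sd(slow)), 0.25)
    sig <- core / max(1e-12, sd(core)) * env * 0.45 * amp
    sig <- sig + respiration_wave(n, 0.2 * amp)
    sig <- sig + rnorm(n, 0, profile$noise_sd)
    new_recording(sig, profile$subject_id,
                  data.frame(start = 0L, end = n, label = "VF"))
  })
}

#' Generate a synthetic motion-artifact BCG recording
#'
#' Irregular low-frequency (<= ~1.5 Hz) large transients whose peak-to-peak
#' amplitude is at least `ma_ratio` times the subject's beat amplitude,
#' superimposed on an underlying beat train and sensor noise. Annotated MA.
#'
#' @inheritParams generate_sr
#' @param ma_ratio ratio of artifact amplitude to beat amplitude (default 6).
#' @return a `bcg_recording`.
#' @export
generate_ma <- function(duration_s, profile, seed, ma_ratio = 6) {
  check_duration(duration_s)
  stopifnot(inherits(profile, "bcg_profile"))
  n <- round(duration_s * BCG_FS)
  amp <- profile$beat_amplitude_scale
  shape <- beat_template(profile)
  with_seed(seed, {
    # underlying cardiac activity, partially obscured
    period <- 60 / profile$baseline_heart_rate * BCG_FS
    base <- seq(1, n, by = period)
    centres <- round(base + runif(length(base), -0.04, 0.04) * period)
    centres <- centres[centres >= 1L & centres <= n]
    sig <- numeric(n)
    for (c0 in centres) sig <- add_pulses(sig, c0, amp * shape)
    # motion transients: one irregular bump roughly every 1.2 s so every
    # 7 s window contains several
    bumps <- seq(0.6, duration_s - 0.6, by = 1.2)
    bumps <- bumps + runif(length(bumps), -0.25, 0.25)
    for (b in bumps) {
      f_m <- runif(1, 0.5, 1.5)
      w_m <- runif(1, 0.25, 0.6)
      b_amp <- ma_ratio * amp * runif(1, 0.7, 1.1) * sample(c(-1, 1), 1)
      half <- round(2.5 * w_m * BCG_FS)
      t <- (-half:half) / BCG_FS
      bump <- b_amp * sin(2 * pi * f_m * t) * exp(-t^2 / (2 * w_m^2))
      sig <- add_pulses(sig, round(b * BCG_FS) + 1L, bump)
    }
    sig <- sig + respiration_wave(n, 0.35 * amp)
    sig <- sig + rnorm(n, 0, profile$noise_sd)
    new_recording(sig, profile$subject_id,
                  data.frame(start = 0L, end = n, label = "MA"))
  })
}

#' Generate a multi-subject synthetic cohort
#'
#' Draws one subject profile per subject from the stated ranges (heart rate
#' uniform in \[55, 165\] bpm, amplitude scale uniform in \[0.6, 1.8\],
#' per-subject beat morphology, noise SD = `noise_level` x amplitude) and
#' produces one recording per subject containing consecutive annotated SR,
#' VF and MA extents of the requested durations. The master seed fully
#' determines the cohort.
#'
#' @param n_subjects number of subjects, >= 2 (leave-one-subject-out needs
#'   at least two).
#' @param per_subject_spec named list of extent durations in seconds, e.g.
#'   `list(sr = 84, vf = 14, ma = 27)`. Entries may be omitted or zero.
#' @param seed master integer seed.
#' @param ventilator add ventilator pulses to SR extents (default TRUE,
#'   matching mechanically ventilated subjects).
#' @param noise_level white-noise SD as a fraction of the subject's beat
#'   amplitude (default 0.15, "moderate").
#' @return list of `bcg_recording`, one per subject.
#' @export
generate_cohort <- function(n_subjects,
                            per_subject_spec = list(sr = 84, vf = 14, ma = 27),
                            seed = 1L,
                            ventilator = TRUE,
                            noise_level = 0.15) {
  if (!is_count(n_subjects) || n_subjects < 2) {
    stop_invalid("n_subjects must be an integer >= 2 (LOSO needs >= 2)")
  }
  n_subjects <- as.integer(n_subjects)
  draws <- with_seed(seed, {
    list(hr = runif(n_subjects, 55, 165),
         amp = runif(n_subjects, 0.6, 1.8),
         morph = sample.int(1e6, n_subjects),
         sub_seed = sample.int(2^30, n_subjects * 4L))
  })
  lapply(seq_len(n_subjects), function(i) {
    prof <- subject_profile(sprintf("S%02d", i),
                            beat_amplitude_scale = draws$amp[i],
                            beat_morphology_seed = draws$morph[i],
                            baseline_heart_rate = draws$hr[i],
                            noise_sd = noise_level * draws$amp[i])
    parts <- list()
    if (!is.null(per_subject_spec$sr) && per_subject_spec$sr >= 7) {
      parts$sr <- generate_sr(per_subject_spec$sr, prof,
                              seed = draws$sub_seed[i],
                              ventilator = ventilator)
    }
    if (!is.null(per_subject_spec$vf) && per_subject_spec$vf >= 7) {
      parts$vf <- generate_vf(per_subject_spec$vf, prof,
                              seed = draws$sub_seed[n_subjects + i])
    }
    if (!is.null(per_subject_spec$ma) && per_subject_spec$ma >= 7) {
      parts$ma <- generate_ma(per_subject_spec$ma, prof,
                              seed = draws$sub_seed[2L * n_subjects + i])
    }
    if (!length(parts)) stop_invalid("per_subject_spec requests no extents")
    samples <- unlist(lapply(parts, `[[`, "samples"), use.names = FALSE)
    lens <- vapply(parts, function(p) length(p$samples), integer(1))
    offs <- cumsum(c(0L, head(lens, -1L)))
    ann <- do.call(rbind, lapply(seq_along(parts), function(k) {
      a <- parts[[k]]$annotations
      a$start <- a$start + offs[k]
      a$end <- a$end + offs[k]
      a
    }))
    rownames(ann) <- NULL
    new_recording(samples, prof$subject_id, ann)
  })
}
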