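test_that("wavelet bank satisfies perfect reconstruction", {
  withr::with_seed(1, {
    for (n in c(875L, 1000L, 4096L)) {
      x <- rnorm(n)
      dec <- dwt_decompose(x)
      rec <- Reduce(`+`, dec[c(paste0("d", 1:7), "a7")])
      expect_lt(max(abs(rec - x)), 1e-8)
    }
  })
})

test_that("wavelet decomposition handles degenerate inputs", {
  dec <- dwt_decompose(numeric(1024))
  for (comp in dec) expect_true(all(comp == 0))
  expect_error(dwt_decompose(numeric(100)), class = "bcgvf_invalid_argument")
})

test_that("detail bands carry the expected frequencies", {
  t <- (0:874) / 125
  dec <- dwt_decompose(sin(2 * pi * 5 * t))
  en <- vapply(dec[paste0("d", 1:7)], function(v) sum(v^2), numeric(1))
  expect_gt(sum(en[3:5]) / (sum(en) + sum(dec$a7^2)), 0.8)

  parts <- detail_reconstruct(dec)
  expect_gt(cor(parts$bcg, sin(2 * pi * 5 * t)), 0.95)

  # slow drift lives in a7: d3-d7 keeps <10% of its RMS (long input so the
  # measurement is not edge-dominated)
  t_long <- (0:4095) / 125
  drift <- sin(2 * pi * 0.1 * t_long)
  out <- detail_reconstruct(dwt_decompose(drift))$bcg
  expect_lt(sqrt(mean(out^2)) / sqrt(mean(drift^2)), 0.10)

  dz <- detail_reconstruct(dwt_decompose(numeric(875)))
  expect_true(all(dz$bcg == 0) && all(dz$d7 == 0))
})

test_that("noise reference tracks ventilator-like pulses", {
  expect_error(build_noise_reference(numeric(400), numeric(300)),
               class = "bcgvf_invalid_argument")
  z <- build_noise_reference(numeric(750), numeric(750))
  expect_true(all(z == 0))

  # one tall pulse per 3 s window
  n <- 1500L
  x <- numeric(n)
  centres <- c(190L, 560L, 940L, 1310L)
  for (c0 in centres) {
    x[(c0 - 15):(c0 + 15)] <- 4 * exp(-((-15:15) / 6)^2)
  }
  ref <- build_noise_reference(x, numeric(n))
  at_pulses <- unlist(lapply(centres, function(c0) (c0 - 20):(c0 + 20)))
  expect_gt(cor(ref[at_pulses], x[at_pulses]), 0.8)

  # low-amplitude 1.2 Hz beat train without ventilator: reference stays
  # small (the pulse gate keeps one beat per 3 s window and the smoother
  # attenuates the beat-band content)
  beat <- 0.2 * planted_train(104L, seed = 1, noise = 0, n = 1500L)
  ref2 <- build_noise_reference(beat, numeric(1500))
  expect_lt(sqrt(mean(ref2^2)), 0.3 * sqrt(mean(beat^2)))
})

test_that("LMS cancellation follows the update equations", {
  withr::with_seed(2, {
    d <- rnorm(500)
    # zero reference: taps are all zero, y = 0, e = d exactly
    expect_identical(lms_cancel(d, numeric(500)), d)
    # output length preserved
    expect_length(lms_cancel(d, rnorm(500)), 500L)
    # mu -> 0: deviation from identity bounded by ||w0||_1 * max|ref|
    st <- lms_state(mu = 1e-300, seed = 3)
    ref <- rnorm(500)
    e <- lms_cancel(d, ref, st)
    expect_lt(max(abs(e - d)), sum(abs(st$w)) * max(abs(ref)))
    expect_error(lms_cancel(d, rnorm(10)), class = "bcgvf_invalid_argument")
    expect_error(lms_state(alpha = 0), class = "bcgvf_invalid_argument")
  })
})

test_that("LMS reduces correlated stationary noise", {
  withr::with_seed(7, {
    n <- 20000L
    t <- (0:(n - 1)) / 125
    clean <- sin(2 * pi * 5 * t)
    noise <- sin(2 * pi * 1 / 3 * t + 0.5)       # ventilator-band tone
    d <- clean + 2 * noise
    # a practical step size for unit-power reference
    e <- lms_cancel(d, noise, lms_state(mu = 5e-3, seed = 1))
    tail_idx <- (n - 5000L):n
    band_power <- function(x) {
      sp <- Mod(fft(x))^2
      f <- (seq_along(x) - 1) * 125 / length(x)
      sum(sp[f > 0.1 & f < 0.6])
    }
    expect_lt(band_power(e[tail_idx]) / band_power(d[tail_idx]), 1)
  })
})

test_that("segmentation strides and boundaries are respected", {
  prof <- test_profile()
  sr <- generate_sr(14, prof, seed = 1)
  expect_length(segment_recording(sr), 2L)                 # 2 x 875

  vf <- generate_vf(10, prof, seed = 1)
  svf <- segment_recording(vf)
  expect_length(svf, 4L)                                   # stride 125
  expect_identical(vapply(svf, `[[`, integer(1), "t0"),
                   c(0L, 125L, 250L, 375L))

  ma <- generate_ma(13, prof, seed = 1)
  expect_length(segment_recording(ma), 3L)                 # stride 375

  # windows lie inside exactly one extent and inherit its label
  cohort <- generate_cohort(2, list(sr = 16, vf = 9, ma = 10), seed = 5)
  for (rec in cohort) {
    ann <- rec$annotations
    for (s in segment_recording(rec)) {
      inside <- ann$start <= s$t0 & (s$t0 + 875L) <= ann$end
      expect_identical(sum(inside), 1L)
      expect_identical(s$label, ann$label[inside])
    }
  }

  # short extent emits nothing (with a log message)
  short <- generate_sr(7, prof, seed = 1)
  short$annotations$end <- 800L
  short$samples <- short$samples[1:800]
  expect_message(out <- segment_recording(short), "skipped")
  expect_length(out, 0L)
})

test_that("preprocessing preserves annotations and is deterministic", {
  rec <- generate_sr(21, test_profile(), seed = 8, ventilator = TRUE)
  p1 <- preprocess_recording(rec, state = lms_state(seed = 2))
  p2 <- preprocess_recording(rec, state = lms_state(seed = 2))
  expect_identical(p1$samples, p2$samples)
  expect_identical(p1$annotations, rec$annotations)
  expect_length(p1$samples, length(rec$samples))
  # no-LMS path is the plain d3..d7 reconstruction
  p3 <- preprocess_recording(rec, lms = FALSE)
  parts <- detail_reconstruct(dwt_decompose(rec$samples))
  expect_identical(p3$samples, parts$bcg)
})
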