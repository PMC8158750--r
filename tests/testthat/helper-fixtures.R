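# Shared fixtures. Everything is generated in code; the expensive cohort
# feature matrix is computed once per test run and memoized.

.fixture_env <- new.env(parent = emptyenv())

test_profile <- function(id = "T1", hr = 75, amp = 1, noise = 0.1,
                         morph = 7L) {
  subject_profile(id, beat_amplitude_scale = amp, beat_morphology_seed = morph,
                  baseline_heart_rate = hr, noise_sd = noise)
}

# One preprocessed-and-segmented 7 s segment of each class from a common
# profile; moderate noise.
fixture_segments <- function() {
  if (is.null(.fixture_env$segments)) {
    prof <- test_profile()
    segs <- list(
      SR = segment_recording(generate_sr(14, prof, seed = 101))[[1]],
      VF = segment_recording(generate_vf(14, prof, seed = 102))[[1]],
      MA = segment_recording(generate_ma(14, prof, seed = 103))[[1]])
    .fixture_env$segments <- segs
  }
  .fixture_env$segments
}

# Small multi-class cohort feature matrix (6 subjects), reused by the
# stats/classify tests. ~15 s of compute, done once.
fixture_features <- function() {
  if (is.null(.fixture_env$features)) {
    cohort <- generate_cohort(6, list(sr = 42, vf = 14, ma = 14), seed = 42)
    segs <- unlist(lapply(cohort, function(r) {
      segment_recording(preprocess_recording(r))
    }), recursive = FALSE)
    .fixture_env$features <- extract_feature_matrix(segs)
  }
  .fixture_env$features
}

# Exactly periodic beat train (planted period, no timing jitter) plus white
# noise; the parameter-recovery fixture.
planted_train <- function(period, seed, noise = 0.2, n = 875L) {
  tpl_t <- seq(-0.17, 0.17, by = 1 / 125)
  tpl <- sin(2 * pi * 7 * tpl_t) * exp(-tpl_t^2 / (2 * 0.08^2))
  x <- numeric(n)
  for (c0 in seq(1, n, by = period)) {
    idx <- c0:(c0 + length(tpl) - 1L)
    ok <- idx <= n
    x[idx[ok]] <- x[idx[ok]] + tpl[ok]
  }
  withr::with_seed(seed, x + rnorm(n, 0, noise))
}

# Brute-force O(N^2) autocorrelation oracle (population variance).
acf_oracle <- function(x) {
  N <- length(x)
  xc <- x - mean(x)
  c0 <- mean(xc^2)
  vapply(0:(N - 1), function(k) {
    sum(xc[seq_len(N - k)] * xc[seq_len(N - k) + k]) / (c0 * N)
  }, numeric(1))
}

# Direct time-domain Stockwell oracle: periodized unit-sum Gaussian voice
# windows (sd = N/j samples, i.e. 1/f), phase referenced to the time origin.
stransform_oracle <- function(x, fs = 125, f_lo = 1, f_hi = 20) {
  N <- length(x)
  js <- seq.int(ceiling(f_lo * N / fs), floor(f_hi * N / fs))
  k <- 0:(N - 1)
  S <- matrix(0, length(js), N)
  for (r in seq_along(js)) {
    j <- js[r]
    w <- numeric(N)
    for (a in -12:12) w <- w + exp(-(k + a * N)^2 * j^2 / (2 * N^2))
    w <- w / sum(w)
    xph <- x * exp(-2i * pi * j * k / N)
    for (tau in k) {
      S[r, tau + 1] <- Mod(sum(xph * w[(k - tau) %% N + 1]))^2
    }
  }
  S
}

# Exact two-sided Mann-Whitney p by full enumeration (untied samples).
mw_enum_oracle <- function(a, b) {
  m <- length(a); n <- length(b)
  pool <- c(a, b)
  combos <- utils::combn(m + n, m)
  ustat <- function(ga, gb) sum(outer(ga, gb, `<`)) # U of first group
  u_obs <- ustat(a, b)
  us <- apply(combos, 2, function(ix) ustat(pool[ix], pool[-ix]))
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# Independent BY oracle: double-loop step-down on the sorted q-values.
by_oracle <- function(p) {
  m <- length(p)
  cm <- sum(1 / seq_len(m))
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(vapply(i:m, function(j) m * cm * ps[j] / j, numeric(1)))
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# Run a CLI invocation with its console output captured.
quiet_cli <- function(expr) {
  out <- NULL
  invisible(utils::capture.output(out <- suppressMessages(expr)))
  out
}
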