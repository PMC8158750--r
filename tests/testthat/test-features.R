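test_that("four_stats computes population moments with sentinel rules", {
  s <- four_stats(c(1, 2, 3, 4))
  expect_equal(s[["mean"]], 2.5)
  expect_equal(s[["variance"]], 1.25)
  expect_equal(s[["skewness"]], 0)

  const <- four_stats(rep(3, 10))
  expect_equal(unname(const[c("variance", "skewness", "kurtosis")]),
               c(0, 0, 0))
  expect_equal(four_stats(c(-2, -1, 0, 1, 2))[["skewness"]], 0)
  expect_error(four_stats(numeric(0)), class = "bcgvf_invalid_argument")
})

make_map <- function(S, f_grid = seq_len(nrow(S)), hbl = NA_integer_) {
  structure(list(S = S, f_grid = f_grid, t_grid = seq_len(ncol(S)),
                 hbl = hbl, fs = 125), class = "bcg_tfmap")
}

test_that("slice correlation sees periodic structure", {
  block <- matrix(runif(5 * 10), 5, 10)
  per <- make_map(do.call(cbind, rep(list(block), 6)), hbl = 10L)
  sc <- slice_correlation(per)
  expect_length(sc, 5L)                     # floor(60/10) - 1
  expect_equal(sc, rep(1, 5), tolerance = 1e-12)

  withr::with_seed(13, {
    means <- replicate(100, {
      m <- make_map(matrix(rnorm(4 * 30), 4, 30), hbl = 10L)
      mean(slice_correlation(m))
    })
    expect_lt(abs(mean(means)), 0.1)
  })

  tiny <- make_map(matrix(1, 3, 12), hbl = 10L)   # only one full slice
  expect_true(isTRUE(attr(slice_correlation(tiny), "degenerate")))
})

test_that("instantaneous frequency is the power-weighted mean", {
  S <- matrix(0, 5, 4); S[3, ] <- 2
  expect_equal(instantaneous_frequency(make_map(S, f_grid = 1:5)),
               rep(3, 4))
  expect_equal(instantaneous_frequency(make_map(matrix(1, 5, 3), 1:5)),
               rep(3, 3))
  two <- matrix(0, 3, 2); two[1, ] <- 1; two[3, ] <- 1
  expect_equal(instantaneous_frequency(make_map(two, c(5, 10, 15))),
               rep(10, 2))
  # zero column -> midpoint sentinel
  S0 <- matrix(0, 3, 2); S0[2, 1] <- 1
  expect_equal(instantaneous_frequency(make_map(S0, c(2, 4, 6)))[2], 4)
})

test_that("time marginal smooths while roughly conserving mass", {
  flat <- marginal_time(make_map(matrix(2, 4, 100)))
  expect_length(flat, 100L)
  expect_equal(flat, rep(2, 100), tolerance = 1e-10)

  imp <- matrix(0, 4, 101); imp[, 51] <- 10
  sm <- marginal_time(make_map(imp))
  expect_gt(min(sum(sm) / sum(colMeans(imp)), sum(colMeans(imp)) / sum(sm)),
            0.95)
})

test_that("amplitude quantization has exactly Q+1 levels", {
  st <- seq(0, 1, length.out = 200)
  qa <- quantize_amplitude(st, Q = 10L)
  expect_true(all(qa %in% ((0:10) / 10)))
  expect_equal(qa[1], 0)
  expect_equal(qa[200], 1)
  # rounding rule: floor(v + 1/2)
  st2 <- c(0, 4.4, 4.5, 10)                 # already on the [0,Q] scale
  qa2 <- quantize_amplitude(st2, Q = 10L)
  expect_equal(qa2, c(0, 0.4, 0.5, 1))
  expect_true(isTRUE(attr(quantize_amplitude(rep(1, 5)), "degenerate")))
})

test_that("peak intervals difference successive detected peaks", {
  st <- numeric(60)
  for (p in c(10L, 25L, 45L)) st <- st + exp(-((seq_len(60) - p) / 1.5)^2)
  expect_equal(as.integer(peak_intervals(st, separation = 5L)), c(15L, 20L))

  per <- rep(exp(-((1:25 - 13) / 3)^2), 6)
  pi_per <- peak_intervals(per, separation = 10L)
  expect_true(all(pi_per == 25L))
  expect_true(isTRUE(attr(peak_intervals(seq_len(50) / 50), "degenerate")))
})

test_that("spectral density is the row-mean identity", {
  withr::with_seed(17, {
    S <- matrix(rexp(6 * 40), 6, 40)
    expect_identical(spectral_density(make_map(S)), rowMeans(S))
    expect_length(spectral_density(make_map(S)), 6L)
  })
})

test_that("FWHM matches closed forms", {
  f <- seq(0, 20, by = 0.01)
  gauss <- exp(-(f - 10)^2 / 2)            # sigma = 1 Hz
  expect_equal(fwhm(gauss, f), 2 * sqrt(2 * log(2)), tolerance = 0.02)

  tri <- pmax(0, 1 - abs(f - 10) / 2)      # base width 4
  expect_equal(fwhm(tri, f), 2, tolerance = 0.02)

  rect <- as.numeric(f >= 9 & f < 12)      # 300 bins of 0.01 -> width 3
  expect_equal(fwhm(rect, f), 3, tolerance = 0.02)

  # peak at the band edge clamps one side
  edge <- exp(-f / 2)
  expect_equal(fwhm(edge, f), 2 * log(2), tolerance = 0.02)
  expect_true(isTRUE(attr(fwhm(numeric(50), seq(1, 20, length.out = 50)),
                          "degenerate")))
})

test_that("range metric is max minus min", {
  expect_equal(range_metric(c(-2, 0, 3)), 5)
  expect_equal(range_metric(rep(1, 875)), 0)
  withr::with_seed(5, {
    x <- rnorm(875)
    expect_equal(range_metric(x), range_metric(rev(x)))
  })
})

test_that("extract_features returns 22 finite named values, purely", {
  segs <- fixture_segments()
  for (s in segs) {
    f <- extract_features(s)
    expect_length(f, 22L)
    expect_identical(names(f), bcgvf:::FEATURE_NAMES)
    expect_true(all(is.finite(f)))
  }
  expect_identical(extract_features(segs$SR), extract_features(segs$SR))
  # qualitative ordering: SR slices correlate more than VF's
  expect_gt(extract_features(segs$SR)[["SC_mean"]],
            extract_features(segs$VF)[["SC_mean"]])
})

test_that("feature matrix round-trips bit-exactly through CSV", {
  X <- utils::head(fixture_features(), 20L)
  path <- withr::local_tempfile(fileext = ".csv")
  write_features(X, path)
  Y <- read_features(path)
  expect_identical(Y, as.data.frame(X))
})
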