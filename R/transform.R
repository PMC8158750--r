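# Segment transformation: weighted wavelet reconstruction, autocorrelation
# enhancement, discrete Stockwell (S) transform, heartbeat-cycle-length
# estimation, and the middle-period crop.

#' Transform-stage configuration
#'
#' @param fs sampling rate, Hz.
#' @param f_lo,f_hi retained S-transform frequency band, Hz.
#' @param acf_norm_range target range of the pre-squaring ACF
#'   normalization.
#' @param hbl_search heartbeat cycle-length search bounds in samples
#'   (0.35-1.2 s, i.e. heart rates 50-170 bpm).
#' @param Q amplitude quantization level count.
#' @param sg_window,sg_order Savitzky-Golay parameters for the time
#'   marginal.
#' @param pi_prominence,pi_separation peak-detection parameters for the
#'   peak-interval feature: minimum prominence as a fraction of the signal
#'   range, and minimum peak separation in samples.
#' @param acf_denominator `"population"` (1/N, so r\[0\] = 1 exactly) or
#'   `"sample"` (1/(N-1)).
#' @return configuration list of class `bcg_config`.
#' @export
transform_config <- function(fs = 125, f_lo = 1, f_hi = 20,
                             acf_norm_range = c(1, 2),
                             hbl_search = c(44L, 150L),
                             Q = 10L, sg_window = 31L, sg_order = 3L,
                             pi_prominence = 0.1, pi_separation = 20L,
                             acf_denominator = c("population", "sample")) {
  if (f_lo >= f_hi) stop_invalid("f_lo must be < f_hi")
  if (hbl_search[1] < 1 || hbl_search[2] >= SEGMENT_LEN) {
    stop_invalid("hbl_search must lie within [1, 875)")
  }
  structure(list(fs = fs, f_lo = f_lo, f_hi = f_hi,
                 acf_norm_range = acf_norm_range,
                 hbl_search = as.integer(hbl_search), Q = as.integer(Q),
                 sg_window = as.integer(sg_window),
                 sg_order = as.integer(sg_order),
                 pi_prominence = pi_prominence,
                 pi_separation = as.integer(pi_separation),
                 acf_denominator = match.arg(acf_denominator)),
            class = "bcg_config")
}

#' Weighted wavelet reconstruction of a segment
#'
#' Decomposes the (preprocessed) segment with a second 7-level db6
#' transform and returns `|cc6| * d6 + d3 + d4 + d5`, where `cc6` is the
#' Pearson correlation between `d6` and the segment. The data-driven d6
#' weight compensates per-subject differences in how much heartbeat energy
#' falls below 2 Hz. A zero-variance `d6` or segment sets `cc6 = 0`.
#'
#' @param x numeric segment (875 samples) or a `bcg_segment`.
#' @return numeric vector, same length as the input.
#' @export
weighted_reconstruct <- function(x) {
  if (inherits(x, "bcg_segment")) x <- x$samples
  dec <- dwt_decompose(x)
  cc6 <- if (sd(dec$d6) == 0 || sd(x) == 0) 0 else cor(dec$d6, x)
  abs(cc6) * dec$d6 + dec$d3 + dec$d4 + dec$d5
}

#' Autocorrelation sequence
#'
#' Normalized autocorrelation over all nonnegative lags,
#' \deqn{r_k = \frac{1}{c_0 N} \sum_{t=1}^{N-k} (x_t - \bar x)(x_{t+k} - \bar x),
#'       \quad k = 0, \dots, N-1,}
#' with \eqn{c_0} the population variance (divide by N), so that
#' \eqn{r_0 = 1} exactly.
#'
#' @param x numeric vector, length >= 2, non-constant.
#' @param denominator `"population"` (default) or `"sample"` (1/(N-1); then
#'   `r[0] = (N-1)/N`).
#' @return numeric vector of length `N` (lags 0..N-1).
#' @export
acf_seq <- function(x, denominator = c("population", "sample")) {
  denominator <- match.arg(denominator)
  N <- length(x)
  if (N < 2L) stop_invalid("acf_seq() needs length >= 2")
  xc <- x - mean(x)
  c0 <- mean(xc^2)
  if (c0 == 0) stop_degenerate("acf_seq() is undefined for constant input")
  # FFT-based autocovariance (linear, via zero padding)
  m <- stats::nextn(2L * N)
  ac <- Re(fft(Mod(fft(c(xc, numeric(m - N))))^2, inverse = TRUE))[1:N] / m
  r <- ac / ac[1]
  if (denominator == "sample") r <- r * (N - 1) / N  # r[0] = (N-1)/N
  r
}

#' Enhance an autocorrelation sequence
#'
#' Affinely maps the ACF onto `range` (default \[1, 2\]) and squares it
#' element-wise, yielding values in \[1, 4\]. The monotone transform
#' preserves peak locations while amplifying the rhythm peaks relative to
#' the floor.
#'
#' @param r numeric ACF sequence, non-constant.
#' @param range length-2 target range of the affine map.
#' @return numeric vector, same length.
#' @export
acf_enhance <- function(r, range = c(1, 2)) {
  rng <- base::range(r)
  if (rng[1] == rng[2]) stop_degenerate("acf_enhance() needs non-constant input")
  ((r - rng[1]) / (rng[2] - rng[1]) * (range[2] - range[1]) + range[1])^2
}

#' Estimate the heartbeat cycle length of a segment
#'
#' For each candidate beat length L in `search` (samples), the time-domain
#' segment is cut into non-overlapping beats of length L; the Pearson
#' correlations of adjacent beat pairs are averaged, and the L maximizing
#' the average is returned, with ties broken to the smallest L. Beats past
#' the last full window are discarded.
#'
#' Under noise, an integer multiple of the true beat length scores a
#' statistical tie with the true length (a window of two aligned beats
#' correlates with its neighbour exactly as well as one beat does), so the
#' tie-break is applied with a small score tolerance: among all candidates
#' within `tie_tol` of the maximum average correlation, the smallest L --
#' the fundamental period -- is returned.
#'
#' @param x numeric time-domain segment (875 samples) or `bcg_segment`.
#' @param search integer bounds, default c(44, 150) (0.35-1.2 s at 125 Hz).
#' @param tie_tol score tolerance treated as a tie (default 0.02).
#' @return integer beat length in samples, within `search`.
#' @export
estimate_hbl <- function(x, search = c(44L, 150L), tie_tol = 0.02) {
  if (inherits(x, "bcg_segment")) x <- x$samples
  n <- length(x)
  cand <- search[1]:search[2]
  score <- vapply(cand, function(L) {
    nb <- n %/% L
    if (nb < 2L) return(NA_real_)
    m <- matrix(x[seq_len(nb * L)], nrow = L)
    cc <- suppressWarnings(
      vapply(seq_len(nb - 1L), function(i) cor(m[, i], m[, i + 1L]),
             numeric(1)))
    if (all(is.na(cc))) return(NA_real_)
    mean(cc, na.rm = TRUE)
  }, numeric(1))
  if (all(is.na(score))) {
    stop_degenerate("estimate_hbl(): all adjacent-beat correlations undefined")
  }
  top <- max(score, na.rm = TRUE)
  cand[which(!is.na(score) & score >= top - tie_tol)[1]]
}

new_tfmap <- function(S, f_grid, t_grid, hbl = NA_integer_, fs = 125) {
  structure(list(S = S, f_grid = f_grid, t_grid = t_grid,
                 hbl = hbl, fs = fs), class = "bcg_tfmap")
}

#' @export
print.bcg_tfmap <- function(x, ...) {
  cat(sprintf("<bcg_tfmap> %d freq bins (%.2f-%.2f Hz) x %d time cols, hbl = %s\n",
              nrow(x$S), min(x$f_grid), max(x$f_grid), ncol(x$S),
              ifelse(is.na(x$hbl), "NA", x$hbl)))
  invisible(x)
}

#' Discrete Stockwell (S) transform power map
#'
#' FFT formulation of the S transform: for each retained DFT frequency
#' bin j, the spectrum is shifted by j, windowed with the frequency-domain
#' Gaussian voice \eqn{\exp(-2\pi^2 m^2 / j^2)} (time-domain standard
#' deviation 1/f, the frequency-adaptive window), and inverse-transformed.
#' Only bins inside \[`f_lo`, `f_hi`\] Hz are kept, and the returned map is
#' the squared modulus (power). The frequency resolution is the DFT bin
#' spacing `fs / length(x)`; each voice's time-domain window sums to 1.
#'
#' @param x numeric signal (here, the enhanced ACF of a segment).
#' @param cfg a [transform_config()].
#' @return a `bcg_tfmap` with nonnegative power matrix `S` (J x I),
#'   `f_grid` (Hz) and `t_grid` (1-based sample indices).
#' @export
stransform <- function(x, cfg = transform_config()) {
  if (any(!is.finite(x))) stop_invalid("stransform() needs finite input")
  N <- length(x)
  X <- fft(x) / N
  j_set <- seq.int(ceiling(cfg$f_lo * N / cfg$fs), floor(cfg$f_hi * N / cfg$fs))
  j_set <- j_set[j_set >= 1L]
  m <- 0:(N - 1L)
  mw <- ifelse(m > N / 2, m - N, m)        # wrapped (signed) voice offsets
  S <- matrix(0, nrow = length(j_set), ncol = N)
  for (row in seq_along(j_set)) {
    j <- j_set[row]
    G <- exp(-2 * pi^2 * mw^2 / j^2)
    S[row, ] <- Mod(fft(X[(m + j) %% N + 1L] * G, inverse = TRUE))^2
  }
  new_tfmap(S, f_grid = j_set * cfg$fs / N, t_grid = seq_len(N), fs = cfg$fs)
}

#' Crop a time-frequency map to the middle period
#'
#' Restricts the time columns to sample indices in
#' `[floor(hbl/2) + 1, N - hbl]`, discarding the transform's biased edges;
#' the retained span depends on the segment's heartbeat cycle length.
#'
#' @param map a `bcg_tfmap` over N time columns.
#' @param hbl heartbeat cycle length in samples.
#' @param N original segment length (default 875).
#' @return cropped `bcg_tfmap` (contiguous column slice) with `hbl` set.
#' @export
middle_crop <- function(map, hbl, N = SEGMENT_LEN) {
  stopifnot(inherits(map, "bcg_tfmap"))
  keep <- (floor(hbl / 2) + 1L):(N - hbl)
  keep <- keep[keep >= 1L & keep <= ncol(map$S)]
  if (!length(keep)) stop("internal error: empty middle-period crop")
  new_tfmap(map$S[, keep, drop = FALSE], map$f_grid, map$t_grid[keep],
            hbl = as.integer(hbl), fs = map$fs)
}

#' Full segment transformation
#'
#' Composition of the transform stage: heartbeat-cycle-length estimation on
#' the time-domain segment, weighted wavelet reconstruction, ACF,
#' enhancement (normalize + square), S-transform power map, and middle-
#' period crop.
#'
#' @param seg a `bcg_segment` (875 samples).
#' @param cfg a [transform_config()].
#' @return a cropped `bcg_tfmap` with the segment's `hbl`.
#' @export
transform_segment <- function(seg, cfg = transform_config()) {
  x <- if (inherits(seg, "bcg_segment")) seg$samples else seg
  if (length(x) != SEGMENT_LEN) {
    stop_invalid("transform_segment() expects an 875-sample segment")
  }
  hbl <- estimate_hbl(x, cfg$hbl_search)
  wr <- weighted_reconstruct(x)
  r <- acf_seq(wr, cfg$acf_denominator)
  re <- acf_enhance(r, cfg$acf_norm_range)
  map <- stransform(re, cfg)
  middle_crop(map, hbl, length(x))
}
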