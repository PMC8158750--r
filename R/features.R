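# The 22-element feature set: five feature sequences (SC, IF, QA, PI, SD;
# mean/variance/skewness/kurtosis each) plus FWHM and RM.

FEATURE_NAMES <- c(
  "SC_mean", "SC_var", "SC_skew", "SC_kurt",
  "IF_mean", "IF_var", "IF_skew", "IF_kurt",
  "QA_mean", "QA_var", "QA_skew", "QA_kurt",
  "PI_mean", "PI_var", "PI_skew", "PI_kurt",
  "SD_mean", "SD_var", "SD_skew", "SD_kurt",
  "FWHM", "RM")

#' Adjacent slice correlations of a time-frequency map
#'
#' Cuts the power map into consecutive time slices of width `hbl` and
#' correlates each slice with the next:
#' `SC[k] = cor(S[, l_k], S[, l_k + hbl])`, `k = 1..floor(I/hbl) - 1`,
#' where both blocks (J x hbl) are vectorized column-major. Rhythmic
#' segments give SC near 1; fibrillatory segments decorrelate.
#'
#' @param map a cropped `bcg_tfmap` with `hbl` set.
#' @return numeric SC sequence; the degenerate case of fewer than two full
#'   slices returns the single sentinel 0 with attribute
#'   `degenerate = TRUE`.
#' @export
slice_correlation <- function(map) {
  stopifnot(inherits(map, "bcg_tfmap"), !is.na(map$hbl))
  hbl <- map$hbl
  I <- ncol(map$S)
  K <- I %/% hbl - 1L
  if (K < 1L) {
    return(structure(0, degenerate = TRUE))
  }
  vapply(seq_len(K), function(k) {
    cols <- ((k - 1L) * hbl + 1L):(k * hbl)
    v <- suppressWarnings(cor(as.vector(map$S[, cols]),
                              as.vector(map$S[, cols + hbl])))
    if (is.na(v)) 0 else v
  }, numeric(1))
}

#' Instantaneous frequency sequence
#'
#' Power-weighted mean frequency of each time column,
#' `IF[i] = sum_j f[j] S[j,i] / sum_j S[j,i]`. Zero-power columns get the
#' midpoint of the frequency grid as a sentinel.
#'
#' @param map a `bcg_tfmap`.
#' @return numeric vector of length `ncol(map$S)`, in Hz.
#' @export
instantaneous_frequency <- function(map) {
  stopifnot(inherits(map, "bcg_tfmap"))
  tot <- colSums(map$S)
  num <- as.numeric(crossprod(map$f_grid, map$S))
  out <- ifelse(tot > 0, num / pmax(tot, .Machine$double.xmin),
                mean(range(map$f_grid)))
  as.numeric(out)
}

#' Time marginal of a time-frequency map
#'
#' Column means of the power map smoothed with a Savitzky-Golay filter.
#'
#' @param map a `bcg_tfmap`.
#' @param sg_window,sg_order smoothing parameters (defaults 31, 3).
#' @return numeric vector of length `ncol(map$S)`.
#' @export
marginal_time <- function(map, sg_window = 31L, sg_order = 3L) {
  stopifnot(inherits(map, "bcg_tfmap"))
  sgolay_smooth(colMeans(map$S), sg_window, sg_order)
}

#' Quantized amplitude sequence
#'
#' Affinely normalizes the time marginal into \[0, Q\] and quantizes to
#' `floor(v + 1/2) / Q`, yielding exactly Q + 1 levels in \{0, 1/Q, .., 1\}.
#' A constant marginal quantizes to all zeros (sentinel).
#'
#' @param st time marginal from [marginal_time()].
#' @param Q quantization level count (default 10).
#' @return numeric QA sequence, values in `{0, 1/Q, ..., 1}`.
#' @export
quantize_amplitude <- function(st, Q = 10L) {
  rng <- range(st)
  if (rng[1] == rng[2]) {
    return(structure(rep(0, length(st)), degenerate = TRUE))
  }
  v <- (st - rng[1]) / (rng[2] - rng[1]) * Q
  floor(v + 0.5) / Q
}

#' Peak intervals of the time marginal
#'
#' Detects local maxima of the (smoothed) time marginal with a minimum
#' prominence of `prominence` x range and minimum separation `separation`
#' samples, then returns successive differences of the peak positions.
#'
#' @param st time marginal.
#' @param prominence minimum prominence as a fraction of the range
#'   (default 0.1).
#' @param separation minimum peak separation in samples (default 20).
#' @return integer PI sequence; fewer than two peaks returns the sentinel 0
#'   with attribute `degenerate = TRUE`.
#' @export
peak_intervals <- function(st, prominence = 0.1, separation = 20L) {
  p <- find_peaks(st, min_prominence = prominence * diff(range(st)),
                  min_separation = separation)
  if (length(p) < 2L) {
    return(structure(0, degenerate = TRUE))
  }
  diff(p)
}

#' Frequency marginal (spectral density) of a time-frequency map
#'
#' Row means of the power map over time; the SD feature sequence is this
#' marginal itself, without further transformation.
#'
#' @param map a `bcg_tfmap`.
#' @return numeric vector of length `nrow(map$S)` (one value per frequency
#'   bin).
#' @export
spectral_density <- function(map) {
  stopifnot(inherits(map, "bcg_tfmap"))
  rowMeans(map$S)
}

#' Full width at half maximum of the dominant spectral peak
#'
#' Locates the global maximum of the frequency marginal (ties break to the
#' lowest frequency) and finds the half-height crossings on either side by
#' linear interpolation between grid points; a side that never crosses
#' within the band is clamped to the band edge.
#'
#' @param sf frequency marginal.
#' @param f_grid frequencies (Hz) matching `sf`.
#' @return width in Hz; an all-zero marginal returns the full band width
#'   (sentinel).
#' @export
fwhm <- function(sf, f_grid) {
  stopifnot(length(sf) == length(f_grid))
  if (all(sf == 0)) {
    return(structure(diff(range(f_grid)), degenerate = TRUE))
  }
  j0 <- which.max(sf)
  half <- sf[j0] / 2
  J <- length(sf)
  f_left <- f_grid[1]
  if (j0 > 1L) {
    for (i in (j0 - 1L):1L) {
      if (sf[i] < half) {
        f_left <- f_grid[i] + (half - sf[i]) / (sf[i + 1L] - sf[i]) *
          (f_grid[i + 1L] - f_grid[i])
        break
      }
    }
  }
  f_right <- f_grid[J]
  if (j0 < J) {
    for (i in (j0 + 1L):J) {
      if (sf[i] < half) {
        f_right <- f_grid[i - 1L] + (sf[i - 1L] - half) / (sf[i - 1L] - sf[i]) *
          (f_grid[i] - f_grid[i - 1L])
        break
      }
    }
  }
  f_right - f_left
}

#' Time-domain range of a segment
#'
#' Max minus min of the preprocessed time-domain segment; the primary
#' motion-artifact discriminator.
#'
#' @param seg `bcg_segment` or numeric vector.
#' @return nonnegative scalar.
#' @export
range_metric <- function(seg) {
  x <- if (inherits(seg, "bcg_segment")) seg$samples else seg
  diff(range(x))
}

#' Extract the 22-element feature vector of a segment
#'
#' Runs [transform_segment()] and computes the five feature sequences and
#' scalar features: SC (slice correlation), IF (instantaneous frequency),
#' QA (quantized amplitude), PI (peak intervals), SD (spectral density) -
#' each summarized by mean, variance, skewness and kurtosis - plus FWHM of
#' the dominant spectral peak and the time-domain range RM. All 22 values
#' are finite for any input; degenerate sequences fall back to documented
#' sentinels recorded in the `quality` attribute.
#'
#' @param seg a `bcg_segment`.
#' @param cfg a [transform_config()].
#' @return named numeric vector of length 22 (attribute `quality` lists any
#'   sentinel substitutions).
#' @export
extract_features <- function(seg, cfg = transform_config()) {
  map <- transform_segment(seg, cfg)
  sc <- slice_correlation(map)
  iff <- instantaneous_frequency(map)
  st <- marginal_time(map, cfg$sg_window, cfg$sg_order)
  qa <- quantize_amplitude(st, cfg$Q)
  pi_seq <- peak_intervals(st, cfg$pi_prominence, cfg$pi_separation)
  sf <- spectral_density(map)
  vals <- c(four_stats(sc), four_stats(iff), four_stats(qa),
            four_stats(pi_seq), four_stats(sf),
            fwhm(sf, map$f_grid), range_metric(seg))
  names(vals) <- FEATURE_NAMES
  flagged <- c(SC = isTRUE(attr(sc, "degenerate")),
               QA = isTRUE(attr(qa, "degenerate")),
               PI = isTRUE(attr(pi_seq, "degenerate")))
  attr(vals, "quality") <- names(flagged)[flagged]
  vals
}

#' Extract a feature matrix from a list of segments
#'
#' @param segments list of `bcg_segment`.
#' @param cfg a [transform_config()].
#' @return data.frame with columns `subject_id`, `label`, `t0` and the 22
#'   named features.
#' @export
extract_feature_matrix <- function(segments, cfg = transform_config()) {
  stopifnot(length(segments) > 0L)
  rows <- lapply(segments, function(s) {
    f <- extract_features(s, cfg)
    cbind(data.frame(subject_id = s$subject_id, label = s$label, t0 = s$t0,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(f)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write / read a feature matrix as CSV with bit-exact round-trip
#'
#' Numeric columns are serialized with 17 significant digits so that
#' `read_features(write_features(x))` reproduces the doubles exactly.
#'
#' @param x feature matrix data.frame from [extract_feature_matrix()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_features <- function(x, path) {
  y <- x
  num <- vapply(y, is.numeric, logical(1)) & !(names(y) %in% "t0")
  y[num] <- lapply(y[num], function(v) formatC(v, digits = 17, format = "g"))
  write.csv(y, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE)
  out$t0 <- as.integer(out$t0)
  out
}
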