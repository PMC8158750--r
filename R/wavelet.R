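# Daubechies-6 discrete wavelet filter bank.
#
# The analysis is an orthonormal periodized DWT run after reflection-padding
# the signal to the next multiple of 2^7, which keeps every level an even
# length and makes perfect reconstruction exact (double-shift orthogonality
# of the Daubechies filters survives periodization for any even length).
# Each detail band is reconstructed back to signal length so the bank behaves
# like MATLAB's wrcoef over a wavedec: d1 + ... + d7 + a7 == x to machine
# precision.

# db6 scaling (reconstruction low-pass) filter, 12 taps.
DB6_REC_LO <- c(
  0.111540743350080145, 0.494623890398385365, 0.751133908021578079,
  0.315250351709243358, -0.226264693965169156, -0.129766867567095570,
  0.097501605587079362, 0.027522865530016288, -0.031582039318031156,
  0.000553842200993802, 0.004777257511010651, -0.001077301084955800)

db6_filters <- function() {
  h <- DB6_REC_LO
  L <- length(h)
  g <- (-1)^(0:(L - 1)) * rev(h)  # QMF high-pass partner
  list(h = h, g = g, L = L)
}

# One periodized analysis step: inner products with even translates of the
# reconstruction filters (self-adjoint formulation, so synthesis reuses the
# same taps). n must be even.
dwt_step <- function(x, flt) {
  n <- length(x)
  half <- n %/% 2L
  a <- numeric(half)
  d <- numeric(half)
  k2 <- 2L * (0:(half - 1L))
  for (m in 0:(flt$L - 1L)) {
    xi <- x[(k2 + m) %% n + 1L]
    a <- a + flt$h[m + 1L] * xi
    d <- d + flt$g[m + 1L] * xi
  }
  list(a = a, d = d)
}

# One periodized synthesis step, exact inverse of dwt_step.
idwt_step <- function(a, d, flt) {
  half <- length(a)
  n <- 2L * half
  y <- numeric(n)
  k2 <- 2L * (0:(half - 1L))
  for (m in 0:(flt$L - 1L)) {
    idx <- (k2 + m) %% n + 1L
    y[idx] <- y[idx] + flt$h[m + 1L] * a + flt$g[m + 1L] * d
  }
  y
}

# Reflection-pad x at the tail up to length n (n - length(x) < length(x)).
reflect_pad <- function(x, n) {
  n0 <- length(x)
  if (n == n0) return(x)
  pad <- n - n0
  ext <- rev(x)
  while (length(ext) < pad) ext <- c(ext, x, rev(x))
  c(x, ext[seq_len(pad)])
}

#' Daubechies-6 seven-level wavelet decomposition
#'
#' Decomposes a signal into seven reconstructed detail signals `d1`..`d7`
#' and the level-7 approximation `a7`, each the same length as the input.
#' At 125 Hz the detail bands are approximately d1 = 31-62 Hz, d2 = 16-31,
#' d3 = 7.8-16, d4 = 3.9-7.8, d5 = 2.0-3.9, d6 = 1.0-2.0, d7 = 0.5-1.0 Hz,
#' with the respiratory/drift remainder in `a7`. The components sum to the
#' input exactly (perfect reconstruction).
#'
#' @param x numeric signal of length >= 128.
#' @param levels number of decomposition levels (default 7).
#' @return object of class `bcg_wavedec`: a list of full-length component
#'   signals `d1`..`d<levels>` and `a<levels>`.
#' @export
dwt_decompose <- function(x, levels = 7L) {
  if (!is.numeric(x) || length(x) < 2L^levels) {
    stop_invalid("dwt_decompose() needs a numeric signal of length >= ",
                 2L^levels)
  }
  x <- as.numeric(x)
  n0 <- length(x)
  block <- 2L^levels
  n <- as.integer(ceiling(n0 / block) * block)
  flt <- db6_filters()
  xp <- reflect_pad(x, n)

  coeffs <- vector("list", levels)  # detail coefficients, level 1..levels
  a <- xp
  for (j in seq_len(levels)) {
    st <- dwt_step(a, flt)
    coeffs[[j]] <- st$d
    a <- st$a
  }

  # Reconstruct one component back to full length from its coefficients.
  lift <- function(vec, level, is_detail) {
    y <- if (is_detail) {
      idwt_step(numeric(length(vec)), vec, flt)
    } else {
      idwt_step(vec, numeric(length(vec)), flt)
    }
    if (level > 1L) for (j in (level - 1L):1L) {
      y <- idwt_step(y, numeric(length(y)), flt)
    }
    y[seq_len(n0)]
  }

  out <- lapply(seq_len(levels), function(j) lift(coeffs[[j]], j, TRUE))
  names(out) <- paste0("d", seq_len(levels))
  out[[paste0("a", levels)]] <- lift(a, levels, FALSE)
  structure(out, class = "bcg_wavedec", n = n0, levels = levels)
}

#' Cardiac-band reconstruction from a wavelet decomposition
#'
#' Sums the detail signals d3..d7 (about 0.5-16 Hz at 125 Hz sampling),
#' the band carrying the heartbeat-related BCG content, and also returns the
#' low-frequency d7 component separately for use in the adaptive-filter
#' noise reference.
#'
#' @param dec a `bcg_wavedec` from [dwt_decompose()].
#' @return list with `bcg` (d3 + d4 + d5 + d6 + d7) and `d7`.
#' @export
detail_reconstruct <- function(dec) {
  if (!inherits(dec, "bcg_wavedec")) {
    stop_invalid("detail_reconstruct() expects a bcg_wavedec")
  }
  list(bcg = dec$d3 + dec$d4 + dec$d5 + dec$d6 + dec$d7, d7 = dec$d7)
}
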