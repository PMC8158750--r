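#' @importFrom stats fft cor sd var rnorm runif quantile coef glm binomial
#'   predict wilcox.test hclust cutree as.dist setNames
#' @importFrom utils read.csv write.csv head tail
NULL

# Internal error helper: user-facing argument errors get a consistent class so
# callers (and the CLI) can distinguish them from internal failures.
stop_invalid <- function(...) {
  stop(structure(class = c("bcgvf_invalid_argument", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_degenerate <- function(...) {
  stop(structure(class = c("bcgvf_degenerate_input", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

# Seeded evaluation that never disturbs the caller's RNG stream.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# Derive a child seed from a master seed; kept below 2^31.
derive_seed <- function(seed, index) {
  (as.numeric(seed) * 7919 + 104729 * as.numeric(index)) %% 2147483629 + 1
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == floor(x)
}

#' Population moment statistics of a sequence
#'
#' Returns the mean, population variance, skewness and (non-excess) kurtosis
#' of a numeric sequence, the four summary statistics attached to every
#' feature sequence. Moments are population moments (denominator `n`);
#' skewness is \eqn{m_3/m_2^{3/2}} and kurtosis \eqn{m_4/m_2^2}. For
#' sequences shorter than 3 elements or with zero variance, skewness and
#' kurtosis are defined as 0 so downstream feature vectors stay finite.
#'
#' @param x numeric vector, length >= 1.
#' @return named numeric vector `c(mean, variance, skewness, kurtosis)`.
#' @examples
#' four_stats(c(1, 2, 3, 4))
#' @export
four_stats <- function(x) {
  if (length(x) < 1L || !is.numeric(x)) {
    stop_invalid("four_stats() needs a non-empty numeric vector")
  }
  x <- as.numeric(x)
  n <- length(x)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (n < 3L || m2 <= 0) {
    return(c(mean = m, variance = m2, skewness = 0, kurtosis = 0))
  }
  m3 <- mean((x - m)^3)
  m4 <- mean((x - m)^4)
  c(mean = m, variance = m2, skewness = m3 / m2^1.5, kurtosis = m4 / m2^2)
}

# Local maxima of a sequence with minimum prominence and minimum separation.
# A peak is strictly greater than both neighbours; prominence is measured
# against the lowest saddle separating it from higher terrain on each side.
# Peaks are greedily thinned tallest-first to enforce the separation.
find_peaks <- function(x, min_prominence = 0, min_separation = 1L) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  cand <- which(x[2:(n - 1L)] > x[1:(n - 2L)] & x[2:(n - 1L)] > x[3:n]) + 1L
  if (!length(cand)) return(integer(0))
  if (min_prominence > 0) {
    prom <- vapply(cand, function(i) {
      lmin <- x[i]; j <- i
      while (j > 1L && x[j] <= x[i]) { lmin <- min(lmin, x[j]); j <- j - 1L }
      if (x[j] <= x[i]) lmin <- min(lmin, x[1L])
      rmin <- x[i]; j <- i
      while (j < n && x[j] <= x[i]) { rmin <- min(rmin, x[j]); j <- j + 1L }
      if (x[j] <= x[i]) rmin <- min(rmin, x[n])
      x[i] - max(lmin, rmin)
    }, numeric(1))
    cand <- cand[prom >= min_prominence]
    if (!length(cand)) return(integer(0))
  }
  if (min_separation > 1L && length(cand) > 1L) {
    ord <- cand[order(x[cand], decreasing = TRUE)]
    keep <- integer(0)
    for (i in ord) {
      if (!length(keep) || all(abs(keep - i) >= min_separation)) {
        keep <- c(keep, i)
      }
    }
    cand <- sort(keep)
  }
  cand
}

#' Savitzky-Golay smoothing filter
#'
#' Least-squares polynomial smoothing with reflection padding at the edges.
#'
#' @param x numeric vector.
#' @param window odd window length in samples (default 31).
#' @param order polynomial order (default 3), must be < `window`.
#' @return smoothed vector, same length as `x`.
#' @export
sgolay_smooth <- function(x, window = 31L, order = 3L) {
  window <- as.integer(window)
  if (window %% 2L == 0L) stop_invalid("sgolay window must be odd")
  if (order >= window) stop_invalid("sgolay order must be < window")
  n <- length(x)
  if (n < 2L) return(x)
  if (window > n) window <- max(3L, (if (n %% 2L == 0L) n - 1L else n) - 2L)
  if (order >= window) order <- window - 1L
  h <- (window - 1L) %/% 2L
  A <- outer(-h:h, 0:order, `^`)
  # convolution kernel = first row of the least-squares projector
  k <- (A %*% solve(crossprod(A), t(A)))[h + 1L, ]
  xp <- c(x[(h + 1L):2L], x, x[(n - 1L):(n - h)])
  as.numeric(stats::filter(xp, rev(k), sides = 2L))[(h + 1L):(h + n)]
}
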