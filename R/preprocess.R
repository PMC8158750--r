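# Preprocessing: wavelet detail reconstruction, LMS ventilator-artifact
# cancellation, and segmentation into labelled 7 s windows.

SEGMENT_LEN <- 875L   # 7 s at 125 Hz
SEGMENT_STRIDE <- c(SR = 875L, MA = 375L, VF = 125L)

#' Least-mean-squares adaptive filter state
#'
#' Houses the leaky-LMS parameters: tap count `L`, leakage `alpha`,
#' adaptation step `mu`, and the seed for the small random weight
#' initialisation.
#'
#' @param length filter length (number of taps), default 64.
#' @param alpha leakage factor in (0, 1], default 1.
#' @param mu adaptation step size, default 1e-8.
#' @param seed seed for weight initialisation (uniform in +/- 1e-3).
#' @return object of class `bcg_lms`.
#' @export
lms_state <- function(length = 64L, alpha = 1, mu = 1e-8, seed = 1L) {
  if (alpha <= 0 || alpha > 1) stop_invalid("alpha must lie in (0, 1]")
  if (mu <= 0) stop_invalid("mu must be > 0")
  w <- with_seed(seed, runif(as.integer(length), -1e-3, 1e-3))
  structure(list(w = w, alpha = alpha, mu = mu, L = as.integer(length),
                 seed = as.integer(seed)),
            class = "bcg_lms")
}

#' Construct the ventilator noise reference
#'
#' In each non-overlapping 3 s (375-sample) window, the extremum of largest
#' absolute amplitude is located; the signal inside a fixed half-width
#' around each extremum forms the pulse component (zero elsewhere). The
#' pulse component plus the low-frequency wavelet detail `d7` is smoothed
#' with a Savitzky-Golay filter to give the adaptive filter's reference
#' input.
#'
#' @param x numeric signal (typically the d3-d7 wavelet reconstruction).
#' @param d7 the separately extracted d7 detail, same length as `x`.
#' @param half_width samples kept either side of each window extremum
#'   (default 30, about one ventilator pulse lobe).
#' @param sg_window,sg_order Savitzky-Golay smoothing parameters.
#' @return numeric reference, same length as `x`.
#' @export
build_noise_reference <- function(x, d7, half_width = 30L,
                                  sg_window = 31L, sg_order = 3L) {
  n <- length(x)
  if (length(d7) != n) stop_invalid("x and d7 must have equal length")
  if (n < 375L) stop_invalid("need at least 375 samples (one 3 s window)")
  pulse <- numeric(n)
  starts <- seq(1L, n - 374L, by = 375L)
  for (s in starts) {
    win <- s:(s + 374L)
    ext <- win[which.max(abs(x[win]))]
    idx <- max(1L, ext - half_width):min(n, ext + half_width)
    pulse[idx] <- x[idx]
  }
  sgolay_smooth(pulse + d7, sg_window, sg_order)
}

#' Leaky-LMS adaptive noise cancellation
#'
#' Iterates, over buffered reference taps x(n) (most recent `L` samples,
#' zero-padded at the start),
#' \deqn{y(n) = w^T(n-1) x(n), \quad e(n) = d(n) - y(n), \quad
#'       w(n) = \alpha w(n-1) + \mu e(n) x(n)}
#' and returns the error signal `e`, i.e. the noise-cancelled BCG.
#'
#' @param d desired-response signal (the wavelet-reconstructed BCG).
#' @param ref reference (ventilator noise estimate), same length as `d`.
#' @param state an [lms_state()].
#' @return numeric vector `e`, same length as `d`.
#' @export
lms_cancel <- function(d, ref, state = lms_state()) {
  if (length(d) != length(ref)) stop_invalid("d and ref must match in length")
  stopifnot(inherits(state, "bcg_lms"))
  n <- length(d)
  L <- state$L
  w <- state$w
  alpha <- state$alpha
  mu <- state$mu
  buf <- c(numeric(L - 1L), ref)   # buf[k + L - 1] is ref[k]
  e <- numeric(n)
  for (k in seq_len(n)) {
    xk <- buf[(k + L - 1L):k]      # newest tap first
    y <- sum(w * xk)
    e[k] <- d[k] - y
    w <- alpha * w + mu * e[k] * xk
  }
  e
}

#' Preprocess a raw recording
#'
#' Runs the full recording through the 7-level db6 decomposition, keeps the
#' cardiac band (d3..d7), and, unless `lms = FALSE`, cancels the
#' ventilator artifact with the leaky-LMS filter driven by the
#' [build_noise_reference()] output.
#'
#' @param rec a `bcg_recording`.
#' @param lms apply ventilator cancellation (default TRUE).
#' @param state an [lms_state()].
#' @param half_width,sg_window,sg_order see [build_noise_reference()].
#' @return a `bcg_recording` with filtered samples (annotations preserved).
#' @export
preprocess_recording <- function(rec, lms = TRUE, state = lms_state(),
                                 half_width = 30L, sg_window = 31L,
                                 sg_order = 3L) {
  stopifnot(inherits(rec, "bcg_recording"))
  dec <- dwt_decompose(rec$samples)
  parts <- detail_reconstruct(dec)
  out <- parts$bcg
  if (isTRUE(lms)) {
    ref <- build_noise_reference(parts$bcg, parts$d7, half_width,
                                 sg_window, sg_order)
    out <- lms_cancel(parts$bcg, ref, state)
  }
  new_recording(out, rec$subject_id, rec$annotations, rec$fs)
}

new_segment <- function(samples, label, subject_id, t0) {
  structure(list(samples = as.numeric(samples), label = label,
                 subject_id = subject_id, t0 = as.integer(t0)),
            class = "bcg_segment")
}

#' @export
print.bcg_segment <- function(x, ...) {
  cat(sprintf("<bcg_segment> %s / %s, t0 = %d\n",
              x$subject_id, x$label, x$t0))
  invisible(x)
}

#' Split an annotated recording into 7 s analysis segments
#'
#' Within each annotated extent, emits 875-sample windows with a
#' class-dependent stride: non-overlapping for SR (875), 3 s shift for MA
#' (375), 1 s shift for VF (125). Incomplete tails are discarded; windows
#' never cross annotation boundaries. Extents shorter than 875 samples emit
#' nothing (a message is logged).
#'
#' @param rec a `bcg_recording` with annotations.
#' @return list of `bcg_segment`.
#' @export
segment_recording <- function(rec) {
  stopifnot(inherits(rec, "bcg_recording"))
  if (rec$fs != BCG_FS) stop_invalid("recordings must be sampled at 125 Hz")
  ann <- rec$annotations
  if (is.null(ann) || nrow(ann) == 0L) stop_invalid("annotations required")
  segs <- list()
  for (i in seq_len(nrow(ann))) {
    lab <- ann$label[i]
    stride <- SEGMENT_STRIDE[[lab]]
    ext_len <- ann$end[i] - ann$start[i]
    if (ext_len < SEGMENT_LEN) {
      message(sprintf("extent %d (%s): %d samples < %d, skipped",
                      i, lab, ext_len, SEGMENT_LEN))
      next
    }
    starts <- seq(ann$start[i], ann$end[i] - SEGMENT_LEN, by = stride)
    for (s in starts) {
      segs[[length(segs) + 1L]] <-
        new_segment(rec$samples[(s + 1L):(s + SEGMENT_LEN)],
                    lab, rec$subject_id, s)
    }
  }
  segs
}
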