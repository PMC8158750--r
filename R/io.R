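# Plain-text readers/writers for recordings and segments.

#' Write a recording to CSV (signal + annotation sidecar)
#'
#' The signal file has columns `sample_index,value` (0-based indices); the
#' sidecar has `start,end,label,subject_id` with half-open 0-based sample
#' extents.
#'
#' @param rec a `bcg_recording`.
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix (default the subject id).
#' @return named character vector of the two paths, invisibly.
#' @export
write_recording <- function(rec, dir, prefix = rec$subject_id) {
  stopifnot(inherits(rec, "bcg_recording"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sig_path <- file.path(dir, paste0(prefix, "_signal.csv"))
  ann_path <- file.path(dir, paste0(prefix, "_annotations.csv"))
  sig <- data.frame(sample_index = seq_along(rec$samples) - 1L,
                    value = formatC(rec$samples, digits = 17, format = "g"))
  write.csv(sig, sig_path, row.names = FALSE, quote = FALSE)
  ann <- rec$annotations
  ann$subject_id <- rec$subject_id
  write.csv(ann, ann_path, row.names = FALSE, quote = FALSE)
  invisible(c(signal = sig_path, annotations = ann_path))
}

#' Read a recording written by [write_recording()]
#'
#' @param signal_path signal CSV path.
#' @param annotations_path annotation CSV path.
#' @param fs sampling rate (default 125 Hz).
#' @return a `bcg_recording`.
#' @export
read_recording <- function(signal_path, annotations_path, fs = 125L) {
  sig <- read.csv(signal_path)
  ann <- read.csv(annotations_path, stringsAsFactors = FALSE)
  new_recording(sig$value, ann$subject_id[1],
                ann[, c("start", "end", "label")], fs)
}

#' Write segments to a columnar CSV container
#'
#' One row per segment: `subject_id`, `label`, `t0`, then 875 sample
#' columns `s0001..s0875`.
#'
#' @param segments list of `bcg_segment`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_segments <- function(segments, path) {
  stopifnot(length(segments) > 0L)
  mat <- t(vapply(segments, `[[`, numeric(SEGMENT_LEN), "samples"))
  colnames(mat) <- sprintf("s%04d", seq_len(SEGMENT_LEN))
  meta <- data.frame(
    subject_id = vapply(segments, `[[`, character(1), "subject_id"),
    label = vapply(segments, `[[`, character(1), "label"),
    t0 = vapply(segments, `[[`, integer(1), "t0"))
  out <- cbind(meta, as.data.frame(formatC(mat, digits = 17, format = "g"),
                                   stringsAsFactors = FALSE))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read segments written by [write_segments()]
#'
#' @param path CSV path.
#' @return list of `bcg_segment`.
#' @export
read_segments <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  sample_cols <- grep("^s[0-9]{4}$", names(df))
  lapply(seq_len(nrow(df)), function(i) {
    new_segment(as.numeric(df[i, sample_cols]), df$label[i],
                df$subject_id[i], df$t0[i])
  })
}
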