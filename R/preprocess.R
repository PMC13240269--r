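#' Construct a Recording
#'
#' A single subject's continuous multichannel EEG with its group label.
#'
#' @param subject_id string.
#' @param group group label (e.g. `"P"` or `"HC"`).
#' @param fs sampling rate, Hz.
#' @param channel_labels unique channel names, one per data row.
#' @param data channels-by-samples numeric matrix (microvolts).
#' @return object of class `recording`.
#' @export
recording <- function(subject_id, group, fs, channel_labels, data) {
  data <- as.matrix(data)
  if (nrow(data) != length(channel_labels)) stopf("data rows must match channel_labels")
  if (anyDuplicated(channel_labels)) stopf("channel labels must be unique")
  if (!all(is.finite(data))) stopf("recording data must be finite")
  if (!is_number(fs) || fs <= 0) stopf("fs must be positive")
  rownames(data) <- channel_labels
  structure(list(subject_id = as.character(subject_id), group = as.character(group),
                 fs = fs, channel_labels = as.character(channel_labels), data = data),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %s [%s]: %d ch x %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, x$group, nrow(x$data), ncol(x$data), x$fs,
              ncol(x$data) / x$fs))
  invisible(x)
}

#' Frequency band specification
#' @param name band label.
#' @param lo,hi band edges in Hz, `0 < lo < hi <= 40`.
#' @export
band_spec <- function(name, lo, hi) {
  if (!(is_number(lo) && is_number(hi) && lo > 0 && hi > lo && hi <= 40)) {
    stopf("band '%s' must satisfy 0 < lo < hi <= 40", name)
  }
  list(name = name, lo = lo, hi = hi)
}

#' Canonical EEG frequency bands
#'
#' delta 1-4, theta 4-8, alpha 8-13, beta 13-30 Hz. All are overridable in a
#' pipeline config; only the theta edges are anchored in the connectivity
#' literature this pipeline targets.
#' @param names optional subset to return.
#' @export
default_bands <- function(names = c("delta", "theta", "alpha", "beta")) {
  all <- list(delta = band_spec("delta", 1, 4), theta = band_spec("theta", 4, 8),
              alpha = band_spec("alpha", 8, 13), beta = band_spec("beta", 13, 30))
  bad <- setdiff(names, names(all))
  if (length(bad)) stopf("unknown band(s): %s", paste(bad, collapse = ", "))
  all[names]
}

## Apply a zero-phase (forward-backward) filter row-wise to a recording.
filter_rows <- function(rec, flt) {
  out <- rec
  out$data <- t(apply(rec$data, 1, function(x) signal::filtfilt(flt, x)))
  dimnames(out$data) <- dimnames(rec$data)
  out
}

#' Zero-phase band-pass filter
#'
#' 4th-order Butterworth band-pass applied forward and backward
#' (zero net phase shift, so downstream phase estimates are undistorted).
#'
#' @param rec a [recording()].
#' @param lo,hi passband edges in Hz, `lo < hi < fs/2`.
#' @return filtered copy of `rec`, same length.
#' @export
bandpass_filter <- function(rec, lo, hi) {
  nyq <- rec$fs / 2
  if (!(lo > 0 && lo < hi)) stopf("need 0 < lo < hi")
  if (hi >= nyq) stopf("hi (%g Hz) must be below Nyquist (%g Hz)", hi, nyq)
  filter_rows(rec, signal::butter(2, c(lo, hi) / nyq, type = "pass"))
}

#' Zero-phase notch filter
#'
#' Narrow Butterworth band-stop centred at `freq` with quality factor `q`
#' (stopband width `freq / q` Hz), applied forward-backward.
#'
#' @param rec a [recording()].
#' @param freq notch centre frequency in Hz (line noise: 50 or 60).
#' @param q quality factor; higher = narrower notch.
#' @export
notch_filter <- function(rec, freq, q = 30) {
  nyq <- rec$fs / 2
  if (freq >= nyq) stopf("notch frequency must be below Nyquist (%g Hz)", nyq)
  bw <- freq / q
  filter_rows(rec, signal::butter(2, c(freq - bw / 2, freq + bw / 2) / nyq, type = "stop"))
}

#' Re-reference to the common average
#'
#' Subtracts the instantaneous mean across channels from every channel, so the
#' channel mean is zero at each sample. Idempotent.
#'
#' @param rec a [recording()] with at least two channels.
#' @export
rereference_average <- function(rec) {
  if (nrow(rec$data) < 2) stopf("average reference needs >= 2 channels")
  out <- rec
  out$data <- sweep(rec$data, 2, colMeans(rec$data))
  out
}

#' Artifact-removal hook
#'
#' Placeholder for component-based artifact removal (e.g. ICA). The default is
#' the identity: no automated component-rejection rule is applied. Users with
#' their own criteria can pass a `function(recording) -> recording`.
#'
#' @param rec a [recording()].
#' @param fun optional replacement hook.
#' @export
artifact_hook <- function(rec, fun = NULL) {
  if (is.null(fun)) rec else fun(rec)
}

#' Segment a recording into fixed-length non-overlapping epochs
#'
#' @param rec a [recording()].
#' @param epoch_len_s epoch length in seconds; `epoch_len_s * fs` must be an
#'   integer. A trailing remainder shorter than one epoch is discarded.
#' @return an `epoch_array`: list with `epochs` (epochs x channels x samples
#'   array), `subject_id`, `group`, `fs`, `epoch_len_s`, `channel_labels`.
#' @export
epoch <- function(rec, epoch_len_s = 2) {
  spe <- epoch_len_s * rec$fs
  if (abs(spe - round(spe)) > 1e-9) stopf("epoch_len_s * fs must be an integer")
  spe <- as.integer(round(spe))
  n <- ncol(rec$data)
  k <- n %/% spe
  if (k < 1) stopf("recording (%d samples) shorter than one epoch (%d samples)", n, spe)
  arr <- array(NA_real_, c(k, nrow(rec$data), spe))
  for (e in seq_len(k)) arr[e, , ] <- rec$data[, ((e - 1) * spe + 1):(e * spe)]
  structure(list(subject_id = rec$subject_id, group = rec$group,
                 epochs = arr, fs = rec$fs, epoch_len_s = epoch_len_s,
                 channel_labels = rec$channel_labels),
            class = "epoch_array")
}

#' Band-filtered copies of a recording
#'
#' Filters the continuous recording into each requested band (zero-phase,
#' before epoching, so epoch edges carry no fresh filter transients) and
#' segments each band copy into epochs.
#'
#' @param rec a [recording()].
#' @param bands list of [band_spec()]s.
#' @param epoch_len_s epoch length passed to [epoch()].
#' @return named list band -> `epoch_array`.
#' @export
band_decompose <- function(rec, bands, epoch_len_s = 2) {
  if (!length(bands)) stopf("band list must be non-empty")
  out <- lapply(bands, function(b) epoch(bandpass_filter(rec, b$lo, b$hi), epoch_len_s))
  names(out) <- vapply(bands, `[[`, character(1), "name")
  out
}
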