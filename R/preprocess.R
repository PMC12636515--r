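# Preprocessing chain: power-line notch -> band-pass -> baseline correction ->
# segmentation -> per-window normalization. All filtering is zero-phase
# (forward-backward), so R-peak locations are preserved.

#' Filter specification for the preprocessing chain
#'
#' @param notch_freq power-line notch centre (Hz, default 50).
#' @param notch_q notch quality factor; the stop band spans
#'   `notch_freq / notch_q` Hz around the centre.
#' @param band_low,band_high diagnostic band edges (Hz). Defaults 0.5-40 Hz,
#'   the standard diagnostic ECG band.
#' @param filter_order band-pass order of the zero-phase cascade.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(notch_freq = 50, notch_q = 30,
                        band_low = 0.5, band_high = 40, filter_order = 4) {
  check_scalar(notch_freq, "notch_freq", 1)
  check_scalar(notch_q, "notch_q", 1e-6)
  check_scalar(band_low, "band_low", 1e-6)
  check_scalar(band_high, "band_high")
  if (band_low >= band_high) stop_invalid("band_low must be below band_high")
  structure(list(notch_freq = notch_freq, notch_q = notch_q,
                 band_low = band_low, band_high = band_high,
                 filter_order = filter_order), class = "filter_spec")
}

#' Zero-phase power-line notch filter
#'
#' A second-order Butterworth band-stop of width `notch_freq / notch_q`
#' around the notch centre, applied forward-backward ([signal::filtfilt()]),
#' which squares the magnitude response and cancels the phase. Attenuation at
#' the notch centre exceeds 30 dB while the passband (up to 40 Hz) stays
#' within 1 dB.
#'
#' @param x signal (mV vector).
#' @param fs sampling rate (Hz); must exceed `2 * notch_freq`.
#' @param spec a [filter_spec()].
#' @return Filtered vector, same length as `x`.
#' @export
notch_filter <- function(x, fs, spec = filter_spec()) {
  if (fs <= 2 * spec$notch_freq) {
    stop_invalid("fs must exceed twice the notch frequency")
  }
  bw <- spec$notch_freq / spec$notch_q
  edges <- c(spec$notch_freq - bw / 2, spec$notch_freq + bw / 2) / (fs / 2)
  bt <- signal::butter(2, edges, type = "stop")
  as.numeric(signal::filtfilt(bt, x))
}

#' Zero-phase diagnostic band-pass filter
#'
#' Cascade of a second-order Butterworth high-pass at `band_low` and a
#' second-order low-pass at `band_high`, each applied forward-backward
#' (fourth-order zero-phase response overall). The cascade avoids the
#' numerical fragility of a single band-pass design with a very low relative
#' lower edge.
#'
#' @inheritParams notch_filter
#' @return Filtered vector.
#' @export
bandpass_filter <- function(x, fs, spec = filter_spec()) {
  if (spec$band_high >= fs / 2) stop_invalid("band_high must be below fs/2")
  hp <- signal::butter(2, spec$band_low / (fs / 2), type = "high")
  lp <- signal::butter(2, spec$band_high / (fs / 2), type = "low")
  y <- signal::filtfilt(hp, x)
  as.numeric(signal::filtfilt(lp, y))
}

#' Median-filter baseline correction
#'
#' Estimates the baseline by a two-stage running median (200 ms then 600 ms
#' windows) and subtracts it, removing components below about 0.5 Hz.
#' The median estimator is used instead of a plain high-pass because it
#' preserves ST-segment levels, on which the myocardial-infarction signature
#' depends.
#'
#' @param x signal (mV vector), at least 2 s long.
#' @param fs sampling rate (Hz).
#' @return Baseline-corrected vector.
#' @export
baseline_correct <- function(x, fs) {
  if (length(x) < 2 * fs) stop_invalid("baseline_correct needs at least 2 s of signal")
  k1 <- odd_at_least(round(0.2 * fs))
  k2 <- odd_at_least(round(0.6 * fs))
  base <- stats::runmed(stats::runmed(x, k1, endrule = "median"), k2,
                        endrule = "median")
  as.numeric(x - base)
}

#' Segment a signal into fixed-length windows
#'
#' Windows of `window_s` seconds advance by `stride_s`; a trailing partial
#' window is dropped (not padded) so every window has equal length.
#'
#' @param x signal vector.
#' @param fs sampling rate (Hz).
#' @param window_s window length (s).
#' @param stride_s stride (s).
#' @return An object of class `segment_set`: a list with `windows` (matrix,
#'   one row per window), `offsets` (0-based start sample of each window),
#'   `window_s`, `stride_s` and `fs`.
#' @export
segment <- function(x, fs, window_s = 6, stride_s = window_s) {
  if (stride_s <= 0) stop_invalid("stride_s must be positive")
  w <- round(window_s * fs)
  s <- round(stride_s * fs)
  if (length(x) < w) stop_invalid("signal shorter than one window")
  k <- floor((length(x) - w) / s) + 1L
  offsets <- (seq_len(k) - 1L) * s
  windows <- matrix(0, nrow = k, ncol = w)
  for (i in seq_len(k)) windows[i, ] <- x[(offsets[i] + 1):(offsets[i] + w)]
  structure(list(windows = windows, offsets = as.integer(offsets),
                 window_s = window_s, stride_s = stride_s, fs = fs),
            class = "segment_set")
}

#' Per-window z-score normalization
#'
#' Returns the window standardized to mean 0 and (sample) standard deviation
#' 1. A constant window maps to zeros and is marked by the `"constant"`
#' attribute (with a warning).
#'
#' @param x numeric window.
#' @return Normalized vector with attribute `constant` (logical).
#' @export
normalize_window <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    warning("constant window mapped to zeros")
    return(structure(rep(0, length(x)), constant = TRUE))
  }
  structure((x - mean(x)) / s, constant = FALSE)
}

#' Run the full preprocessing chain on a record
#'
#' Fixed order: notch -> band-pass -> baseline correction -> segmentation ->
#' per-window normalization.
#'
#' @param record an `ecg_record`, or a numeric vector (then `fs` is required).
#' @param fs sampling rate, taken from the record when omitted.
#' @param spec a [filter_spec()].
#' @param window_s,stride_s segmentation parameters; the default window is
#'   the full record length (one diagnostic window per record).
#' @return A `segment_set` whose `windows` are normalized; per-window
#'   constant flags are in `$constant`.
#' @export
preprocess_record <- function(record, fs = NULL, spec = filter_spec(),
                              window_s = NULL, stride_s = NULL) {
  if (inherits(record, "ecg_record")) {
    x <- record$samples
    fs <- record$fs
  } else {
    x <- as.numeric(record)
    if (is.null(fs)) stop_invalid("fs is required for a bare signal vector")
  }
  if (is.null(window_s)) window_s <- length(x) / fs
  if (is.null(stride_s)) stride_s <- window_s
  y <- notch_filter(x, fs, spec)
  y <- bandpass_filter(y, fs, spec)
  y <- baseline_correct(y, fs)
  seg <- segment(y, fs, window_s, stride_s)
  flags <- logical(nrow(seg$windows))
  for (i in seq_len(nrow(seg$windows))) {
    nw <- suppressWarnings(normalize_window(seg$windows[i, ]))
    flags[i] <- isTRUE(attr(nw, "constant"))
    seg$windows[i, ] <- nw
  }
  seg$constant <- flags
  seg
}

# Filtered (notch + band-pass + baseline-corrected, NOT normalized) full
# traces, one row per record. Model windows are cropped from these and
# normalized per window.
model_signals <- function(records, spec = filter_spec()) {
  if (inherits(records, "ecg_dataset")) records <- records$records
  if (inherits(records, "ecg_record")) records <- list(records)
  out <- NULL
  for (i in seq_along(records)) {
    r <- records[[i]]
    y <- baseline_correct(bandpass_filter(notch_filter(r$samples, r$fs, spec),
                                          r$fs, spec), r$fs)
    if (is.null(out)) out <- matrix(0, nrow = length(records), ncol = length(y))
    out[i, ] <- y
  }
  out
}

crop_normalize <- function(trace, len, offset) {
  suppressWarnings(normalize_window(trace[(offset + 1):(offset + len)]))
}

# One normalized model-input window per record: the centre `len` samples of
# the filtered trace (the whole trace when `len` is NULL).
model_windows <- function(records, spec = filter_spec(), len = NULL) {
  sig <- model_signals(records, spec)
  if (is.null(len)) len <- ncol(sig)
  if (len > ncol(sig)) stop_invalid("requested window longer than the record")
  offset <- (ncol(sig) - len) %/% 2L
  out <- matrix(0, nrow = nrow(sig), ncol = len)
  for (i in seq_len(nrow(sig))) out[i, ] <- crop_normalize(sig[i, ], len, offset)
  attr(out, "offset") <- offset
  out
}
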