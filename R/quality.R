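# Signal-quality metrics: template SNR, baseline-drift amplitude,
# instantaneous-frequency map, and lag-searched cross-correlation.

#' Template (ensemble-average) signal-to-noise ratio
#'
#' Beats are aligned on their R peaks over a window spanning half the
#' shortest RR interval on each side (capped at 0.6 s), with an integer-lag
#' realignment pass against the ensemble average; the ensemble-average
#' template is taken as the signal estimate and the per-beat residuals as
#' noise: `SNR = 10 log10(n_beats * sum(template^2) / sum(residual^2))`.
#' This definition makes SNR values comparable across runs of this package;
#' it is not calibrated to any particular recording device.
#'
#' @param x signal (mV vector).
#' @param fs sampling rate (Hz).
#' @param rpeaks an `rpeak_set` with at least 5 usable beats.
#' @return SNR in dB.
#' @export
snr <- function(x, fs, rpeaks) {
  idx <- rpeaks$indices + 1L  # 1-based
  if (length(idx) < 5) stop_insufficient("snr needs at least 5 detected beats")
  rr_min <- min(diff(idx))
  maxlag <- round(0.02 * fs)
  # windows tile (almost) the whole beat so that the template/residual power
  # ratio is commensurate with the record-wide signal/noise power ratio
  half <- min(floor(rr_min / 2) - maxlag - 1L, round(0.6 * fs))
  pre <- half; post <- half
  if (pre < 1 || post < 1) stop_insufficient("beats too close for template alignment")
  ok <- idx[idx - pre - maxlag >= 1 & idx + post + maxlag <= length(x)]
  if (length(ok) < 5) stop_insufficient("snr needs at least 5 fully contained beats")
  extract <- function(centers) {
    t(vapply(centers, function(i) x[(i - pre):(i + post)],
             numeric(pre + post + 1)))
  }
  beats <- extract(ok)
  template <- colMeans(beats)
  # integer-lag realignment against the ensemble average: detector jitter of
  # even one sample on the steep QRS slope would otherwise dominate the
  # residual and bias the SNR low
  for (iter in 1:2) {
    lags <- vapply(ok, function(i) {
      sc <- vapply(-maxlag:maxlag, function(l) {
        sum(template * x[(i + l - pre):(i + l + post)])
      }, numeric(1))
      (-maxlag:maxlag)[which.max(sc)]
    }, numeric(1))
    ok <- ok + as.integer(lags)
    beats <- extract(ok)
    template <- colMeans(beats)
  }
  resid <- sweep(beats, 2, template)
  10 * log10(nrow(beats) * sum(template^2) / sum(resid^2))
}

# Brick-wall FFT low-pass: keeps components at or below `cutoff` Hz.
fft_lowpass <- function(x, fs, cutoff) {
  n <- length(x)
  X <- stats::fft(x)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)  # two-sided frequency axis
  X[f > cutoff] <- 0
  Re(stats::fft(X, inverse = TRUE)) / n
}

#' Baseline-drift amplitude
#'
#' Extracts the baseline as the 0.5 Hz low-pass component and reports its
#' total (peak-to-peak) amplitude in units of the detrended signal's
#' peak-to-peak amplitude, i.e. the drift of the normalized trace. The
#' normalization makes the metric scale-invariant: multiplying the record by
#' a constant leaves it unchanged.
#'
#' @param x signal vector, at least 10 s.
#' @param fs sampling rate (Hz).
#' @return Drift amplitude (dimensionless, >= 0).
#' @export
drift_amplitude <- function(x, fs) {
  if (length(x) < 10 * fs) stop_invalid("drift_amplitude needs at least 10 s of signal")
  base <- fft_lowpass(x, fs, 0.5)
  detr <- x - base
  span <- diff(range(detr))
  if (span == 0) return(0)
  diff(range(base - mean(base))) / span
}

#' Short-time instantaneous-frequency map
#'
#' Computes a spectrogram (1 s Hanning window, 75% overlap) and the
#' spectral first-moment ridge
#' `IF(t) = sum(f * |S(f,t)|^2) / sum(|S(f,t)|^2)`, a robust instantaneous-
#' frequency estimate for multi-component signals such as the ECG.
#'
#' @param x signal vector, at least 256 samples and one window long.
#' @param fs sampling rate (Hz).
#' @param window_s analysis window (s).
#' @param overlap fractional window overlap.
#' @return An object of class `tf_map`: `times` (s), `frequencies` (Hz),
#'   `magnitude` (frequency x time matrix of `|S|`), and `ridge`
#'   (instantaneous frequency per frame, Hz).
#' @export
instantaneous_frequency <- function(x, fs, window_s = 1, overlap = 0.75) {
  w <- round(window_s * fs)
  if (length(x) < max(256, w)) stop_invalid("signal too short for time-frequency analysis")
  sp <- signal::specgram(x, n = w, Fs = fs, overlap = round(overlap * w))
  mag <- abs(sp$S)
  p <- mag^2
  ridge <- as.numeric(colSums(sp$f * p) / colSums(p))
  structure(list(times = as.numeric(sp$t), frequencies = as.numeric(sp$f),
                 magnitude = mag, ridge = ridge), class = "tf_map")
}

#' @export
print.tf_map <- function(x, ...) {
  cat(sprintf("<tf_map> %d frames x %d frequencies, ridge %.2f-%.2f Hz\n",
              length(x$times), length(x$frequencies),
              min(x$ridge), max(x$ridge)))
  invisible(x)
}

#' Lag-searched normalized cross-correlation
#'
#' Pearson correlation between `a` and `b[t + lag]` over the overlapping
#' span, maximized in magnitude over lags up to `max_lag`; the signed value
#' at the best lag is reported together with the lag. With `fs` supplied the
#' lag search spans +/- 0.5 s.
#'
#' @param a,b equal-length numeric vectors (non-constant).
#' @param fs optional sampling rate (Hz) setting `max_lag = 0.5 * fs`.
#' @param max_lag maximum |lag| in samples.
#' @return List with `value` (in `[-1, 1]`) and `lag` (samples; positive
#'   means `b` is delayed relative to `a`).
#' @export
xcorr_coefficient <- function(a, b, fs = NULL, max_lag = NULL) {
  n <- length(a)
  if (length(b) != n || n < 2) stop_invalid("a and b must have equal length >= 2")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop(structure(class = c("cardiopatch_undefined_metric", "error", "condition"),
                   list(message = "cross-correlation undefined for constant input",
                        call = sys.call())))
  }
  if (is.null(max_lag)) {
    max_lag <- if (!is.null(fs)) round(0.5 * fs) else n %/% 4
  }
  max_lag <- min(max_lag, n - 8L)
  best <- c(value = -Inf, lag = 0)
  for (lag in -max_lag:max_lag) {
    if (lag >= 0) {
      aa <- a[seq_len(n - lag)]; bb <- b[seq_len(n - lag) + lag]
    } else {
      aa <- a[seq_len(n + lag) - lag]; bb <- b[seq_len(n + lag)]
    }
    if (stats::sd(aa) == 0 || stats::sd(bb) == 0) next
    r <- stats::cor(aa, bb)
    if (abs(r) > abs(best[["value"]]) || !is.finite(best[["value"]])) {
      best <- c(value = r, lag = lag)
    }
  }
  list(value = unname(best[["value"]]), lag = as.integer(best[["lag"]]))
}

#' Quality metrics bundle for a record
#'
#' @param record an `ecg_record`.
#' @param rpeaks optional `rpeak_set`; detected with [pan_tompkins()] when
#'   omitted.
#' @return List with `snr_db`, `drift_amplitude` and, when a clean reference
#'   is available, `xcorr_max` (+ `xcorr_lag`) against it.
#' @export
quality_metrics <- function(record, rpeaks = NULL) {
  if (is.null(rpeaks)) rpeaks <- pan_tompkins(record$samples, record$fs)
  snr_db <- tryCatch(snr(record$samples, record$fs, rpeaks),
                     error = function(e) NA_real_)
  drift <- tryCatch(drift_amplitude(record$samples, record$fs),
                    error = function(e) NA_real_)
  out <- list(snr_db = snr_db, drift_amplitude = drift,
              xcorr_max = NA_real_, xcorr_lag = NA_integer_)
  if (!is.null(record$clean_samples) &&
      stats::sd(record$clean_samples) > 0 && stats::sd(record$samples) > 0) {
    xc <- xcorr_coefficient(record$clean_samples, record$samples, fs = record$fs)
    out$xcorr_max <- xc$value
    out$xcorr_lag <- xc$lag
  }
  out
}
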