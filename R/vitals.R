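# Pan-Tompkins QRS detection and heart-rate / heart-rate-variability
# reporting on 6-second update windows.

#' Pan-Tompkins QRS detector
#'
#' Classic adaptive-threshold formulation: 5-15 Hz band-pass, five-point
#' derivative, squaring, 150 ms moving-window integration, dual adaptive
#' thresholds with signal/noise peak tracking (update coefficients
#' 0.125/0.25), a 200 ms refractory period, a T-wave slope check for
#' candidates within 360 ms, and search-back at 1.66 times the running mean
#' RR using the halved threshold. All stages are zero-phase, and accepted
#' detections are refined to the local maximum of the raw signal within
#' +/- 50 ms.
#'
#' @param x signal (mV vector), at least 2 s.
#' @param fs sampling rate (Hz, >= 100).
#' @param integration_ms moving-window integration length (ms).
#' @param refractory_ms refractory period (ms).
#' @param learn_s initial threshold-learning span (s).
#' @return An object of class `rpeak_set`: `indices` (0-based sample indices,
#'   strictly increasing, separated by at least the refractory period), `fs`,
#'   `n_samples`, and `thresholds` (the running threshold trace, in units of
#'   the integrated signal).
#' @examples
#' rec <- generate_record(rhythm = rhythm_model(60, 0), duration = 10, seed = 1)
#' pan_tompkins(rec$samples, rec$fs)$indices
#' @export
pan_tompkins <- function(x, fs, integration_ms = 150, refractory_ms = 200,
                         learn_s = 2) {
  if (fs < 100) stop_invalid("fs must be at least 100 Hz")
  n <- length(x)
  if (n < 2 * fs) stop_invalid("pan_tompkins needs at least 2 s of signal")
  empty <- structure(list(indices = integer(0), fs = fs, n_samples = n,
                          thresholds = numeric(0)), class = "rpeak_set")
  if (all(x == x[1])) return(empty)

  bp <- signal::butter(2, c(5, 15) / (fs / 2), type = "pass")
  xf <- as.numeric(signal::filtfilt(bp, x))
  # centred five-point derivative (zero-phase)
  d <- numeric(n)
  d[3:(n - 2)] <- (-xf[1:(n - 4)] - 2 * xf[2:(n - 3)] +
                     2 * xf[4:(n - 1)] + xf[5:n]) / 8
  sq <- d^2
  w <- max(3L, round(integration_ms / 1000 * fs))
  integ <- as.numeric(stats::filter(sq, rep(1 / w, w), sides = 2))
  integ[is.na(integ)] <- 0

  # candidate peaks: local maxima of the integrated signal, pruned to a
  # minimum separation of one refractory period (ripple on a single QRS
  # integration bump otherwise yields spurious rising-edge candidates)
  cand <- which(integ[2:(n - 1)] > integ[1:(n - 2)] &
                  integ[2:(n - 1)] >= integ[3:n]) + 1L
  if (!length(cand)) return(empty)
  refr <- round(refractory_ms / 1000 * fs)
  ord <- cand[order(integ[cand], decreasing = TRUE)]
  sel <- integer(0)
  for (i in ord) {
    if (!length(sel) || min(abs(sel - i)) >= refr) sel <- c(sel, i)
  }
  cand <- sort(sel)
  twin <- round(0.36 * fs)

  learn_n <- min(n, round(learn_s * fs))
  spki <- max(integ[seq_len(learn_n)]) * 0.5
  npki <- mean(integ[seq_len(learn_n)]) * 0.5
  thr_trace <- numeric(length(cand))

  # peak slope (max derivative magnitude near the peak) for the T-wave rule
  slope_at <- function(i) {
    lo <- max(1L, i - round(0.075 * fs)); hi <- min(n, i + round(0.075 * fs))
    max(abs(d[lo:hi]))
  }

  accepted <- integer(0)
  acc_slope <- numeric(0)
  last_scan <- 0L  # candidate index already covered by search-back
  for (ci in seq_along(cand)) {
    i <- cand[ci]
    thr1 <- npki + 0.25 * (spki - npki)
    thr_trace[ci] <- thr1
    pk <- integ[i]
    is_beat <- FALSE
    if (length(accepted) && (i - accepted[length(accepted)]) < refr) {
      next  # inside refractory: ignore entirely
    }
    if (pk > thr1) {
      is_beat <- TRUE
      if (length(accepted) && (i - accepted[length(accepted)]) < twin) {
        # possible T wave: reject if slope less than half the previous QRS slope
        if (slope_at(i) < 0.5 * acc_slope[length(acc_slope)]) is_beat <- FALSE
      }
    }
    if (is_beat) {
      accepted <- c(accepted, i)
      acc_slope <- c(acc_slope, slope_at(i))
      spki <- 0.125 * pk + 0.875 * spki
      last_scan <- ci
    } else {
      npki <- 0.125 * pk + 0.875 * npki
      # search-back when the gap since the last beat exceeds 1.66 * mean RR
      if (length(accepted) >= 2) {
        rr_avg <- mean(diff(utils::tail(accepted, 9)))
        if ((i - accepted[length(accepted)]) > 1.66 * rr_avg) {
          back <- cand[cand > accepted[length(accepted)] + refr & cand < i]
          back <- back[integ[back] > 0.5 * thr1]
          if (length(back)) {
            j <- back[which.max(integ[back])]
            accepted <- c(accepted, j)
            acc_slope <- c(acc_slope, slope_at(j))
            spki <- 0.25 * integ[j] + 0.75 * spki
          }
        }
      }
    }
  }
  if (!length(accepted)) return(empty)

  # refine to the local maximum of the raw signal within +/- 50 ms
  half <- as.integer(round(0.05 * fs))
  refined <- vapply(accepted, function(i) {
    lo <- max(1L, as.integer(i) - half); hi <- min(n, as.integer(i) + half)
    lo + which.max(x[lo:hi]) - 1L
  }, integer(1))
  refined <- sort(unique(refined))
  # enforce the refractory period on the refined indices (keep larger peak)
  if (length(refined) > 1) {
    keep <- refined[1]
    for (i in refined[-1]) {
      if (i - keep[length(keep)] >= refr) {
        keep <- c(keep, i)
      } else if (x[i] > x[keep[length(keep)]]) {
        keep[length(keep)] <- i
      }
    }
    refined <- keep
  }
  structure(list(indices = as.integer(refined - 1L), fs = fs, n_samples = n,
                 thresholds = thr_trace), class = "rpeak_set")
}

#' Build an `rpeak_set` from known peak indices
#'
#' @param indices 0-based sample indices (strictly increasing).
#' @param fs sampling rate (Hz).
#' @param n_samples signal length (samples); defaults to just past the last peak.
#' @return An `rpeak_set`.
#' @export
rpeak_set <- function(indices, fs, n_samples = max(indices) + 1L) {
  indices <- as.integer(indices)
  if (is.unsorted(indices, strictly = TRUE)) stop_invalid("indices must be strictly increasing")
  structure(list(indices = indices, fs = fs, n_samples = n_samples,
                 thresholds = numeric(0)), class = "rpeak_set")
}

#' @export
print.rpeak_set <- function(x, ...) {
  cat(sprintf("<rpeak_set> %d peaks @ %g Hz over %.1f s\n",
              length(x$indices), x$fs, x$n_samples / x$fs))
  invisible(x)
}

#' Per-window heart rate from detected R peaks
#'
#' Heart rate in a window is `60 / mean(RR)` over the RR intervals whose
#' midpoint falls inside the window (mean-RR rather than peak counting, which
#' is the stabler estimator for short windows). Windows containing no RR
#' midpoint are flagged missing.
#'
#' @param rpeaks an `rpeak_set`.
#' @param window_s window length (s, default 6 to match the reporting cadence).
#' @param duration total duration (s); defaults to the signal span.
#' @return A data frame with one row per window: `window`, `t_start`,
#'   `t_end`, `n_rr`, `hr_bpm`, `missing`.
#' @export
heart_rate <- function(rpeaks, window_s = 6, duration = NULL) {
  if (window_s <= 0) stop_invalid("window_s must be positive")
  if (is.null(duration)) duration <- rpeaks$n_samples / rpeaks$fs
  k <- max(1L, floor(duration / window_s))
  tpk <- rpeaks$indices / rpeaks$fs
  rr <- diff(tpk)
  mid <- (tpk[-length(tpk)] + tpk[-1]) / 2
  out <- data.frame(window = seq_len(k),
                    t_start = (seq_len(k) - 1) * window_s,
                    t_end = seq_len(k) * window_s,
                    n_rr = 0L, hr_bpm = NA_real_, missing = TRUE)
  for (i in seq_len(k)) {
    sel <- which(mid >= out$t_start[i] & mid < out$t_end[i])
    out$n_rr[i] <- length(sel)
    if (length(sel)) {
      out$hr_bpm[i] <- 60 / mean(rr[sel])
      out$missing[i] <- FALSE
    }
  }
  out
}

#' Time-domain HRV statistics from an RR-interval vector
#'
#' `sdnn` is the population standard deviation of the RR intervals (ms),
#' `rmssd` the root mean square of successive differences (ms), and `pnn50`
#' the percentage of successive differences exceeding 50 ms.
#'
#' @param rr_ms RR intervals in milliseconds (length >= 2).
#' @return Named list with `sdnn`, `rmssd`, `pnn50`.
#' @export
hrv_from_rr <- function(rr_ms) {
  if (length(rr_ms) < 2) stop_insufficient("need at least 2 RR intervals")
  dd <- diff(rr_ms)
  list(sdnn = sqrt(mean((rr_ms - mean(rr_ms))^2)),
       rmssd = sqrt(mean(dd^2)),
       pnn50 = 100 * mean(abs(dd) > 50))
}

#' Vitals report: heart rate and HRV over 6-second windows
#'
#' @param rpeaks an `rpeak_set` with at least 3 peaks.
#' @param window_s reporting window (s, default 6).
#' @param duration total duration (s); defaults to the signal span.
#' @return An object of class `vitals_report`: per-window heart-rate table
#'   (`$windows`), `sdnn`, `rmssd`, `pnn50` (ms / percent), `hr_min`,
#'   `hr_max` (bpm over non-missing windows), `window_s`.
#' @export
hrv_metrics <- function(rpeaks, window_s = 6, duration = NULL) {
  if (length(rpeaks$indices) < 3) stop_insufficient("need at least 3 R peaks")
  rr_ms <- diff(rpeaks$indices) / rpeaks$fs * 1000
  h <- hrv_from_rr(rr_ms)
  win <- heart_rate(rpeaks, window_s, duration)
  hr_ok <- win$hr_bpm[!win$missing]
  structure(list(windows = win, sdnn = h$sdnn, rmssd = h$rmssd,
                 pnn50 = h$pnn50,
                 hr_min = if (length(hr_ok)) min(hr_ok) else NA_real_,
                 hr_max = if (length(hr_ok)) max(hr_ok) else NA_real_,
                 window_s = window_s, n_beats = length(rpeaks$indices)),
            class = "vitals_report")
}

#' @export
print.vitals_report <- function(x, ...) {
  cat(sprintf("<vitals_report> %d beats | HR %.1f-%.1f bpm | SDNN %.1f ms | RMSSD %.1f ms | pNN50 %.1f%%\n",
              x$n_beats, x$hr_min, x$hr_max, x$sdnn, x$rmssd, x$pnn50))
  invisible(x)
}

# Match detected peaks against ground truth within a tolerance (s).
# Returns sensitivity, positive predictive value and counts.
match_rpeaks <- function(detected, truth, fs, tol_s = 0.05) {
  tol <- tol_s * fs
  used <- logical(length(detected))
  tp <- 0L
  for (g in truth) {
    d <- abs(detected - g)
    ok <- which(!used & d <= tol)
    if (length(ok)) {
      used[ok[which.min(d[ok])]] <- TRUE
      tp <- tp + 1L
    }
  }
  fn <- length(truth) - tp
  fp <- length(detected) - tp
  list(sensitivity = if (length(truth)) tp / (tp + fn) else NA_real_,
       ppv = if (length(detected)) tp / (tp + fp) else NA_real_,
       tp = tp, fp = fp, fn = fn)
}
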