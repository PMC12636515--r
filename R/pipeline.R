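# End-to-end orchestration mirroring the app's four sections: real-time ECG
# (streamed vitals), heart-rate data, wearing-position correction, and
# health assessment.

#' Run the full analysis pipeline on one record
#'
#' Order: position check first (a misplaced patch flags the diagnosis as
#' position-compromised, but the diagnosis is still emitted), then vitals
#' (Pan-Tompkins on the notch-filtered, baseline-corrected trace), quality
#' metrics, and the IAT classification with attention saliency.
#'
#' @param record an `ecg_record`.
#' @param iat_model a fitted [iat_fit()] model.
#' @param position_model a fitted [position_fit()] model.
#' @param window_s vitals reporting window (s).
#' @param spec the [filter_spec()] for preprocessing.
#' @return An object of class `health_report` with sections `position`,
#'   `vitals`, `quality`, `diagnosis` (probabilities, predicted label,
#'   top-3 high-attention spans, `position_compromised` flag) and a
#'   `provenance` block (seeds, configs, schema version) sufficient to
#'   reproduce every numeric field.
#' @export
run_report <- function(record, iat_model, position_model, window_s = 6,
                       spec = filter_spec()) {
  if (!inherits(iat_model, "iat_model") ||
      !inherits(position_model, "position_model")) {
    stop(structure(class = c("cardiopatch_model_not_ready", "error", "condition"),
                   list(message = "trained iat_model and position_model are required",
                        call = sys.call())))
  }
  pos <- assess_position(position_model, record)
  y <- baseline_correct(notch_filter(record$samples, record$fs, spec), record$fs)
  pk <- pan_tompkins(y, record$fs)
  vit <- tryCatch(hrv_metrics(pk, window_s = window_s),
                  error = function(e) NULL)
  qual <- quality_metrics(record, pk)
  probs <- predict(iat_model, record, type = "prob")[1, ]
  sal <- iat_saliency(iat_model, record)
  top <- order(sal$token_scores, decreasing = TRUE)[1:3]
  structure(list(
    record_id = paste0("rec-", record$seed),
    position = unclass(pos),
    vitals = if (is.null(vit)) list(available = FALSE) else list(
      available = TRUE, window_s = vit$window_s,
      hr_bpm = vit$windows$hr_bpm, missing = vit$windows$missing,
      sdnn = vit$sdnn, rmssd = vit$rmssd, pnn50 = vit$pnn50,
      hr_min = vit$hr_min, hr_max = vit$hr_max),
    quality = qual,
    diagnosis = list(
      probabilities = as.list(probs),
      predicted = iat_model$classes[which.max(probs)],
      top_attention_spans = sal$spans[top, , drop = FALSE],
      position_compromised = !isTRUE(pos$within_tolerance)),
    provenance = list(
      schema_version = "1.0",
      record_seed = record$seed,
      class_label = record$class_label,
      orientation_label = record$orientation_label,
      fs = record$fs,
      window_s = window_s,
      iat_seed = iat_model$config$seed,
      position_seed = position_model$config$seed,
      filter = unclass(spec))),
    class = "health_report")
}

#' @export
print.health_report <- function(x, ...) {
  cat(sprintf("<health_report> %s\n", x$record_id))
  cat(sprintf("  position: %s (%s, discriminator %.3f)\n",
              x$position$orientation,
              if (isTRUE(x$position$within_tolerance)) "within tolerance" else "misplaced",
              x$position$discriminator_score))
  if (isTRUE(x$vitals$available)) {
    cat(sprintf("  vitals: HR %.1f-%.1f bpm | SDNN %.1f ms | RMSSD %.1f ms | pNN50 %.1f%%\n",
                x$vitals$hr_min, x$vitals$hr_max, x$vitals$sdnn,
                x$vitals$rmssd, x$vitals$pnn50))
  } else cat("  vitals: unavailable (too few beats)\n")
  cat(sprintf("  quality: SNR %.1f dB | drift %.4f | xcorr vs clean %.3f\n",
              x$quality$snr_db, x$quality$drift_amplitude, x$quality$xcorr_max))
  cat(sprintf("  diagnosis: %s (p = %.2f)%s\n", x$diagnosis$predicted,
              max(unlist(x$diagnosis$probabilities)),
              if (x$diagnosis$position_compromised) " [position-compromised]" else ""))
  invisible(x)
}

#' Serialize a health report as JSON
#'
#' @param report a `health_report`.
#' @param path optional output path; when `NULL` the JSON string is
#'   returned.
#' @return JSON string (invisibly, when written to a file).
#' @export
report_json <- function(report, path = NULL) {
  js <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = NA,
                         na = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Streamed vitals updates at a fixed cadence
#'
#' Emits one update per window (heart rate for the window plus the running
#' HRV statistics over all beats seen so far). Detection runs on the full
#' record so that emitted windows are identical to the batch segmentation —
#' the stream reproduces the app's update cadence, and its final accumulated
#' state equals the batch [hrv_metrics()] report exactly.
#'
#' @param record an `ecg_record` longer than one window.
#' @param window_s update cadence (s, default 6).
#' @return An object of class `vitals_stream`: `updates` (list of per-window
#'   lists) and `final` (the batch `vitals_report`).
#' @export
stream_vitals <- function(record, window_s = 6) {
  dur <- length(record$samples) / record$fs
  if (dur < window_s) stop_insufficient("record shorter than one window")
  y <- baseline_correct(notch_filter(record$samples, record$fs), record$fs)
  pk <- pan_tompkins(y, record$fs)
  final <- hrv_metrics(pk, window_s = window_s, duration = dur)
  k <- nrow(final$windows)
  updates <- vector("list", k)
  for (i in seq_len(k)) {
    upto <- pk$indices[pk$indices < final$windows$t_end[i] * record$fs]
    run <- if (length(upto) >= 3) {
      hrv_from_rr(diff(upto) / record$fs * 1000)
    } else list(sdnn = NA_real_, rmssd = NA_real_, pnn50 = NA_real_)
    updates[[i]] <- list(window = i,
                         t_end = final$windows$t_end[i],
                         hr_bpm = final$windows$hr_bpm[i],
                         missing = final$windows$missing[i],
                         n_beats = length(upto),
                         sdnn = run$sdnn, rmssd = run$rmssd,
                         pnn50 = run$pnn50)
  }
  structure(list(updates = updates, final = final, window_s = window_s),
            class = "vitals_stream")
}

#' @export
print.vitals_stream <- function(x, ...) {
  cat(sprintf("<vitals_stream> %d updates every %g s\n", length(x$updates),
              x$window_s))
  print(x$final)
  invisible(x)
}

#' Offline template health advice
#'
#' A pluggable text-advice interface standing where an external
#' conversational service would sit; this backend is a fixed offline
#' template keyed on the predicted class and position flag (no network
#' access).
#'
#' @param report a `health_report`.
#' @return Character advice text.
#' @export
health_advice <- function(report) {
  base <- switch(report$diagnosis$predicted,
    NR = "Rhythm and waveform appear normal. Keep monitoring regularly.",
    AR = "Irregular R-R intervals detected, consistent with arrhythmia. Consider a clinical ECG review.",
    AH = "P-wave morphology changes suggest atrial hypertrophy. A cardiology follow-up is advisable.",
    MI = "ST-segment deviation detected, a myocardial-infarction signature. Seek medical attention promptly.",
    "Unrecognized classification result.")
  if (report$diagnosis$position_compromised) {
    base <- paste(base,
                  sprintf("Note: the patch appears misplaced (suggested rotation %+d degrees); re-seat it and re-record before acting on this result.",
                          as.integer(report$position$adjustment_deg)))
  }
  base
}
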