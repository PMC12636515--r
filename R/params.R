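# Parameter containers for the synthetic ECG generator.

WAVE_NAMES <- c("P", "Q", "R", "S", "T")
CLASS_LEVELS <- c("NR", "AR", "AH", "MI")
ORIENTATION_LEVELS <- c("O0", "O120", "O240")

#' Morphology parameters of one synthetic heartbeat
#'
#' Each of the five canonical deflections (P, Q, R, S, T) is a Gaussian bump
#' on the beat phase \eqn{\phi \in (-\pi, \pi]} with the R peak at phase zero:
#' the clean beat is \eqn{\sum_w a_w \exp(-(\phi - \theta_w)^2 / (2 b_w^2))}.
#' Defaults approximate an upright lead-II-like morphology with a PR interval
#' of about 160 ms and a T peak about 270 ms after R at 60 bpm.
#'
#' @param theta named numeric vector of angular positions (radians, strictly
#'   increasing over P, Q, R, S, T; R at 0).
#' @param amp named numeric vector of amplitudes (mV; R must be positive).
#' @param width named numeric vector of Gaussian widths (radians, all > 0).
#' @return An object of class `wave_params`.
#' @examples
#' w <- wave_params()
#' w$amp["R"]
#' @export
wave_params <- function(theta = c(P = -1.0, Q = -0.15, R = 0, S = 0.15, T = 1.7),
                        amp = c(P = 0.12, Q = -0.10, R = 1.0, S = -0.15, T = 0.30),
                        width = c(P = 0.20, Q = 0.08, R = 0.10, S = 0.08, T = 0.35)) {
  theta <- theta[WAVE_NAMES]; amp <- amp[WAVE_NAMES]; width <- width[WAVE_NAMES]
  if (anyNA(theta) || anyNA(amp) || anyNA(width)) {
    stop_invalid("wave_params needs named entries for P, Q, R, S, T")
  }
  if (any(width <= 0)) stop_invalid("all wave widths must be > 0")
  if (any(diff(theta) <= 0)) stop_invalid("wave angles must satisfy P < Q < R < S < T")
  if (amp[["R"]] <= 0) stop_invalid("R amplitude must be positive")
  if (any(theta <= -pi) || any(theta > pi)) stop_invalid("wave angles must lie in (-pi, pi]")
  structure(list(theta = theta, amp = amp, width = width), class = "wave_params")
}

#' Beat-to-beat rhythm model
#'
#' RR intervals are drawn as `60/mean_hr` seconds with standard deviation
#' `60 * hr_sd / mean_hr^2` (the bpm-equivalent spread mapped to the RR
#' domain), optionally modulated by a respiratory sinusoid.
#'
#' @param mean_hr mean heart rate (bpm, in [20, 240]).
#' @param hr_sd heart-rate standard deviation (bpm, >= 0).
#' @param resp_freq respiratory modulation frequency (Hz).
#' @param resp_depth respiratory modulation depth (dimensionless, in [0, 1)).
#'   The default 0 disables modulation so that a zero `hr_sd` yields exactly
#'   periodic beats.
#' @return An object of class `rhythm_model`.
#' @export
rhythm_model <- function(mean_hr = 70, hr_sd = 2, resp_freq = 0.25, resp_depth = 0) {
  check_scalar(mean_hr, "mean_hr", 20, 240)
  check_scalar(hr_sd, "hr_sd", 0)
  check_scalar(resp_freq, "resp_freq", 0)
  check_scalar(resp_depth, "resp_depth", 0, 1 - 1e-12)
  structure(list(mean_hr = mean_hr, hr_sd = hr_sd,
                 resp_freq = resp_freq, resp_depth = resp_depth),
            class = "rhythm_model")
}

#' Pathology profile for a synthetic record
#'
#' The three disease classes mirror the textbook waveform signatures: ST-segment
#' shift for myocardial infarction (MI), RR-interval irregularity with
#' premature (ectopic) beats for arrhythmia (AR), and enlarged/widened P waves
#' for atrial hypertrophy (AH). `NR` is the identity profile.
#'
#' @param label one of `"NR"`, `"AR"`, `"AH"`, `"MI"`.
#' @param st_shift ST-segment offset in mV (MI only).
#' @param rr_irregularity_factor multiplier (>= 1) on the RR standard deviation
#'   (AR only).
#' @param ectopic_prob per-beat probability of a premature beat (AR only).
#' @param p_amp_scale P-wave amplitude scale (> 1, AH only).
#' @param p_width_scale P-wave width scale (> 1, AH only).
#' @return An object of class `pathology_profile`.
#' @export
pathology_profile <- function(label = c("NR", "AR", "AH", "MI"),
                              st_shift = 0.2,
                              rr_irregularity_factor = 4,
                              ectopic_prob = 0.1,
                              p_amp_scale = 2,
                              p_width_scale = 1.5) {
  label <- match.arg(label)
  prof <- list(label = label, st_shift = 0, rr_irregularity_factor = 1,
               ectopic_prob = 0, p_amp_scale = 1, p_width_scale = 1)
  if (label == "MI") {
    check_scalar(st_shift, "st_shift")
    prof$st_shift <- st_shift
  } else if (label == "AR") {
    check_scalar(rr_irregularity_factor, "rr_irregularity_factor", 1)
    check_scalar(ectopic_prob, "ectopic_prob", 0, 1)
    prof$rr_irregularity_factor <- rr_irregularity_factor
    prof$ectopic_prob <- ectopic_prob
  } else if (label == "AH") {
    check_scalar(p_amp_scale, "p_amp_scale", 1)
    check_scalar(p_width_scale, "p_width_scale", 1)
    prof$p_amp_scale <- p_amp_scale
    prof$p_width_scale <- p_width_scale
  }
  structure(prof, class = "pathology_profile")
}

# Fixed distortion parameters of the three stable placements of the
# 120-degree-symmetric triangular patch. O0 is the identity.
POSITION_TABLE <- list(
  O0   = list(amplitude_scale = 1.0, polarity = 1,  baseline_offset = 0.0,  morphology_mix = 0.0),
  O120 = list(amplitude_scale = 0.6, polarity = -1, baseline_offset = 0.1,  morphology_mix = 0.3),
  O240 = list(amplitude_scale = 0.7, polarity = 1,  baseline_offset = -0.1, morphology_mix = 0.5)
)

# Per-wave amplitude re-weighting used by the morphology warp component of the
# misplacement transform.
WARP_WEIGHTS <- c(P = 1.5, Q = 0.5, R = 0.8, S = 2.0, T = 0.6)

#' Patch wear-position (orientation) model
#'
#' The triangular patch admits three stable placements 120 degrees apart.
#' Misplacement distorts the trace through an affine component (amplitude
#' scale, polarity flip, baseline offset) mixed with a morphology warp that
#' re-weights the per-wave amplitudes. `O0` maps to the identity transform.
#'
#' @param orientation `"O0"`, `"O120"` or `"O240"`.
#' @param amplitude_scale,polarity,baseline_offset,morphology_mix optional
#'   overrides of the built-in transform parameters.
#' @return An object of class `position_model`.
#' @export
position_model <- function(orientation = c("O0", "O120", "O240"),
                           amplitude_scale = NULL, polarity = NULL,
                           baseline_offset = NULL, morphology_mix = NULL) {
  orientation <- match.arg(orientation)
  p <- POSITION_TABLE[[orientation]]
  if (!is.null(amplitude_scale)) p$amplitude_scale <- check_scalar(amplitude_scale, "amplitude_scale", 1e-6)
  if (!is.null(polarity)) {
    if (!polarity %in% c(-1, 1)) stop_invalid("polarity must be +1 or -1")
    p$polarity <- polarity
  }
  if (!is.null(baseline_offset)) p$baseline_offset <- check_scalar(baseline_offset, "baseline_offset")
  if (!is.null(morphology_mix)) p$morphology_mix <- check_scalar(morphology_mix, "morphology_mix", 0, 1 - 1e-9)
  if (orientation == "O0" &&
      (p$amplitude_scale != 1 || p$polarity != 1 ||
       p$baseline_offset != 0 || p$morphology_mix != 0)) {
    stop_invalid("O0 must be the identity transform")
  }
  structure(c(list(orientation = orientation), p), class = "position_model")
}

#' Additive noise model
#'
#' Noise is the sum of a baseline-wander sinusoid, a power-line sinusoid
#' (50 Hz by default, matching mains interference), white broadband noise,
#' and Poisson-timed motion-artifact bursts with Gaussian envelopes.
#'
#' @param wander_freq baseline wander frequency (Hz).
#' @param wander_amp baseline wander amplitude (mV).
#' @param powerline_freq power-line frequency (Hz, default 50).
#' @param powerline_amp power-line amplitude (mV).
#' @param broadband_sd white-noise standard deviation (mV).
#' @param burst_rate motion-burst rate (events per minute).
#' @param burst_amp motion-burst peak amplitude (mV).
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(wander_freq = 0.3, wander_amp = 0.15,
                        powerline_freq = 50, powerline_amp = 0.05,
                        broadband_sd = 0.03,
                        burst_rate = 1, burst_amp = 0.2) {
  check_scalar(wander_freq, "wander_freq", 0)
  check_scalar(wander_amp, "wander_amp", 0)
  check_scalar(powerline_freq, "powerline_freq", 0)
  check_scalar(powerline_amp, "powerline_amp", 0)
  check_scalar(broadband_sd, "broadband_sd", 0)
  check_scalar(burst_rate, "burst_rate", 0)
  check_scalar(burst_amp, "burst_amp", 0)
  structure(list(wander_freq = wander_freq, wander_amp = wander_amp,
                 powerline_freq = powerline_freq, powerline_amp = powerline_amp,
                 broadband_sd = broadband_sd, burst_rate = burst_rate,
                 burst_amp = burst_amp),
            class = "noise_model")
}

#' Silent noise model (all components zero)
#' @return A `noise_model` whose components are all zero.
#' @export
no_noise <- function() {
  noise_model(wander_amp = 0, powerline_amp = 0, broadband_sd = 0,
              burst_rate = 0, burst_amp = 0)
}
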