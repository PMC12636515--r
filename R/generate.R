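# Synthetic single-lead ECG generation.
#
# A record is synthesized beat-by-beat on a phase variable: RR intervals are
# drawn from the rhythm model, each beat spans phase (-pi, pi] with the R peak
# at phase zero, and the clean trace is the sum of five Gaussian deflections
# (P, Q, R, S, T). Fiducial spans (P wave, QRS, ST segment, T wave) follow
# analytically from the wave parameters, which is what makes ground-truth
# labels exact.

# Fiducial phase boundaries for a beat, derived from wave positions/widths.
fiducial_phases <- function(wave) {
  th <- wave$theta; b <- wave$width
  p_on    <- th[["P"]] - 2.5 * b[["P"]]
  p_off   <- th[["P"]] + 2.5 * b[["P"]]
  qrs_on  <- th[["Q"]] - 2.5 * b[["Q"]]
  qrs_off <- th[["S"]] + 2.5 * b[["S"]]
  st_on   <- qrs_off
  st_off  <- max(st_on + 0.05, th[["T"]] - 2 * b[["T"]])
  t_off   <- th[["T"]] + 2 * b[["T"]]
  c(p_on = p_on, p_off = p_off, qrs_on = qrs_on, qrs_off = qrs_off,
    st_on = st_on, st_off = st_off, t_off = t_off)
}

# Core synthesis from a fixed RR sequence. Consecutive R peaks are separated
# by exactly the drawn RR intervals (r_1 = rr_1/2, r_i = r_{i-1} + rr_i);
# each sample belongs to the beat whose R peak is nearest (midpoint
# boundaries) and gets phase 2*pi*(t - r_j)/rr_j, wrapped to (-pi, pi].
# Returns the clean trace plus exact ground truth. All indices are 0-based;
# fiducial spans are half-open.
synth_from_rr <- function(wave, rr, fs, n_samples, ectopic_idx = integer(0)) {
  stopifnot(length(rr) >= 1, all(rr > 0))
  r_times <- rr[1] / 2 + c(0, cumsum(rr[-1]))
  if (r_times[length(r_times)] < n_samples / fs) {
    stop_invalid("RR sequence does not cover the requested duration")
  }
  t <- (seq_len(n_samples) - 1) / fs
  mids <- (r_times[-length(r_times)] + r_times[-1]) / 2
  j <- findInterval(t, mids) + 1L
  phi <- 2 * pi * (t - r_times[j]) / rr[j]
  phi <- ((phi + pi) %% (2 * pi)) - pi
  # ectopic (premature) beats carry the textbook morphology: absent P wave,
  # widened QRS, damped T
  nb <- length(rr)
  amp_scale <- list(P = rep(1, nb), Q = rep(1, nb), R = rep(1, nb),
                    S = rep(1, nb), T = rep(1, nb))
  wid_scale <- list(P = rep(1, nb), Q = rep(1, nb), R = rep(1, nb),
                    S = rep(1, nb), T = rep(1, nb))
  if (length(ectopic_idx)) {
    ect <- ectopic_idx[ectopic_idx >= 1 & ectopic_idx <= nb]
    amp_scale$P[ect] <- 0
    amp_scale$T[ect] <- 0.8
    for (w in c("Q", "R", "S")) wid_scale[[w]][ect] <- 1.6
  }
  clean <- numeric(n_samples)
  for (w in WAVE_NAMES) {
    d <- phi - wave$theta[[w]]
    d <- ((d + pi) %% (2 * pi)) - pi
    aw <- wave$amp[[w]] * amp_scale[[w]][j]
    bw <- wave$width[[w]] * wid_scale[[w]][j]
    clean <- clean + aw * exp(-d^2 / (2 * bw^2))
  }
  rpeak_all <- floor(r_times * fs + 0.5)  # half-up: avoids banker's-rounding jitter
  keep <- which(rpeak_all >= 0 & rpeak_all <= n_samples - 1)
  fph <- fiducial_phases(wave)
  fid <- matrix(0L, nrow = length(keep), ncol = length(fph),
                dimnames = list(NULL, names(fph)))
  for (k in seq_along(keep)) {
    i <- keep[k]
    idx <- floor((r_times[i] + fph * rr[i] / (2 * pi)) * fs + 0.5)
    fid[k, ] <- as.integer(pmin(pmax(idx, 0L), n_samples - 1L))
  }
  fiducials <- as.data.frame(fid)
  fiducials$beat <- seq_along(keep)
  list(clean = clean, rpeaks = as.integer(rpeak_all[keep]),
       fiducials = fiducials, r_times = r_times[keep])
}

apply_st_shift <- function(x, fiducials, st_shift) {
  if (st_shift == 0) return(x)
  for (k in seq_len(nrow(fiducials))) {
    on <- fiducials$st_on[k]; off <- fiducials$st_off[k]
    if (off > on) x[(on + 1):off] <- x[(on + 1):off] + st_shift  # [on, off), 0-based
  }
  x
}

new_record <- function(samples, fs, clean, rpeaks, fiducials, class_label,
                       orientation_label, seed, gen) {
  structure(list(samples = samples, fs = fs, clean_samples = clean,
                 rpeaks = rpeaks, fiducials = fiducials,
                 class_label = class_label, orientation_label = orientation_label,
                 seed = seed, gen = gen),
            class = "ecg_record")
}

# Rebuild the record's noise-free trace from its stored generation state
# (wave parameters, RR sequence, ST shift). Used for the morphology warp and
# for exact position-transform inversion.
resynth_clean <- function(record, wave = record$gen$wave) {
  s <- synth_from_rr(wave, record$gen$rr, record$fs, length(record$samples),
                     ectopic_idx = record$gen$ectopics)
  s$clean <- apply_st_shift(s$clean, s$fiducials, record$gen$st_shift)
  s
}

warp_signal <- function(record) {
  wave <- record$gen$wave
  wave$amp <- wave$amp * WARP_WEIGHTS[WAVE_NAMES]
  resynth_clean(record, wave = wave)$clean
}

#' Generate a synthetic single-lead ECG record
#'
#' Draws an RR sequence from the rhythm model and synthesizes the clean
#' waveform as a sum of Gaussian deflections on the beat phase. The returned
#' record carries exact ground truth: R-peak sample indices (each at the
#' phase-zero maximum of its beat), per-beat fiducial spans (P wave, QRS
#' complex, ST segment, T wave; half-open, 0-based), the class and
#' orientation labels, and the clean reference trace (`clean_samples ==
#' samples` until noise is added).
#'
#' @param wave a [wave_params()] object.
#' @param rhythm a [rhythm_model()] object.
#' @param fs sampling rate (Hz, >= 100).
#' @param duration record length (s); must cover at least 2 beats.
#' @param seed integer seed; records are deterministic given the seed.
#' @return An object of class `ecg_record`.
#' @examples
#' rec <- generate_record(rhythm = rhythm_model(60, 0), duration = 10, seed = 1)
#' diff(rec$rpeaks)  # exactly 250 samples at 250 Hz
#' @export
generate_record <- function(wave = wave_params(), rhythm = rhythm_model(),
                            fs = 250, duration = 10, seed = 1) {
  if (!inherits(wave, "wave_params")) stop_invalid("wave must be a wave_params object")
  if (!inherits(rhythm, "rhythm_model")) stop_invalid("rhythm must be a rhythm_model object")
  check_scalar(fs, "fs", 100)
  if (!is.numeric(duration) || duration <= 0) stop_invalid("duration must be positive")
  if (duration < 2 * 60 / rhythm$mean_hr) {
    stop_invalid("duration must cover at least 2 beats at mean_hr")
  }
  n <- round(duration * fs)
  mean_rr <- 60 / rhythm$mean_hr
  sd_rr <- 60 * rhythm$hr_sd / rhythm$mean_hr^2
  m <- ceiling((duration + 4) / mean_rr) + 8L
  rr <- with_rng(seed, {
    rr <- stats::rnorm(m, mean_rr, sd_rr)
    rr <- pmax(rr, max(0.25, 0.4 * mean_rr))
    if (rhythm$resp_depth > 0) {
      tt <- 0
      for (i in seq_along(rr)) {
        rr[i] <- rr[i] * (1 + rhythm$resp_depth *
                            sin(2 * pi * rhythm$resp_freq * tt))
        tt <- tt + rr[i]
      }
    }
    rr
  })
  s <- synth_from_rr(wave, rr, fs, n)
  gen <- list(wave = wave, rhythm = rhythm, rr = rr, duration = duration,
              st_shift = 0, ectopics = integer(0), position = NULL)
  new_record(s$clean, fs, s$clean, s$rpeaks, s$fiducials,
             "NR", "O0", seed, gen)
}

#' Imprint a pathology on a synthetic record
#'
#' `MI` offsets every ST-segment span by `st_shift` mV; `AR` re-draws the RR
#' sequence with its standard deviation multiplied by
#' `rr_irregularity_factor` and inserts premature (ectopic) beats with the
#' profile's per-beat probability; `AH` scales the P-wave amplitude and width
#' and re-synthesizes the trace. Fiducials and R-peak ground truth are updated
#' consistently. Apply pathology before [apply_position()] and [add_noise()].
#'
#' @param record an `ecg_record` (noise-free, orientation `O0`).
#' @param profile a [pathology_profile()].
#' @param seed integer seed for the AR re-draw.
#' @return The modified `ecg_record` with `class_label` set.
#' @export
apply_pathology <- function(record, profile, seed = record$seed + 1L) {
  if (!inherits(record, "ecg_record")) stop_invalid("record must be an ecg_record")
  if (!inherits(profile, "pathology_profile")) stop_invalid("profile must be a pathology_profile")
  if (!is.null(record$gen$position)) {
    stop_invalid("apply pathology before the position transform")
  }
  lab <- profile$label
  if (lab == "NR") {
    if (profile$st_shift != 0 || profile$rr_irregularity_factor != 1 ||
        profile$ectopic_prob != 0 || profile$p_amp_scale != 1 ||
        profile$p_width_scale != 1) {
      stop_invalid("NR profile must have all modifiers at identity")
    }
    record$class_label <- "NR"
    return(record)
  }
  fs <- record$fs
  n <- length(record$samples)
  if (lab == "MI") {
    record$gen$st_shift <- record$gen$st_shift + profile$st_shift
    shifted <- apply_st_shift(record$clean_samples, record$fiducials, profile$st_shift)
    record$samples <- shifted
    record$clean_samples <- shifted
  } else if (lab == "AR") {
    rhythm <- record$gen$rhythm
    mean_rr <- 60 / rhythm$mean_hr
    sd_rr <- 60 * rhythm$hr_sd / rhythm$mean_hr^2
    m <- length(record$gen$rr)
    drawn <- with_rng(seed, {
      rr <- stats::rnorm(m, mean_rr, sd_rr * profile$rr_irregularity_factor)
      rr <- pmax(rr, 0.25)
      ect <- integer(0)
      if (profile$ectopic_prob > 0) {
        ect <- which(stats::runif(m) < profile$ectopic_prob)
        for (i in ect) {
          rr[i] <- 0.6 * rr[i]       # premature
          if (i < m) rr[i + 1] <- 1.4 * rr[i + 1]  # compensatory pause
        }
      }
      list(rr = rr, ect = ect)
    })
    rr <- drawn$rr
    record$gen$rr <- rr
    record$gen$ectopics <- drawn$ect
    s <- synth_from_rr(record$gen$wave, rr, fs, n, ectopic_idx = drawn$ect)
    s$clean <- apply_st_shift(s$clean, s$fiducials, record$gen$st_shift)
    record$samples <- s$clean
    record$clean_samples <- s$clean
    record$rpeaks <- s$rpeaks
    record$fiducials <- s$fiducials
  } else if (lab == "AH") {
    wave <- record$gen$wave
    wave$amp[["P"]] <- wave$amp[["P"]] * profile$p_amp_scale
    wave$width[["P"]] <- wave$width[["P"]] * profile$p_width_scale
    record$gen$wave <- wave
    s <- resynth_clean(record)
    record$samples <- s$clean
    record$clean_samples <- s$clean
    record$rpeaks <- s$rpeaks
    record$fiducials <- s$fiducials
  }
  record$class_label <- lab
  record
}

orientation_rotation <- c(O0 = 0L, O120 = 1L, O240 = 2L)

#' Compose two orientations of the triangular patch
#'
#' Orientations form a cyclic group of order 3 under composition
#' (`O0 -> O120 -> O240 -> O0`); `O0` is the identity.
#' @param a,b orientation labels.
#' @return The composed orientation label.
#' @export
orientation_compose <- function(a, b) {
  ORIENTATION_LEVELS[((orientation_rotation[[a]] + orientation_rotation[[b]]) %% 3L) + 1L]
}

#' Apply a wear-position (misplacement) transform
#'
#' Misplacing the 120-degree-symmetric patch distorts the trace as
#' `polarity * amplitude_scale * ((1 - mix) * x + mix * warp(x)) +
#' baseline_offset`, where `warp` re-synthesizes the record with fixed
#' per-wave amplitude re-weighting (the documented morphology distortion).
#' This reproduces the misplacement signatures of baseline shift, amplitude
#' variation and waveform shape alteration. R-peak ground truth is preserved
#' as time indices. The transform is exactly invertible via
#' [inverse_position()].
#'
#' @param record an `ecg_record` currently in orientation `O0`.
#' @param pos a [position_model()].
#' @return The transformed `ecg_record` with `orientation_label` set.
#' @export
apply_position <- function(record, pos) {
  if (!inherits(record, "ecg_record")) stop_invalid("record must be an ecg_record")
  if (!inherits(pos, "position_model")) stop_invalid("pos must be a position_model")
  if (pos$orientation == "O0") return(record)
  if (!is.null(record$gen$position)) {
    stop_invalid("record already carries a position transform; invert it first ",
                 "(orientation labels compose via orientation_compose())")
  }
  w <- warp_signal(record)
  tr <- function(x) {
    pos$polarity * pos$amplitude_scale *
      ((1 - pos$morphology_mix) * x + pos$morphology_mix * w) +
      pos$baseline_offset
  }
  record$samples <- tr(record$samples)
  record$clean_samples <- tr(record$clean_samples)
  record$orientation_label <- orientation_compose(record$orientation_label,
                                                  pos$orientation)
  record$gen$position <- pos
  record
}

#' Invert the wear-position transform of a record
#'
#' Reconstructs the morphology-warp component from the record's stored
#' generation state and inverts the affine/mix transform exactly (to
#' numerical precision on noise-free records; on noisy records the additive
#' noise is rescaled by the inverse gain).
#'
#' @param record an `ecg_record` with a stored position transform.
#' @return The record restored to orientation `O0`.
#' @export
inverse_position <- function(record) {
  pos <- record$gen$position
  if (is.null(pos)) return(record)
  record$gen$position <- NULL
  w <- warp_signal(record)
  inv <- function(y) {
    ((y - pos$baseline_offset) / (pos$polarity * pos$amplitude_scale) -
       pos$morphology_mix * w) / (1 - pos$morphology_mix)
  }
  record$samples <- inv(record$samples)
  record$clean_samples <- inv(record$clean_samples)
  back <- ORIENTATION_LEVELS[((3L - orientation_rotation[[pos$orientation]]) %% 3L) + 1L]
  record$orientation_label <- orientation_compose(record$orientation_label, back)
  record
}

#' Add structured noise to a record
#'
#' `samples` becomes `clean_samples` plus a baseline-wander sinusoid, a
#' power-line sinusoid, white broadband noise and Poisson-timed Gaussian
#' motion bursts; `clean_samples` is retained as the noise-free reference.
#' Deterministic given the seed.
#'
#' @param record an `ecg_record`.
#' @param noise a [noise_model()].
#' @param seed integer seed.
#' @return The noisy `ecg_record`.
#' @export
add_noise <- function(record, noise, seed = record$seed + 2L) {
  if (!inherits(record, "ecg_record")) stop_invalid("record must be an ecg_record")
  if (!inherits(noise, "noise_model")) stop_invalid("noise must be a noise_model")
  amps <- c(noise$wander_amp, noise$powerline_amp, noise$broadband_sd, noise$burst_amp)
  if (any(amps < 0)) stop_invalid("noise amplitudes must be >= 0")
  n <- length(record$clean_samples)
  fs <- record$fs
  t <- (seq_len(n) - 1) / fs
  dur <- n / fs
  record$samples <- with_rng(seed, {
    x <- record$clean_samples
    if (noise$wander_amp > 0) {
      x <- x + noise$wander_amp * sin(2 * pi * noise$wander_freq * t +
                                        stats::runif(1, 0, 2 * pi))
    }
    if (noise$powerline_amp > 0) {
      x <- x + noise$powerline_amp * sin(2 * pi * noise$powerline_freq * t +
                                           stats::runif(1, 0, 2 * pi))
    }
    if (noise$broadband_sd > 0) x <- x + stats::rnorm(n, 0, noise$broadband_sd)
    if (noise$burst_rate > 0 && noise$burst_amp > 0) {
      nb <- stats::rpois(1, noise$burst_rate * dur / 60)
      if (nb > 0) {
        centers <- stats::runif(nb, 0, dur)
        signs <- sample(c(-1, 1), nb, replace = TRUE)
        for (k in seq_len(nb)) {
          x <- x + signs[k] * noise$burst_amp * exp(-(t - centers[k])^2 / (2 * 0.05^2))
        }
      }
    }
    x
  })
  record
}

#' Broadband noise model achieving a target signal-to-noise ratio
#'
#' Chooses the white-noise standard deviation so that the clean-signal power
#' divided by the noise power equals `10^(snr_db/10)` in expectation; all
#' other noise components are zero.
#'
#' @param record an `ecg_record` providing the clean reference power.
#' @param snr_db target SNR in dB.
#' @return A [noise_model()] with only the broadband component active.
#' @export
noise_for_snr <- function(record, snr_db) {
  p_sig <- mean(record$clean_samples^2)
  noise_model(wander_amp = 0, powerline_amp = 0,
              broadband_sd = sqrt(p_sig / 10^(snr_db / 10)),
              burst_rate = 0, burst_amp = 0)
}

largest_remainder <- function(n, props) {
  raw <- n * props / sum(props)
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}

#' Generate a labelled synthetic dataset with a stratified split
#'
#' Produces `n` records with the requested class and orientation mixes
#' (largest-remainder rounding), applies the default pathology profiles, the
#' orientation transforms and the noise model, and returns a stratified
#' 80/20 train/test split by class. Per-record seeds and per-record mean
#' heart rates (uniform on 55-95 bpm) are derived deterministically from the
#' master seed, so identical seeds give byte-identical datasets.
#'
#' @param n number of records (>= 10; every class with positive mix needs at
#'   least 5 records).
#' @param class_mix named proportions over `NR`, `AR`, `AH`, `MI` (sum 1).
#' @param position_mix named proportions over `O0`, `O120`, `O240` (sum 1).
#' @param fs sampling rate (Hz).
#' @param duration record duration (s).
#' @param noise a [noise_model()] applied to every record.
#' @param seed master seed.
#' @param wave base [wave_params()].
#' @param hr_sd within-record heart-rate SD (bpm).
#' @param profiles named list of [pathology_profile()] objects per class.
#' @param train_frac training fraction of the stratified split.
#' @return An object of class `ecg_dataset` with elements `records`,
#'   `labels`, `orientations`, `split` (`$train`, `$test` index vectors) and
#'   the generating parameters.
#' @examples
#' ds <- make_dataset(n = 12, seed = 1, duration = 6)
#' table(ds$labels)
#' @export
make_dataset <- function(n = 100,
                         class_mix = c(NR = 0.25, AR = 0.25, AH = 0.25, MI = 0.25),
                         position_mix = c(O0 = 1, O120 = 0, O240 = 0),
                         fs = 250, duration = 10,
                         noise = noise_model(), seed = 1,
                         wave = wave_params(), hr_sd = 2,
                         profiles = list(
                           NR = pathology_profile("NR"),
                           AR = pathology_profile("AR"),
                           AH = pathology_profile("AH"),
                           MI = pathology_profile("MI")),
                         train_frac = 0.8) {
  if (n < 10) stop_invalid("n must be at least 10")
  class_mix <- class_mix[CLASS_LEVELS]; class_mix[is.na(class_mix)] <- 0
  position_mix <- position_mix[ORIENTATION_LEVELS]; position_mix[is.na(position_mix)] <- 0
  if (abs(sum(class_mix) - 1) > 1e-8 || abs(sum(position_mix) - 1) > 1e-8) {
    stop_invalid("class_mix and position_mix must each sum to 1")
  }
  counts <- largest_remainder(n, class_mix)
  if (any(counts > 0 & counts < 5)) {
    stop_invalid("each class with positive mix needs at least 5 records for stratification")
  }
  labels <- rep(CLASS_LEVELS, counts)
  ocounts <- largest_remainder(n, position_mix)
  # weighted round-robin over the class-ordered records, so every class sees
  # the orientation mix while counts match exactly
  remaining <- ocounts
  orientations <- character(n)
  for (i in seq_len(n)) {
    k <- which.max(remaining / max(sum(remaining), 1))
    orientations[i] <- ORIENTATION_LEVELS[k]
    remaining[k] <- remaining[k] - 1L
  }

  master <- with_rng(seed, list(
    seeds = matrix(sample.int(.Machine$integer.max - 1L, 3L * n), ncol = 3L),
    mean_hrs = stats::runif(n, 55, 95),
    shuffle = sample.int(n)
  ))
  records <- vector("list", n)
  for (i in seq_len(n)) {
    r <- generate_record(wave = wave,
                         rhythm = rhythm_model(mean_hr = master$mean_hrs[i], hr_sd = hr_sd),
                         fs = fs, duration = duration, seed = master$seeds[i, 1])
    r <- apply_pathology(r, profiles[[labels[i]]], seed = master$seeds[i, 2])
    if (orientations[i] != "O0") {
      r <- apply_position(r, position_model(orientations[i]))
    }
    r <- add_noise(r, noise, seed = master$seeds[i, 3])
    records[[i]] <- r
  }
  labels <- factor(labels, levels = CLASS_LEVELS)
  orientations <- factor(orientations, levels = ORIENTATION_LEVELS)
  # stratified split by class (records were laid out class-by-class; shuffle
  # within class under the master seed)
  train <- integer(0)
  for (cl in CLASS_LEVELS) {
    idx <- which(labels == cl)
    if (!length(idx)) next
    idx <- idx[order(master$shuffle[idx])]
    ntr <- round(train_frac * length(idx))
    train <- c(train, idx[seq_len(ntr)])
  }
  train <- sort(train)
  test <- setdiff(seq_len(n), train)
  structure(list(records = records, labels = labels, orientations = orientations,
                 split = list(train = train, test = test),
                 fs = fs, duration = duration, seed = seed,
                 class_mix = class_mix, position_mix = position_mix),
            class = "ecg_dataset")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record> %.1f s @ %g Hz | class %s | orientation %s | %d beats\n",
              length(x$samples) / x$fs, x$fs, x$class_label,
              x$orientation_label, length(x$rpeaks)))
  invisible(x)
}

#' @export
print.ecg_dataset <- function(x, ...) {
  cat(sprintf("<ecg_dataset> %d records (%.0f s @ %g Hz), train/test %d/%d\n",
              length(x$records), x$duration, x$fs,
              length(x$split$train), length(x$split$test)))
  print(table(class = x$labels, orientation = x$orientations))
  invisible(x)
}

#' Plot a synthetic ECG record
#'
#' @param x an `ecg_record`.
#' @param show_clean overlay the clean reference trace.
#' @param show_rpeaks mark ground-truth R peaks.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.ecg_record <- function(x, show_clean = TRUE, show_rpeaks = TRUE, ...) {
  t <- (seq_along(x$samples) - 1) / x$fs
  graphics::plot(t, x$samples, type = "l", xlab = "time (s)", ylab = "mV",
                 main = sprintf("%s / %s", x$class_label, x$orientation_label), ...)
  if (show_clean) graphics::lines(t, x$clean_samples, col = "grey60")
  if (show_rpeaks && length(x$rpeaks)) {
    graphics::points(x$rpeaks / x$fs, x$samples[x$rpeaks + 1], col = 2, pch = 20)
  }
  invisible(x)
}
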