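fs <- 250
tt <- (0:(10 * fs - 1)) / fs
core <- (2 * fs):(8 * fs)  # avoid filter edge transients

test_that("notch filter attenuates 50 Hz by >= 30 dB and spares the passband", {
  s50 <- sin(2 * pi * 50 * tt)
  ratio <- sqrt(mean(notch_filter(s50, fs)[core]^2) / mean(s50[core]^2))
  expect_lt(ratio, 10^(-30 / 20))

  s10 <- sin(2 * pi * 10 * tt)
  ratio10 <- sqrt(mean(notch_filter(s10, fs)[core]^2) / mean(s10[core]^2))
  expect_lt(abs(ratio10 - 1), 0.11)

  expect_identical(notch_filter(rep(0, 1000), fs), rep(0, 1000))
  expect_error(notch_filter(s10, fs = 90), "twice")
})

test_that("computed frequency response meets the attenuation/ripple contract", {
  spec <- filter_spec()
  bw <- spec$notch_freq / spec$notch_q
  bt <- signal::butter(2, c(spec$notch_freq - bw / 2,
                            spec$notch_freq + bw / 2) / (fs / 2), type = "stop")
  H <- signal::freqz(bt$b, bt$a, n = 4096, Fs = fs)
  mag_db <- 20 * log10(abs(H$h)^2)  # |H|^2: forward-backward application
  expect_lt(mag_db[which.min(abs(H$f - 50))], -30)
  band <- H$f >= 1 & H$f <= 40
  expect_lt(max(abs(mag_db[band])), 1)
})

test_that("baseline correction removes wander but preserves QRS and ST", {
  rec <- generate_record(rhythm = rhythm_model(70, 2), duration = 30, seed = 31)
  t30 <- (seq_along(rec$samples) - 1) / fs
  x <- rec$samples + 0.5 * sin(2 * pi * 0.25 * t30)
  bandpow <- function(sig) {
    p <- stats::spec.pgram(stats::ts(sig, frequency = fs), plot = FALSE,
                           taper = 0)
    sum(p$spec[p$freq > 0.1 & p$freq < 0.4])
  }
  y <- baseline_correct(x, fs)
  expect_gt(1 - bandpow(y) / bandpow(x), 0.9)

  yd <- baseline_correct(rec$samples, fs)
  ramp <- rec$samples[rec$rpeaks + 1]
  expect_lt(max(abs(yd[rec$rpeaks + 1] - ramp) / abs(ramp)), 0.05)

  const <- baseline_correct(rep(1, 2500), fs)
  expect_lt(abs(mean(const)), 1e-9)
  expect_error(baseline_correct(rep(0, 100), fs), "2 s")
})

test_that("segmentation arithmetic and error cases", {
  x <- numeric(2500)
  s1 <- segment(x, fs, 6, 6)
  expect_equal(nrow(s1$windows), 1)
  s2 <- segment(numeric(3000), fs, 6, 3)
  expect_equal(nrow(s2$windows), 3)
  expect_equal(s2$offsets, c(0L, 750L, 1500L))
  expect_error(segment(numeric(1499), fs, 6), "shorter")
  expect_error(segment(x, fs, 6, stride_s = 0), "stride")
})

test_that("per-window normalization: z-score, affine invariance, idempotence", {
  set.seed(41)
  for (i in 1:5) {
    w <- rnorm(500) * runif(1, 0.1, 5) + runif(1, -2, 2)
    nw <- normalize_window(w)
    expect_lt(abs(mean(nw)), 1e-9)
    expect_lt(abs(stats::sd(nw) - 1), 1e-9)
    expect_equal(normalize_window(3.2 * w + 0.7), nw, tolerance = 1e-9)
    expect_equal(normalize_window(as.numeric(nw)), as.numeric(nw),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
  expect_warning(z <- normalize_window(rep(2, 100)), "constant")
  expect_true(all(z == 0))
  expect_true(attr(z, "constant"))
})

test_that("zero-phase chain shifts R peaks by at most one sample", {
  rec <- generate_record(rhythm = rhythm_model(72, 2), duration = 20, seed = 32)
  y <- baseline_correct(bandpass_filter(notch_filter(rec$samples, fs), fs), fs)
  for (i in rec$rpeaks) {
    w <- max(1, i - 24):min(length(y), i + 26)
    shifted <- w[which.max(y[w])] - 1 - i
    expect_lte(abs(shifted), 1)
  }
})
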