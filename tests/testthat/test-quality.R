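test_that("template SNR: noiseless floor, known mixture, scale invariance", {
  rec <- generate_record(rhythm = rhythm_model(60, 0), duration = 60, seed = 1)
  pk <- pan_tompkins(rec$samples, rec$fs)
  expect_gt(snr(rec$samples, rec$fs, pk), 40)

  nz <- add_noise(rec, noise_for_snr(rec, 20), seed = 8)
  pk2 <- pan_tompkins(nz$samples, nz$fs)
  est <- snr(nz$samples, nz$fs, pk2)
  expect_lt(abs(est - 20), 1)
  expect_lt(abs(snr(4.2 * nz$samples, nz$fs, pk2) - est), 0.1)
  expect_error(snr(rec$samples, rec$fs, rpeak_set(c(0L, 250L), 250)),
               "5 detected")
})

test_that("template SNR decreases monotonically with noise level", {
  rec <- generate_record(rhythm = rhythm_model(60, 0), duration = 60, seed = 2)
  est <- vapply(c(25, 15, 5), function(target) {
    nz <- add_noise(rec, noise_for_snr(rec, target), seed = 30 + target)
    snr(nz$samples, nz$fs, pan_tompkins(nz$samples, nz$fs))
  }, numeric(1))
  expect_true(all(diff(est) < 0))
})

test_that("drift amplitude measures normalized baseline peak-to-peak", {
  rec <- generate_record(rhythm = rhythm_model(60, 0), duration = 60, seed = 3)
  expect_lt(drift_amplitude(rec$samples, rec$fs), 0.02)
  expect_identical(drift_amplitude(rep(0, 15000), 250), 0)

  xn <- (rec$samples - min(rec$samples)) / diff(range(rec$samples))
  t60 <- (seq_along(xn) - 1) / rec$fs
  withw <- xn + 0.2 * sin(2 * pi * 0.25 * t60)
  expect_equal(drift_amplitude(withw, rec$fs), 0.4, tolerance = 0.04)
  # scale invariance by construction
  expect_equal(drift_amplitude(5 * withw, rec$fs),
               drift_amplitude(withw, rec$fs), tolerance = 1e-9)
  expect_error(drift_amplitude(rnorm(100), 250), "10 s")
})

test_that("instantaneous-frequency ridge tracks tones and chirps", {
  fs <- 250
  t <- (0:(20 * fs - 1)) / fs
  ridge <- instantaneous_frequency(sin(2 * pi * 10 * t), fs)$ridge
  expect_true(all(abs(ridge - 10) < 0.5))

  t10 <- (0:(10 * fs - 1)) / fs
  chirp <- sin(2 * pi * (5 * t10 + 0.5 * t10^2))  # 5 -> 15 Hz over 10 s
  tf <- instantaneous_frequency(chirp, fs)
  mid <- which.min(abs(tf$times - 5))
  expect_lt(abs(tf$ridge[mid] - 10), 1)
  expect_error(instantaneous_frequency(rnorm(100), fs), "too short")
})

test_that("arrhythmic records have more variable instantaneous frequency", {
  base <- generate_record(rhythm = rhythm_model(70, 2), duration = 30, seed = 51)
  ar <- apply_pathology(base, pathology_profile("AR"), seed = 52)
  v_nr <- stats::var(instantaneous_frequency(base$clean_samples, base$fs)$ridge)
  v_ar <- stats::var(instantaneous_frequency(ar$clean_samples, ar$fs)$ridge)
  expect_gt(v_ar, v_nr)
})

test_that("cross-correlation: identity, inversion, shift recovery, symmetry", {
  rec <- generate_record(rhythm = rhythm_model(70, 2), duration = 8, seed = 53)
  a <- rec$samples
  expect_equal(xcorr_coefficient(a, a, fs = rec$fs)$value, 1, tolerance = 1e-12)

  neg <- xcorr_coefficient(a, -a, fs = rec$fs)
  expect_equal(neg$value, -1, tolerance = 1e-12)
  expect_equal(neg$lag, 0L)

  b <- c(rep(0, 25), a[1:(length(a) - 25)])
  sh <- xcorr_coefficient(a, b, fs = rec$fs)
  expect_equal(sh$lag, 25L)
  expect_gt(sh$value, 0.99)

  ab <- xcorr_coefficient(a, b, fs = rec$fs)
  ba <- xcorr_coefficient(b, a, fs = rec$fs)
  expect_equal(ab$value, ba$value, tolerance = 1e-9)
  expect_equal(ab$lag, -ba$lag)

  expect_error(xcorr_coefficient(rep(1, 100), rnorm(100)), "constant")
  expect_error(xcorr_coefficient(1:10, 1:5), "equal length")
})
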