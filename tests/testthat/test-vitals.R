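test_that("Pan-Tompkins finds every clean beat at the exact location", {
  rec <- generate_record(rhythm = rhythm_model(60, 0), fs = 250,
                         duration = 30, seed = 1)
  pk <- pan_tompkins(rec$samples, rec$fs)
  expect_length(pk$indices, length(rec$rpeaks))
  expect_lte(max(abs(pk$indices - rec$rpeaks)), 1)
})

test_that("degenerate detector inputs are handled", {
  expect_length(pan_tompkins(rep(0, 1000), 250)$indices, 0)
  expect_error(pan_tompkins(rnorm(100), 250), "2 s")
  expect_error(pan_tompkins(rnorm(1000), 50), "100 Hz")
})

test_that("refractory invariant holds and sensitivity degrades monotonically", {
  rec <- generate_record(rhythm = rhythm_model(75, 2), duration = 60, seed = 4)
  sens <- numeric(0)
  for (sdv in c(0.05, 0.3, 0.8)) {
    nz <- add_noise(rec, noise_model(wander_amp = 0, powerline_amp = 0,
                                     broadband_sd = sdv, burst_rate = 0),
                    seed = 6)
    pk <- pan_tompkins(nz$samples, nz$fs)
    if (length(pk$indices) > 1) {
      expect_gte(min(diff(pk$indices)), round(0.2 * nz$fs))
    }
    m <- cp$match_rpeaks(pk$indices, nz$rpeaks, nz$fs, 0.05)
    sens <- c(sens, m$sensitivity)
  }
  expect_true(all(diff(sens) <= 1e-9))
})

test_that("windowed heart rate follows the mean-RR definition exactly", {
  pk <- rpeak_set(seq(0, 59 * 250, by = 250), 250, n_samples = 60 * 250)
  hr <- heart_rate(pk, window_s = 6)
  expect_equal(nrow(hr), 10)
  expect_true(all(abs(hr$hr_bpm - 60) < 1e-12))

  pk2 <- rpeak_set(seq(0, 119 * 125, by = 125), 250, n_samples = 60 * 250)
  hr2 <- heart_rate(pk2, window_s = 6)
  expect_true(all(abs(hr2$hr_bpm - 120) < 1e-12))

  # alternating 0.8 / 1.0 s intervals -> HR = 60 / 0.9
  idx <- cumsum(c(0, rep(c(200, 250), 20)))
  hr3 <- heart_rate(rpeak_set(idx, 250), window_s = 18)
  expect_equal(hr3$hr_bpm[1], 60 / 0.9, tolerance = 1e-9)
})

test_that("HRV statistics match a brute-force oracle to 1e-9", {
  set.seed(3)
  rr <- runif(100, 700, 1100)
  h <- hrv_from_rr(rr)
  expect_equal(h$sdnn, sqrt(mean((rr - mean(rr))^2)), tolerance = 1e-9)
  expect_equal(h$rmssd, sqrt(mean(diff(rr)^2)), tolerance = 1e-9)
  expect_equal(h$pnn50, 100 * mean(abs(diff(rr)) > 50), tolerance = 1e-9)

  const <- hrv_from_rr(rep(1000, 50))
  expect_identical(c(const$sdnn, const$rmssd, const$pnn50), c(0, 0, 0))

  alt <- hrv_from_rr(rep(c(800, 1000), 25))
  expect_equal(alt$rmssd, 200, tolerance = 1e-12)
})

test_that("vitals report bounds windowed heart rates and flags gaps", {
  rec <- generate_record(rhythm = rhythm_model(70, 3), duration = 60, seed = 9)
  pk <- pan_tompkins(rec$samples, rec$fs)
  v <- hrv_metrics(pk, window_s = 6)
  ok <- v$windows$hr_bpm[!v$windows$missing]
  expect_true(all(ok >= v$hr_min - 1e-12 & ok <= v$hr_max + 1e-12))
  expect_gte(v$sdnn, 0)
  expect_gte(v$rmssd, 0)
  expect_error(hrv_metrics(rpeak_set(c(0L, 250L), 250)), "3 R peaks")
})
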