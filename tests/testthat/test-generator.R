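test_that("zero-variance rhythm gives exactly periodic R peaks", {
  rec <- generate_record(rhythm = rhythm_model(60, 0), fs = 250,
                         duration = 10, seed = 1)
  expect_length(rec$rpeaks, 10)
  expect_true(all(diff(rec$rpeaks) == 250))
  expect_identical(rec$samples, rec$clean_samples)

  rec2 <- generate_record(rhythm = rhythm_model(120, 0), fs = 250,
                          duration = 10, seed = 1)
  expect_true(all(diff(rec2$rpeaks) == 125))
})

test_that("empirical mean RR matches the rhythm model within 3 SE", {
  rec <- generate_record(rhythm = rhythm_model(70, 3), fs = 250,
                         duration = 60, seed = 42)
  rr <- diff(rec$rpeaks) / rec$fs
  se <- stats::sd(rr) / sqrt(length(rr))
  expect_lt(abs(mean(rr) - 60 / 70), 3 * se)
})

test_that("generation is deterministic and validates arguments", {
  a <- generate_record(seed = 11)
  b <- generate_record(seed = 11)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  expect_error(generate_record(fs = 50), "fs")
  expect_error(generate_record(duration = -1), "duration")
  expect_error(generate_record(duration = 1, rhythm = rhythm_model(30, 0)),
               "2 beats")
  expect_error(rhythm_model(mean_hr = 300), "mean_hr")
})

test_that("R-peak ground truth sits at the clean-waveform maximum", {
  rec <- generate_record(rhythm = rhythm_model(75, 2), duration = 30, seed = 5)
  expect_false(is.unsorted(rec$rpeaks, strictly = TRUE))
  for (i in rec$rpeaks) {
    lo <- max(0, i - 60); hi <- min(length(rec$clean_samples) - 1, i + 60)
    am <- lo + which.max(rec$clean_samples[(lo + 1):(hi + 1)]) - 1
    expect_lte(abs(am - i), 1)
  }
  fid <- rec$fiducials
  expect_true(all(fid$p_on >= 0 & fid$t_off < length(rec$samples)))
  expect_true(all(fid$st_off > fid$st_on))
})

test_that("NR pathology is the identity and invalid profiles are rejected", {
  rec <- generate_record(seed = 2)
  out <- apply_pathology(rec, pathology_profile("NR"))
  expect_identical(out$samples, rec$samples)
  expect_equal(out$class_label, "NR")
  bad <- pathology_profile("NR")
  bad$st_shift <- 0.1
  expect_error(apply_pathology(rec, bad), "identity")
})

test_that("MI shifts every ST span by exactly st_shift", {
  rec <- generate_record(rhythm = rhythm_model(70, 2), duration = 10, seed = 4)
  mi <- apply_pathology(rec, pathology_profile("MI", st_shift = 0.2))
  idx <- span_index(mi$fiducials$st_on, mi$fiducials$st_off)
  expect_equal(mean(mi$samples[idx] - rec$clean_samples[idx]), 0.2,
               tolerance = 1e-12)
  out <- setdiff(seq_along(rec$samples), idx)
  expect_equal(max(abs(mi$samples[out] - rec$clean_samples[out])), 0)
  expect_equal(mi$class_label, "MI")
})

test_that("AR re-draws RR with the inflated spread and marks ectopics", {
  rec <- generate_record(rhythm = rhythm_model(70, 2), duration = 60, seed = 5)
  ar <- apply_pathology(rec, pathology_profile("AR", rr_irregularity_factor = 4,
                                               ectopic_prob = 0), seed = 11)
  rr <- diff(ar$rpeaks) / ar$fs
  sd_bpm <- stats::sd(rr) * 70^2 / 60
  se <- sd_bpm / sqrt(2 * (length(rr) - 1))
  expect_lt(abs(sd_bpm - 8), 3 * se)

  ar2 <- apply_pathology(rec, pathology_profile("AR", ectopic_prob = 0.5),
                         seed = 12)
  expect_gt(length(ar2$gen$ectopics), 0)
})

test_that("AH scales the P wave and leaves the R peak dominant", {
  rec <- generate_record(rhythm = rhythm_model(65, 1), duration = 10, seed = 6)
  ah <- apply_pathology(rec, pathology_profile("AH", p_amp_scale = 2,
                                               p_width_scale = 1.5))
  p_amp <- function(r, k) {
    max(r$clean_samples[(r$fiducials$p_on[k] + 1):r$fiducials$p_off[k]])
  }
  expect_equal(p_amp(ah, 3) / p_amp(rec, 3), 2, tolerance = 0.05)
  expect_equal(ah$class_label, "AH")
})

test_that("pathology summary statistics separate classes by >= 5 pooled SDs", {
  stat_for <- function(cls, stat) {
    vapply(1:8, function(s) {
      r <- generate_record(rhythm = rhythm_model(70, 2), duration = 30,
                           seed = 100 * s)
      if (cls != "NR") r <- apply_pathology(r, pathology_profile(cls),
                                            seed = 100 * s + 1)
      stat(r)
    }, numeric(1))
  }
  st_level <- function(r) {
    mean(r$clean_samples[span_index(r$fiducials$st_on, r$fiducials$st_off)])
  }
  rr_sd <- function(r) stats::sd(diff(r$rpeaks) / r$fs)
  pr_ratio <- function(r) {
    p <- vapply(seq_len(nrow(r$fiducials)), function(k) {
      max(r$clean_samples[(r$fiducials$p_on[k] + 1):r$fiducials$p_off[k]])
    }, numeric(1))
    mean(p) / max(r$clean_samples)
  }
  for (case in list(list("MI", st_level), list("AR", rr_sd),
                    list("AH", pr_ratio))) {
    a <- stat_for("NR", case[[2]])
    b <- stat_for(case[[1]], case[[2]])
    pooled <- sqrt((stats::var(a) + stats::var(b)) / 2)
    expect_gt(abs(mean(a) - mean(b)) / pooled, 5)
  }
})

test_that("orientation transforms: identity, invertibility, 3-cycle", {
  rec <- generate_record(seed = 7)
  expect_identical(apply_position(rec, position_model("O0"))$samples,
                   rec$samples)
  p <- apply_position(rec, position_model("O120"))
  expect_equal(p$orientation_label, "O120")
  back <- inverse_position(p)
  expect_lt(max(abs(back$samples - rec$samples)), 1e-9)
  expect_equal(back$orientation_label, "O0")
  # label composition is a cyclic group of order 3
  expect_equal(orientation_compose("O120", "O120"), "O240")
  expect_equal(orientation_compose("O240", "O120"), "O0")
  lab <- "O0"
  for (i in 1:3) lab <- orientation_compose(lab, "O120")
  expect_equal(lab, "O0")
  expect_error(apply_position(p, position_model("O120")), "already")
  expect_error(position_model("O0", amplitude_scale = 0.5), "identity")
})

test_that("noise model: zero noise is the identity, SNR construction holds", {
  rec <- generate_record(rhythm = rhythm_model(60, 0), duration = 30, seed = 8)
  z <- add_noise(rec, no_noise(), seed = 1)
  expect_identical(z$samples, z$clean_samples)

  nz <- add_noise(rec, noise_for_snr(rec, 20), seed = 9)
  realized <- 10 * log10(sum(nz$clean_samples^2) /
                           sum((nz$samples - nz$clean_samples)^2))
  expect_lt(abs(realized - 20), 1)

  pl <- add_noise(rec, noise_model(wander_amp = 0, powerline_amp = 0.1,
                                   broadband_sd = 0, burst_rate = 0), seed = 10)
  sp <- stats::spec.pgram(stats::ts(pl$samples - pl$clean_samples,
                                    frequency = rec$fs), plot = FALSE,
                          taper = 0)
  expect_equal(sp$freq[which.max(sp$spec)], 50, tolerance = 0.5)
  expect_error(noise_model(broadband_sd = -1), "broadband_sd")
})

test_that("make_dataset honours mixes, stratification and determinism", {
  ds <- quick_dataset(n = 100, seed = 13)
  expect_equal(as.integer(table(ds$labels)), rep(25L, 4))
  expect_length(ds$split$train, 80)
  expect_length(ds$split$test, 20)
  expect_equal(as.integer(table(ds$labels[ds$split$test])), rep(5L, 4))

  ds2 <- make_dataset(n = 200, class_mix = c(NR = 0.4, AR = 0.2, AH = 0.2,
                                             MI = 0.2),
                      seed = 14, duration = 6)
  expect_equal(as.integer(table(ds2$labels)), c(80L, 40L, 40L, 40L))

  a <- quick_dataset(n = 20, seed = 15)
  b <- quick_dataset(n = 20, seed = 15)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  expect_error(make_dataset(n = 8), "at least 10")

  ds3 <- quick_dataset(n = 30, seed = 16,
                       position_mix = c(O0 = 1 / 3, O120 = 1 / 3, O240 = 1 / 3))
  expect_equal(as.integer(table(ds3$orientations)), rep(10L, 3))
})
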