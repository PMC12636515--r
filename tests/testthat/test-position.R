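# Structural tests of the position network on a miniature configuration;
# the full-scale adversarial training run lives in test-acceptance.R.

small_cfg <- list(frame_len = 10L, fc_dim = 6L, conv_channels = 5L,
                  conv_kernel = 3L, gru_hidden = 7L, disc_hidden = 4L)
L <- 40L

test_that("position-net analytic gradient matches finite differences", {
  p <- cp$cpp_pos_init(small_cfg, L, 5L, sd = 0.2)
  set.seed(1)
  X <- matrix(rnorm(3 * L), 3, L)
  y <- c(0L, 1L, 2L)
  ref <- rnorm(7) * 0.1
  g <- cp$cpp_pos_grad(p, small_cfg, X, y, ref, 1.0)
  set.seed(3)
  idx <- sample(length(p), 30)
  eps <- 1e-6
  fd <- vapply(idx, function(i) {
    pp <- p; pp[i] <- pp[i] + eps
    l1 <- cp$cpp_pos_grad(pp, small_cfg, X, y, ref, 1)$loss
    pp[i] <- pp[i] - 2 * eps
    l0 <- cp$cpp_pos_grad(pp, small_cfg, X, y, ref, 1)$loss
    (l1 - l0) / (2 * eps)
  }, numeric(1))
  expect_lt(max(abs(fd - g$grad[idx]) / pmax(abs(fd), 1e-4)), 1e-4)
})

test_that("forward pass: shapes, determinism, sigmoid range", {
  p <- cp$cpp_pos_init(small_cfg, L, 6L)
  set.seed(2)
  X <- matrix(rnorm(4 * L), 4, L)
  ref <- rnorm(7)
  fw <- cp$cpp_pos_forward(p, small_cfg, X, ref)
  expect_equal(dim(fw$probs), c(4, 3))
  expect_true(all(abs(rowSums(fw$probs) - 1) < 1e-9))
  expect_equal(dim(fw$summaries), c(4, 7))
  expect_true(all(fw$scores > 0 & fw$scores < 1))
  fw2 <- cp$cpp_pos_forward(p, small_cfg, X, ref)
  expect_identical(fw$summaries, fw2$summaries)
})

ds_pos <- quick_dataset(n = 30, seed = 71,
                        position_mix = c(O0 = 1 / 3, O120 = 1 / 3, O240 = 1 / 3))

test_that("training decreases the joint loss and is deterministic", {
  fit <- position_fit(ds_pos, tiny_pos_config(seed = 3, epochs = 6))
  expect_lt(utils::tail(fit$train_log$loss, 1), fit$train_log$loss[1])
  fit2 <- position_fit(ds_pos, tiny_pos_config(seed = 3, epochs = 6))
  expect_identical(fit$params, fit2$params)
  dsO0 <- quick_dataset(n = 20, seed = 72)  # single orientation
  expect_error(position_fit(dsO0, tiny_pos_config()), "three orientations")
})

fit_pos <- position_fit(ds_pos, tiny_pos_config(seed = 4, epochs = 4))

test_that("embedding and summary accessors behave as specified", {
  w <- model_windows(ds_pos$records[[1]], spec = fit_pos$spec)[1, ]
  E <- position_embed(fit_pos, w)
  expect_equal(dim(E), c(length(w) / 25, 8))
  expect_identical(E, position_embed(fit_pos, w))
  # zero input with (freshly initialized) zero biases gives a zero embedding
  init_model <- structure(list(
    params = as.numeric(cp$cpp_pos_init(unclass(fit_pos$config),
                                        fit_pos$input_len, 1L)),
    config = fit_pos$config, input_len = fit_pos$input_len,
    reference = numeric(fit_pos$config$gru_hidden), spec = fit_pos$spec),
    class = "position_model")
  expect_true(all(position_embed(init_model, rep(0, length(w))) == 0))
  s <- position_features(fit_pos, w)
  expect_length(s, 8)
  expect_identical(s, position_features(fit_pos, w))
})

test_that("discriminator scores lie in (0,1) and match the compiled path", {
  w <- model_windows(ds_pos$records[[2]], spec = fit_pos$spec)[1, ]
  s <- position_features(fit_pos, w)
  d <- discriminate(fit_pos, s)
  expect_true(d > 0 && d < 1)
  fw <- cp$pos_forward(fit_pos, matrix(w, 1))
  expect_equal(d, as.numeric(fw$scores[1]), tolerance = 1e-12)
  expect_error(discriminate(fit_pos, s[1:3]), "dimension")
})

test_that("assessments satisfy the declared invariants", {
  df <- predict(fit_pos, ds_pos)
  expect_true(all(abs(df$p_O0 + df$p_O120 + df$p_O240 - 1) < 1e-9))
  expect_true(all(df$adjustment_deg %in% c(0, -120, 120)))
  expect_identical(df$adjustment_deg == 0, df$orientation == "O0")
  thr <- fit_pos$config$tolerance_threshold
  expect_identical(df$within_tolerance, df$discriminator_score >= thr)
  # within_tolerance is monotone in the score at fixed threshold
  ord <- order(df$discriminator_score)
  expect_false(is.unsorted(df$within_tolerance[ord]))
  a <- assess_position(fit_pos, ds_pos$records[[1]])
  expect_s3_class(a, "position_assessment")
  # the suggested rotation composes with the predicted orientation to O0
  inverse_of <- c(O0 = "O0", O120 = "O240", O240 = "O120")[[a$orientation]]
  expect_equal(orientation_compose(a$orientation, inverse_of), "O0")
})
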