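# Structural and numerical tests of the attention-transformer core on a
# miniature configuration (fast); the full-scale training run lives in
# test-acceptance.R.

small_cfg <- list(slice_len = 10L, embed_dim = 8L, n_heads = 2L,
                  n_layers = 1L, mlp_dim = 16L, dropout = 0,
                  n_classes = 4L, conv_kernel = 5L, conv_kernel_local = 3L,
                  conv_channels = 2L)
L <- 40L

test_that("parameter count: closed form, compiled layout and a hand count agree", {
  cfgR <- iat_config(slice_len = 10, embed_dim = 8, n_heads = 2, n_layers = 1,
                     mlp_dim = 16, conv_kernel = 5, conv_kernel_local = 3,
                     conv_channels = 2)
  expect_equal(iat_param_count(cfgR, L), 870)  # hand-computed for this config
  expect_equal(cp$cpp_iat_nparams(small_cfg, L), 870)
  expect_length(cp$cpp_iat_init(small_cfg, L, 1L), 870)
})

test_that("tokenization: slice arithmetic, remainder drop, determinism", {
  p <- cp$cpp_iat_init(small_cfg, L, 2L)
  x <- matrix(sin(1:L / 3), 1, L)
  fw <- cp$cpp_iat_forward(p, small_cfg, x, FALSE, TRUE, FALSE)
  expect_equal(dim(fw$tokens[[1]]), c(L / 10 + 1, 8))  # slices + CLS

  # remainder dropped: 43 samples -> still 4 slice tokens
  p2 <- cp$cpp_iat_init(small_cfg, 43L, 2L)
  fw2 <- cp$cpp_iat_forward(p2, small_cfg, matrix(rnorm(43), 1), FALSE, TRUE, FALSE)
  expect_equal(nrow(fw2$tokens[[1]]), 5)

  fwa <- cp$cpp_iat_forward(p, small_cfg, x)
  fwb <- cp$cpp_iat_forward(p, small_cfg, x)
  expect_identical(fwa$probs, fwb$probs)
})

test_that("attention rows are probability distributions in every layer/head", {
  p <- cp$cpp_iat_init(small_cfg, L, 3L)
  set.seed(5)
  fw <- cp$cpp_iat_forward(p, small_cfg, matrix(rnorm(L), 1), TRUE)
  A <- fw$attention[[1]]
  expect_true(all(A >= 0))
  for (s in seq_len(dim(A)[3])) {
    expect_true(all(abs(rowSums(A[, , s]) - 1) < 1e-6))
  }
})

test_that("encoder is equivariant under token permutation", {
  p <- cp$cpp_iat_init(small_cfg, L, 4L)
  set.seed(6)
  tok <- matrix(rnorm(5 * 8), 5, 8)  # 4 tokens + CLS
  out <- cp$cpp_iat_encode(p, small_cfg, tok, L)
  perm <- c(1, 2, 4, 3, 5)  # swap two non-CLS tokens
  out2 <- cp$cpp_iat_encode(p, small_cfg, tok[perm, ], L)
  expect_equal(out2$reps, out$reps[perm, ], tolerance = 1e-9)
  expect_equal(out2$probs, out$probs, tolerance = 1e-9)
})

test_that("zero classification head yields the uniform distribution", {
  p <- cp$cpp_iat_init(small_cfg, L, 7L)
  nh <- 4L * 8L + 4L
  p[(length(p) - nh + 1):length(p)] <- 0
  fw <- cp$cpp_iat_forward(p, small_cfg, matrix(rnorm(L), 1))
  expect_equal(as.numeric(fw$probs), rep(0.25, 4), tolerance = 1e-12)
})

test_that("analytic gradient matches central finite differences", {
  p <- cp$cpp_iat_init(small_cfg, L, 3L, sd = 0.1)
  set.seed(1)
  X <- matrix(rnorm(3 * L), 3, L)
  y <- c(0L, 2L, 3L)
  g <- cp$cpp_iat_grad(p, small_cfg, X, y, 0)
  set.seed(2)
  idx <- sample(length(p), 30)
  eps <- 1e-6
  fd <- vapply(idx, function(i) {
    pp <- p; pp[i] <- pp[i] + eps
    l1 <- cp$cpp_iat_grad(pp, small_cfg, X, y, 0)$loss
    pp[i] <- pp[i] - 2 * eps
    l0 <- cp$cpp_iat_grad(pp, small_cfg, X, y, 0)$loss
    (l1 - l0) / (2 * eps)
  }, numeric(1))
  expect_lt(max(abs(fd - g$grad[idx]) / pmax(abs(fd), 1e-4)), 1e-4)
})

ds_tiny <- quick_dataset(n = 24, seed = 61)

test_that("training decreases the loss and is deterministic given the seed", {
  fit <- iat_fit(ds_tiny, tiny_iat_config(seed = 5, epochs = 6))
  expect_lt(utils::tail(fit$train_log$loss, 1), fit$train_log$loss[1])
  fit2 <- iat_fit(ds_tiny, tiny_iat_config(seed = 5, epochs = 6))
  expect_identical(fit$params, fit2$params)
  expect_lt(abs(utils::tail(fit$train_log$loss, 1) -
                  utils::tail(fit2$train_log$loss, 1)), 1e-6)
  expect_error(iat_fit(ds_tiny, tiny_iat_config(), labels =
                         factor(rep("NR", 24), levels = levels(ds_tiny$labels))),
               "two classes")
})

test_that("prediction outputs proper probabilities and classes", {
  fit <- iat_fit(ds_tiny, tiny_iat_config(seed = 6, epochs = 2))
  pr <- predict(fit, ds_tiny, type = "prob")
  expect_equal(dim(pr), c(24, 4))
  expect_true(all(abs(rowSums(pr) - 1) < 1e-9))
  cl <- predict(fit, ds_tiny$records[[1]])
  expect_s3_class(cl, "factor")
  ev <- iat_evaluate(fit, ds_tiny, "test")
  expect_true(all(abs(rowSums(ev$confusion_norm) - 1) < 1e-9))
  expect_equal(sum(ev$confusion), length(ds_tiny$split$test))
})

test_that("saliency is a within-window distribution, slice-constant and
           amplitude-invariant", {
  fit <- iat_fit(ds_tiny, tiny_iat_config(seed = 7, epochs = 2))
  rec <- ds_tiny$records[[3]]
  for (method in c("cls", "rollout")) {
    sal <- iat_saliency(fit, rec, method = method)
    expect_equal(sum(sal$saliency), 1, tolerance = 1e-6)
    expect_true(all(sal$saliency >= 0))
    S <- fit$config$slice_len
    m <- matrix(sal$saliency, nrow = S)
    expect_true(all(apply(m, 2, function(col) diff(range(col)) == 0)))
  }
  # end-to-end amplitude invariance (the window is normalized)
  rec2 <- rec
  rec2$samples <- rec2$samples * 3.5
  rec2$clean_samples <- rec2$clean_samples * 3.5
  s1 <- iat_saliency(fit, rec)
  s2 <- iat_saliency(fit, rec2)
  expect_equal(s1$saliency, s2$saliency, tolerance = 1e-9)
})
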