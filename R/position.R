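# Wear-position assessment: per-frame FC embedding -> 1-D CNN over the frame
# sequence -> GRU summary -> 3-class orientation head, plus a discriminator
# that scores the summary against the encoded standard-position reference.
# Trained with a joint objective (orientation cross-entropy + adversarial
# discriminator loss); the discriminator acts as a verifier of correct
# placement, not as a generator critic.

#' Position-network architecture and training configuration
#'
#' @param frame_len frame length in samples (one GRU step per frame).
#' @param fc_dim width of the per-frame fully connected embedding.
#' @param conv_channels channels of the 1-D convolution over the embedded
#'   frame sequence.
#' @param conv_kernel convolution kernel (odd, in frames).
#' @param gru_hidden GRU hidden size (= summary dimension).
#' @param disc_hidden discriminator hidden width.
#' @param tolerance_threshold discriminator score above which the placement
#'   is judged within tolerance.
#' @param lambda_adv weight of the discriminator loss in the joint objective.
#' @param epochs,batch_size,lr training schedule (Adam).
#' @param augment_noise_sd upper bound of the relative white-noise
#'   augmentation applied to training windows (each window gets noise with
#'   standard deviation uniform on `[0, augment_noise_sd]` times its own).
#'   This keeps the discriminator keyed on waveform morphology rather than
#'   on the noise floor, which matters when judging inverse-transformed
#'   (noise-rescaled) windows.
#' @param seed integer seed; training is deterministic given it.
#' @return An object of class `position_config`.
#' @export
position_config <- function(frame_len = 50, fc_dim = 32, conv_channels = 32,
                            conv_kernel = 3, gru_hidden = 32, disc_hidden = 16,
                            tolerance_threshold = 0.5, lambda_adv = 1,
                            epochs = 200, batch_size = 32, lr = 1e-3,
                            augment_noise_sd = 0.5, seed = 1) {
  check_scalar(tolerance_threshold, "tolerance_threshold", 1e-9, 1 - 1e-9)
  if (conv_kernel %% 2 == 0) stop_invalid("conv_kernel must be odd")
  structure(list(frame_len = as.integer(frame_len), fc_dim = as.integer(fc_dim),
                 conv_channels = as.integer(conv_channels),
                 conv_kernel = as.integer(conv_kernel),
                 gru_hidden = as.integer(gru_hidden),
                 disc_hidden = as.integer(disc_hidden),
                 tolerance_threshold = tolerance_threshold,
                 lambda_adv = lambda_adv, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 augment_noise_sd = augment_noise_sd,
                 seed = as.integer(seed)),
            class = "position_config")
}

#' Fit the wear-position network
#'
#' Joint training of the shared feature extractor (FC embedding, 1-D CNN,
#' GRU), the 3-class orientation head, and the discriminator. Discriminator
#' targets are "real" for standard-position (`O0`) windows and "fake" for
#' misplaced windows; the standard-position reference vector is tracked as
#' an exponential moving average of `O0` summaries during training and
#' frozen to the mean training `O0` summary afterwards.
#'
#' @param dataset an `ecg_dataset` whose records cover all three
#'   orientations.
#' @param config a [position_config()].
#' @param spec the [filter_spec()] used to build model windows.
#' @param orientations optional orientation-label override (factor; used for
#'   shuffled-label controls).
#' @param verbose print per-epoch loss.
#' @return An object of class `position_model` with `params`, `config`,
#'   `reference` (the encoded standard-position vector), `train_log`.
#' @export
position_fit <- function(dataset, config = position_config(),
                         spec = filter_spec(), orientations = NULL,
                         verbose = FALSE) {
  if (!inherits(dataset, "ecg_dataset")) stop_invalid("dataset must be an ecg_dataset")
  X <- model_windows(dataset$records, spec = spec)
  ori <- if (is.null(orientations)) dataset$orientations else
    factor(orientations, levels = ORIENTATION_LEVELS)
  y <- as.integer(ori) - 1L
  tr <- dataset$split$train
  if (length(unique(y[tr])) < 3) {
    stop_invalid("all three orientations must be present in the training data")
  }
  input_len <- ncol(X)
  cfg <- unclass(config)
  np <- cpp_pos_nparams(cfg, input_len)
  params <- as.numeric(cpp_pos_init(cfg, input_len, config$seed))
  ref <- numeric(config$gru_hidden)
  opt <- adam_init(np)
  Xtr <- X[tr, , drop = FALSE]
  ytr <- y[tr]
  nb <- ceiling(length(tr) / config$batch_size)
  log <- data.frame(epoch = seq_len(config$epochs), loss = NA_real_)
  t0 <- proc.time()[3]
  for (ep in seq_len(config$epochs)) {
    sched <- with_rng(config$seed * 2000L + ep, list(
      ord = sample.int(length(tr)),
      nsd = stats::runif(length(tr), 0, config$augment_noise_sd),
      noise_seed = sample.int(.Machine$integer.max - 1L, 1)))
    ord <- sched$ord
    warm <- max(1, round(0.1 * config$epochs))
    lr_ep <- if (ep <= warm) {
      config$lr * ep / warm
    } else {
      config$lr * (0.55 + 0.45 * cos(pi * (ep - warm) / (config$epochs - warm)))
    }
    eploss <- 0
    for (b in seq_len(nb)) {
      pos_in_ep <- ((b - 1) * config$batch_size + 1):min(b * config$batch_size,
                                                         length(tr))
      idx <- ord[pos_in_ep]
      Xb <- Xtr[idx, , drop = FALSE]
      if (config$augment_noise_sd > 0) {
        Xb <- Xb + with_rng(sched$noise_seed + b, {
          matrix(stats::rnorm(length(Xb)), nrow(Xb)) * sched$nsd[pos_in_ep] *
            apply(Xb, 1, stats::sd)
        })
      }
      g <- cpp_pos_grad(params, cfg, Xb, ytr[idx],
                        ref, config$lambda_adv)
      st <- adam_step(opt, params, g$grad, lr_ep)
      opt <- st$state
      params <- st$params
      if (g$n_o0 > 0) {
        ref <- 0.95 * ref + 0.05 * (as.numeric(g$o0_sum) / g$n_o0)
      }
      eploss <- eploss + g$loss * length(idx)
    }
    log$loss[ep] <- eploss / length(tr)
    if (verbose) message(sprintf("epoch %2d  loss %.4f", ep, log$loss[ep]))
  }
  # freeze the standard-position reference to the mean O0 training summary
  o0 <- tr[ytr == 0L]
  if (length(o0)) {
    fw <- cpp_pos_forward(params, cfg, X[o0, , drop = FALSE], ref)
    ref <- colMeans(fw$summaries)
  }
  structure(list(params = params, config = config, input_len = input_len,
                 reference = ref, train_log = log, spec = spec,
                 n_train = length(tr), fit_seconds = proc.time()[3] - t0),
            class = "position_model")
}

pos_forward <- function(object, newdata, want_intermediate = FALSE) {
  X <- if (is.matrix(newdata)) newdata else
    model_windows(newdata, spec = object$spec, len = object$input_len)
  if (ncol(X) != object$input_len) stop_invalid("window length mismatch")
  cpp_pos_forward(object$params, unclass(object$config), X, object$reference,
                  want_intermediate)
}

#' Per-frame embedding of a window (position network)
#'
#' The deterministic fully connected projection of each frame into the
#' higher-dimensional feature space.
#'
#' @param model a `position_model`.
#' @param window numeric window of the model's input length.
#' @return Matrix (frames x `fc_dim`).
#' @export
position_embed <- function(model, window) {
  fw <- pos_forward(model, matrix(as.numeric(window), 1), TRUE)
  fw$intermediate[[1]]$embedding
}

#' Spatio-temporal summary vector of a window (position network)
#'
#' 1-D convolution over the embedded frame sequence followed by the GRU; the
#' final hidden state is the summary.
#'
#' @inheritParams position_embed
#' @return Numeric summary vector of length `gru_hidden`.
#' @export
position_features <- function(model, window) {
  fw <- pos_forward(model, matrix(as.numeric(window), 1), FALSE)
  as.numeric(fw$summaries[1, ])
}

#' Discriminator score of a summary against the standard-position reference
#'
#' @param model a `position_model`.
#' @param summary summary vector (length `gru_hidden`).
#' @param reference optional reference override (defaults to the model's
#'   frozen standard-position vector).
#' @return Probability in (0, 1) that the summary matches the
#'   standard-position manifold.
#' @export
discriminate <- function(model, summary, reference = model$reference) {
  if (length(summary) != length(reference)) stop_invalid("dimension mismatch")
  p <- model$params
  cfg <- model$config
  # discriminator head lives at the tail of the parameter vector
  np <- length(p)
  nd <- cfg$disc_hidden * (2 * cfg$gru_hidden) + cfg$disc_hidden +
    cfg$disc_hidden + 1
  off <- np - nd
  W1 <- matrix(p[off + seq_len(cfg$disc_hidden * 2 * cfg$gru_hidden)],
               cfg$disc_hidden, 2 * cfg$gru_hidden)
  off2 <- off + cfg$disc_hidden * 2 * cfg$gru_hidden
  b1 <- p[off2 + seq_len(cfg$disc_hidden)]
  w2 <- p[off2 + cfg$disc_hidden + seq_len(cfg$disc_hidden)]
  b2 <- p[np]
  u <- c(summary, summary - reference)
  d1 <- pmax(W1 %*% u + b1, 0)
  1 / (1 + exp(-(sum(w2 * d1) + b2)))
}

ADJUSTMENT_DEG <- c(O0 = 0, O120 = -120, O240 = 120)

#' Assess the wear position of records
#'
#' @param object a `position_model`.
#' @param newdata an `ecg_dataset`, list of records, single record, or
#'   window matrix.
#' @param ... unused.
#' @return A data frame with one row per record: predicted `orientation`,
#'   class probabilities `p_O0`/`p_O120`/`p_O240`, `discriminator_score`,
#'   `within_tolerance` (score at or above the configured threshold) and
#'   `adjustment_deg` (0 iff predicted `O0`; otherwise the rotation, in
#'   degrees, that maps the predicted orientation back to standard).
#' @export
predict.position_model <- function(object, newdata, ...) {
  fw <- pos_forward(object, newdata)
  pred <- ORIENTATION_LEVELS[max.col(fw$probs)]
  data.frame(orientation = factor(pred, levels = ORIENTATION_LEVELS),
             p_O0 = fw$probs[, 1], p_O120 = fw$probs[, 2],
             p_O240 = fw$probs[, 3],
             discriminator_score = as.numeric(fw$scores),
             within_tolerance = as.numeric(fw$scores) >=
               object$config$tolerance_threshold,
             adjustment_deg = unname(ADJUSTMENT_DEG[pred]))
}

#' Assess a single record's wear position
#'
#' @param model a `position_model`.
#' @param record an `ecg_record`.
#' @return An object of class `position_assessment` (the fields of
#'   [predict.position_model()] as a list).
#' @export
assess_position <- function(model, record) {
  df <- predict(model, record)
  out <- as.list(df[1, ])
  out$orientation <- as.character(out$orientation)
  structure(out, class = "position_assessment")
}

#' @export
print.position_assessment <- function(x, ...) {
  cat(sprintf("<position_assessment> %s (p = %.2f) | discriminator %.3f -> %s | adjust %+d deg\n",
              x$orientation, max(x$p_O0, x$p_O120, x$p_O240),
              x$discriminator_score,
              if (x$within_tolerance) "within tolerance" else "misplaced",
              as.integer(x$adjustment_deg)))
  invisible(x)
}

#' Apply a suggested wear-position adjustment to a synthetic record
#'
#' Inverts the misplacement transform of the orientation implied by the
#' assessment's adjustment (a rotation of -120 undoes `O120`, +120 undoes
#' `O240`). Requires a generator-backed record (the morphology warp is
#' re-synthesized from its stored state). When the predicted orientation
#' matches the record's true transform the inversion is exact up to the
#' rescaled noise.
#'
#' @param record a synthetic `ecg_record`.
#' @param assessment a `position_assessment` (or an adjustment in degrees).
#' @return The adjusted `ecg_record`.
#' @export
apply_adjustment <- function(record, assessment) {
  adj <- if (inherits(assessment, "position_assessment")) {
    assessment$adjustment_deg
  } else as.numeric(assessment)
  if (adj == 0) return(record)
  if (is.null(record$gen)) stop_invalid("adjustment requires a generator-backed record")
  assumed <- names(ADJUSTMENT_DEG)[match(adj, ADJUSTMENT_DEG)]
  pos <- position_model(assumed)
  w <- warp_signal(record)
  inv <- function(yv) {
    ((yv - pos$baseline_offset) / (pos$polarity * pos$amplitude_scale) -
       pos$morphology_mix * w) / (1 - pos$morphology_mix)
  }
  record$samples <- inv(record$samples)
  record$clean_samples <- inv(record$clean_samples)
  back <- ORIENTATION_LEVELS[((3L - orientation_rotation[[assumed]]) %% 3L) + 1L]
  record$orientation_label <- orientation_compose(record$orientation_label, back)
  if (!is.null(record$gen$position) &&
      record$gen$position$orientation == assumed) {
    record$gen$position <- NULL
  }
  record
}

#' Evaluate the position network on a dataset split
#'
#' @param model a `position_model`.
#' @param dataset an `ecg_dataset`.
#' @param subset `"test"`, `"train"` or `"all"`.
#' @return List with 3-class `accuracy`, `confusion`, and mean discriminator
#'   `score_by_orientation`.
#' @export
position_evaluate <- function(model, dataset, subset = c("test", "train", "all")) {
  subset <- match.arg(subset)
  idx <- switch(subset, test = dataset$split$test, train = dataset$split$train,
                all = seq_along(dataset$records))
  df <- predict(model, dataset$records[idx])
  truth <- dataset$orientations[idx]
  list(accuracy = mean(df$orientation == truth),
       confusion = table(truth = truth, predicted = df$orientation),
       score_by_orientation = tapply(df$discriminator_score, truth, mean),
       n = length(idx))
}

#' @export
print.position_model <- function(x, ...) {
  cat(sprintf("<position_model> 3-class wear-position net | %d params | input %d samples (%d frames)\n",
              length(x$params), x$input_len, x$input_len %/% x$config$frame_len))
  cat(sprintf("  fc %d, conv %d ch, gru %d | tolerance threshold %.2f | trained %d epochs (final loss %.4f)\n",
              x$config$fc_dim, x$config$conv_channels, x$config$gru_hidden,
              x$config$tolerance_threshold, x$config$epochs,
              utils::tail(x$train_log$loss, 1)))
  invisible(x)
}

#' @export
summary.position_model <- function(object, ...) {
  print(object)
  cat(sprintf("  training loss: %.4f -> %.4f\n", object$train_log$loss[1],
              utils::tail(object$train_log$loss, 1)))
  invisible(object)
}

#' @export
coef.position_model <- function(object, ...) object$params

#' Plot the position-network training-loss curve
#' @param x a `position_model`.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.position_model <- function(x, ...) {
  graphics::plot(x$train_log$epoch, x$train_log$loss, type = "b",
                 xlab = "epoch", ylab = "mean training loss", ...)
  invisible(x)
}
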