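# Interpretable attention transformer (IAT): R-level model interface over
# the compiled core. The classifier reads one normalized diagnostic window
# per record, slices it into tokens, and aggregates them through a CLS token
# whose final attention row doubles as the interpretability signal.

#' IAT architecture and training configuration
#'
#' Defaults are sized for CPU training: 0.1 s slices at 250 Hz, a 64-d
#' embedding, 2 pre-norm encoder layers with 4 heads, and a 128-d MLP. The
#' local-feature convolution runs over the whole window before slicing, so
#' its kernel (default 51 samples, about 0.2 s) gives each token context
#' beyond its own slice — important for rhythm (R-R interval) features.
#' Windows whose length is not a multiple of `slice_len` have the remainder
#' dropped (not padded), which avoids edge-token artefacts in the saliency.
#'
#' @param slice_len slice length in samples (one token per slice).
#' @param embed_dim token embedding dimension (divisible by `n_heads`).
#' @param n_heads attention heads per layer.
#' @param n_layers encoder layers.
#' @param mlp_dim hidden width of the per-token feed-forward block.
#' @param dropout dropout probability during training.
#' @param n_classes number of disease classes (4: NR, AR, AH, MI).
#' @param conv_kernel kernel length (odd, in samples) of the wide-scale
#'   feature convolution applied before slice projection. The convolution
#'   runs over the whole window, so this kernel sets how much beat-to-beat
#'   (rhythm) context each token carries; the default spans about half a
#'   second, enough to see both QRS complexes flanking any sample.
#' @param conv_kernel_local kernel length (odd) of the narrow-scale
#'   convolution; these channels keep morphology features localized to the
#'   waveform they describe, which is what ties the attention saliency to
#'   the right part of the trace.
#' @param conv_channels total convolution channels, split evenly between
#'   the two scales (must be even).
#' @param epochs,batch_size,lr training schedule (Adam optimizer).
#' @param seed integer seed controlling initialization, batch order and
#'   dropout; training is fully deterministic given the seed.
#' @param saliency `"cls"` (final-layer CLS attention, head-averaged) or
#'   `"rollout"` (attention rollout across layers).
#' @param window_s diagnostic window length (s). The window is cropped from
#'   the record's filtered trace: at a random position during training
#'   (temporal-crop augmentation, which teaches translation-invariant rhythm
#'   features), centred at prediction time.
#' @param augment_shift enable the random-crop augmentation.
#' @param augment_timescale half-range of the random time-rescaling applied
#'   to training crops (crops of `window_s * U(1 - r, 1 + r)` seconds are
#'   resampled to the model length). This enforces heart-rate-scale
#'   invariance, so rhythm irregularity is learned relative to the mean R-R
#'   interval; 0 disables it.
#' @param swa_frac fraction of the epoch budget (at the end, under the low
#'   cosine-tail learning rate) over which parameters are averaged
#'   (stochastic weight averaging); reduces run-to-run variance of the
#'   final model. 0 disables averaging.
#' @param attn_dropout also apply dropout to the attention probabilities
#'   (off by default; it spreads attention mass but was observed to blur
#'   the alignment between saliency and waveform regions).
#' @return An object of class `iat_config`.
#' @export
iat_config <- function(slice_len = 25, embed_dim = 64, n_heads = 4,
                       n_layers = 2, mlp_dim = 128, dropout = 0.1,
                       n_classes = 4, conv_kernel = 127,
                       conv_kernel_local = 127, conv_channels = 8,
                       epochs = 80, batch_size = 32, lr = 1e-3,
                       seed = 1, saliency = c("cls", "rollout"),
                       window_s = 8, augment_shift = TRUE,
                       augment_timescale = 0, swa_frac = 0.25,
                       attn_dropout = FALSE) {
  saliency <- match.arg(saliency)
  check_scalar(augment_timescale, "augment_timescale", 0, 0.5)
  check_scalar(swa_frac, "swa_frac", 0, 1)
  if (embed_dim %% n_heads != 0) stop_invalid("embed_dim must be divisible by n_heads")
  if (conv_kernel %% 2 == 0 || conv_kernel_local %% 2 == 0) {
    stop_invalid("conv kernels must be odd")
  }
  if (conv_channels %% 2 != 0) stop_invalid("conv_channels must be even")
  check_scalar(dropout, "dropout", 0, 1 - 1e-9)
  structure(list(slice_len = as.integer(slice_len),
                 embed_dim = as.integer(embed_dim),
                 n_heads = as.integer(n_heads),
                 n_layers = as.integer(n_layers),
                 mlp_dim = as.integer(mlp_dim),
                 dropout = dropout,
                 n_classes = as.integer(n_classes),
                 conv_kernel = as.integer(conv_kernel),
                 conv_kernel_local = as.integer(conv_kernel_local),
                 conv_channels = as.integer(conv_channels),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 lr = lr, seed = as.integer(seed), saliency = saliency,
                 window_s = window_s, augment_shift = isTRUE(augment_shift),
                 augment_timescale = augment_timescale, swa_frac = swa_frac,
                 attn_dropout = isTRUE(attn_dropout)),
            class = "iat_config")
}

#' Closed-form IAT parameter count
#'
#' @param config an [iat_config()].
#' @param input_len model input window length (samples).
#' @return Total number of trainable parameters.
#' @export
iat_param_count <- function(config, input_len) {
  S <- config$slice_len; D <- config$embed_dim; M <- config$mlp_dim
  K <- config$conv_kernel; K2 <- config$conv_kernel_local
  C <- config$conv_channels
  Tn <- input_len %/% S
  per_layer <- 2 * D + 4 * (D^2 + D) + 2 * D + (M * D + M) + (D * M + D)
  ((C / 2) * K + (C / 2) * K2 + C) + (D * S * C + D) + (Tn * D + D) +
    config$n_layers * per_layer + 2 * D +
    (config$n_classes * D + config$n_classes)
}

adam_init <- function(n) list(m = numeric(n), v = numeric(n), t = 0)

adam_step <- function(state, params, grad, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  list(state = state, params = params - lr * mhat / (sqrt(vhat) + eps))
}

dataset_windows <- function(dataset, spec, len = NULL) {
  X <- model_windows(dataset$records, spec = spec, len = len)
  list(X = X, y = as.integer(dataset$labels) - 1L,
       classes = levels(dataset$labels))
}

#' Fit the interpretable attention transformer
#'
#' Trains the 4-class heart-disease classifier on the training split of a
#' synthetic dataset by minimizing cross-entropy with Adam over a fixed
#' epoch budget. Records are reduced to one normalized diagnostic window
#' each (the full preprocessing chain). Training is deterministic given
#' `config$seed`.
#'
#' @param dataset an `ecg_dataset` from [make_dataset()] (all classes with
#'   positive mix should be present; a single-class dataset is an error).
#' @param config an [iat_config()].
#' @param spec the [filter_spec()] used to build model windows.
#' @param labels optional label override (factor, same length as records) —
#'   used e.g. for shuffled-label controls.
#' @param verbose print per-epoch loss.
#' @return An object of class `iat_model` with elements `params`, `config`,
#'   `input_len`, `classes`, `train_log` (per-epoch mean loss) and `spec`.
#' @examples
#' \donttest{
#' ds <- make_dataset(n = 40, seed = 2, duration = 6)
#' fit <- iat_fit(ds, iat_config(embed_dim = 16, n_heads = 2, n_layers = 1,
#'                               mlp_dim = 32, epochs = 2))
#' print(fit)
#' }
#' @export
iat_fit <- function(dataset, config = iat_config(), spec = filter_spec(),
                    labels = NULL, verbose = FALSE) {
  if (!inherits(dataset, "ecg_dataset")) stop_invalid("dataset must be an ecg_dataset")
  traces <- model_signals(dataset$records, spec)
  y <- as.integer(dataset$labels) - 1L
  classes <- levels(dataset$labels)
  if (!is.null(labels)) {
    labels <- factor(labels, levels = levels(dataset$labels))
    y <- as.integer(labels) - 1L
  }
  tr <- dataset$split$train
  if (length(unique(y[tr])) < 2) {
    stop_invalid("training data must contain at least two classes")
  }
  input_len <- round(config$window_s * dataset$fs)
  if (input_len > ncol(traces)) {
    stop_invalid("diagnostic window longer than the records")
  }
  max_off <- ncol(traces) - input_len
  center <- max_off %/% 2L
  cfg <- unclass(config)
  np <- cpp_iat_nparams(cfg, input_len)
  params <- as.numeric(cpp_iat_init(cfg, input_len, config$seed))
  opt <- adam_init(np)
  ytr <- y[tr]
  nb <- ceiling(length(tr) / config$batch_size)
  log <- data.frame(epoch = seq_len(config$epochs), loss = NA_real_)
  swa_start <- config$epochs - floor(config$swa_frac * config$epochs) + 1L
  swa_sum <- numeric(np)
  swa_n <- 0L
  t0 <- proc.time()[3]
  for (ep in seq_len(config$epochs)) {
    sched <- with_rng(config$seed * 1000L + ep, {
      scl <- if (config$augment_timescale > 0) {
        stats::runif(length(tr), 1 - config$augment_timescale,
                     1 + config$augment_timescale)
      } else rep(1, length(tr))
      wl <- pmin(round(input_len * scl), ncol(traces))
      offs <- if (config$augment_shift) {
        floor(stats::runif(length(tr)) * (ncol(traces) - wl + 1))
      } else pmax((ncol(traces) - wl) %/% 2L, 0L)
      list(ord = sample.int(length(tr)), wl = wl, offs = offs)
    })
    # linear warmup over the first tenth of the budget, then cosine decay to
    # lr/10 (stabilizes the early attention dynamics)
    warm <- max(1, round(0.1 * config$epochs))
    lr_ep <- if (ep <= warm) {
      config$lr * ep / warm
    } else {
      config$lr * (0.55 + 0.45 * cos(pi * (ep - warm) / (config$epochs - warm)))
    }
    eploss <- 0
    for (b in seq_len(nb)) {
      pos <- ((b - 1) * config$batch_size + 1):min(b * config$batch_size,
                                                   length(tr))
      idx <- sched$ord[pos]
      Xb <- matrix(0, length(idx), input_len)
      for (k in seq_along(idx)) {
        wl <- sched$wl[pos[k]]
        xw <- traces[tr[idx[k]], (sched$offs[pos[k]] + 1):(sched$offs[pos[k]] + wl)]
        if (wl != input_len) {
          xw <- stats::approx(seq_len(wl), xw, n = input_len)$y
        }
        Xb[k, ] <- suppressWarnings(normalize_window(xw))
      }
      dseed <- (config$seed %% 10000) * 1e5 + ep * 1000 + b
      g <- cpp_iat_grad(params, cfg, Xb, ytr[idx], dseed)
      st <- adam_step(opt, params, g$grad, lr_ep)
      opt <- st$state
      params <- st$params
      eploss <- eploss + g$loss * length(idx)
    }
    log$loss[ep] <- eploss / length(tr)
    if (config$swa_frac > 0 && ep >= swa_start) {
      swa_sum <- swa_sum + params
      swa_n <- swa_n + 1L
    }
    if (verbose) message(sprintf("epoch %2d  loss %.4f", ep, log$loss[ep]))
  }
  if (swa_n > 0) params <- swa_sum / swa_n
  structure(list(params = params, config = config, input_len = input_len,
                 classes = classes, train_log = log, spec = spec,
                 n_train = length(tr), fit_seconds = proc.time()[3] - t0),
            class = "iat_model")
}

windows_for <- function(object, newdata) {
  if (is.matrix(newdata)) {
    if (ncol(newdata) != object$input_len) {
      stop_invalid("window length does not match the fitted model")
    }
    return(newdata)
  }
  model_windows(newdata, spec = object$spec, len = object$input_len)
}

#' Predict disease class (or probabilities) from a fitted IAT
#'
#' @param object an `iat_model`.
#' @param newdata an `ecg_dataset`, a list of `ecg_record`s, a single record,
#'   or a matrix of prepared normalized windows.
#' @param type `"class"` or `"prob"`.
#' @param ... unused.
#' @return Factor of predicted classes, or a probability matrix with one row
#'   per record (rows sum to 1).
#' @export
predict.iat_model <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  X <- windows_for(object, newdata)
  probs <- cpp_iat_forward(object$params, unclass(object$config), X)$probs
  colnames(probs) <- object$classes
  if (type == "prob") return(probs)
  factor(object$classes[max.col(probs)], levels = object$classes)
}

#' Evaluate a fitted IAT on a dataset split
#'
#' @param model an `iat_model`.
#' @param dataset an `ecg_dataset`.
#' @param subset `"test"`, `"train"` or `"all"`.
#' @return An object of class `iat_eval`: `accuracy`, `confusion` (raw
#'   counts, truth in rows), `confusion_norm` (row-stochastic), `recall`
#'   (per-class, the diagonal of the normalized matrix).
#' @export
iat_evaluate <- function(model, dataset, subset = c("test", "train", "all")) {
  subset <- match.arg(subset)
  idx <- switch(subset, test = dataset$split$test, train = dataset$split$train,
                all = seq_along(dataset$records))
  if (!length(idx)) stop_invalid("empty evaluation subset")
  pred <- predict(model, dataset$records[idx])
  truth <- factor(dataset$labels[idx], levels = model$classes)
  cm <- table(truth = truth, predicted = pred)
  cmn <- sweep(cm, 1, pmax(rowSums(cm), 1), "/")
  structure(list(accuracy = mean(pred == truth),
                 confusion = cm, confusion_norm = cmn,
                 recall = diag(as.matrix(cmn)), n = length(idx),
                 subset = subset),
            class = "iat_eval")
}

#' @export
print.iat_eval <- function(x, ...) {
  cat(sprintf("<iat_eval> %s set, n = %d, accuracy %.3f\n", x$subset, x$n,
              x$accuracy))
  cat("per-class recall:\n")
  print(round(x$recall, 3))
  print(x$confusion)
  invisible(x)
}

#' Attention saliency for one window
#'
#' Maps the attention score matrix back onto the input signal: the CLS row
#' of the final layer is averaged over heads, the CLS self-score is dropped,
#' the remainder renormalized to sum 1 and spread uniformly across each
#' token's sample span. With `method = "rollout"`, head-averaged attention
#' (mixed with the identity and renormalized) is multiplied across layers
#' before the CLS row is read off.
#'
#' @param model an `iat_model`.
#' @param newdata one `ecg_record` or a single prepared window (numeric
#'   vector of the model's input length).
#' @param method `"cls"` or `"rollout"`; default from the model config.
#' @return An object of class `iat_saliency`: `saliency` (per-sample, sums
#'   to 1, constant within slices), `token_scores`, `spans` (0-based
#'   half-open sample spans per token), `method`.
#' @export
iat_saliency <- function(model, newdata, method = NULL) {
  if (is.null(method)) method <- model$config$saliency
  method <- match.arg(method, c("cls", "rollout"))
  offset <- 0L
  if (inherits(newdata, "ecg_record")) {
    X <- model_windows(newdata, spec = model$spec, len = model$input_len)
    offset <- attr(X, "offset")
  } else {
    X <- matrix(as.numeric(newdata), nrow = 1)
  }
  if (ncol(X) != model$input_len) stop_invalid("window length mismatch")
  fw <- cpp_iat_forward(model$params, unclass(model$config), X,
                        want_attention = TRUE)
  A <- fw$attention[[1]]  # (T+1) x (T+1) x (n_layers * n_heads)
  H <- model$config$n_heads
  nl <- model$config$n_layers
  T1 <- dim(A)[1]
  head_avg <- function(l) {
    out <- matrix(0, T1, T1)
    for (h in seq_len(H)) out <- out + A[, , (l - 1) * H + h]
    out / H
  }
  if (method == "cls") {
    cls_row <- head_avg(nl)[1, ]
  } else {
    R <- diag(T1)
    for (l in seq_len(nl)) {
      Ah <- 0.5 * head_avg(l) + 0.5 * diag(T1)
      Ah <- Ah / rowSums(Ah)
      R <- Ah %*% R
    }
    cls_row <- R[1, ]
  }
  tok <- cls_row[-1]            # drop the CLS self-score (degenerate attractor)
  tok <- tok / sum(tok)
  S <- model$config$slice_len
  Tn <- T1 - 1L
  sal <- numeric(model$input_len)
  for (t in seq_len(Tn)) {
    sal[((t - 1) * S + 1):(t * S)] <- tok[t] / S
  }
  # spans in the coordinates of the input record (0-based, half-open)
  spans <- cbind(start = offset + (seq_len(Tn) - 1L) * S,
                 end = offset + seq_len(Tn) * S)
  structure(list(saliency = sal, token_scores = tok, spans = spans,
                 window_offset = offset, method = method,
                 probs = fw$probs[1, ]),
            class = "iat_saliency")
}

#' @export
print.iat_saliency <- function(x, ...) {
  top <- order(x$token_scores, decreasing = TRUE)[1:min(3, length(x$token_scores))]
  cat(sprintf("<iat_saliency> method %s; top tokens: %s\n", x$method,
              paste(sprintf("[%d,%d)", x$spans[top, 1], x$spans[top, 2]),
                    collapse = " ")))
  invisible(x)
}

#' Saliency enrichment over ground-truth regions
#'
#' Mean per-sample saliency over the given spans divided by the global mean
#' per-sample saliency; values above 1 mean the model attends to those
#' regions more than uniformly.
#'
#' @param sal an `iat_saliency` (or bare saliency vector).
#' @param on,off 0-based half-open span boundaries in record coordinates
#'   (vectors, e.g. fiducial columns). Spans outside the model's diagnostic
#'   window are clipped.
#' @return Enrichment ratio (dimensionless).
#' @export
saliency_enrichment <- function(sal, on, off) {
  offset <- 0L
  v <- if (inherits(sal, "iat_saliency")) {
    offset <- sal$window_offset
    sal$saliency
  } else as.numeric(sal)
  idx <- unlist(mapply(function(a, b) if (b > a) (a + 1):b else integer(0),
                       on - offset, off - offset, SIMPLIFY = FALSE))
  idx <- idx[idx >= 1 & idx <= length(v)]
  if (!length(idx)) return(NA_real_)
  mean(v[idx]) / mean(v)
}

#' @export
print.iat_model <- function(x, ...) {
  cat(sprintf("<iat_model> %d-class IAT | %d params | input %d samples (%d tokens + CLS)\n",
              x$config$n_classes, length(x$params), x$input_len,
              x$input_len %/% x$config$slice_len))
  cat(sprintf("  layers %d, heads %d, embed %d, mlp %d | trained %d epochs on %d windows (final loss %.4f)\n",
              x$config$n_layers, x$config$n_heads, x$config$embed_dim,
              x$config$mlp_dim, x$config$epochs, x$n_train,
              utils::tail(x$train_log$loss, 1)))
  invisible(x)
}

#' @export
summary.iat_model <- function(object, ...) {
  cat(sprintf("Interpretable attention transformer (seed %d)\n", object$config$seed))
  print(object)
  cat(sprintf("  parameter count (closed form): %d\n",
              iat_param_count(object$config, object$input_len)))
  cat(sprintf("  training loss: %.4f (epoch 1) -> %.4f (epoch %d)\n",
              object$train_log$loss[1], utils::tail(object$train_log$loss, 1),
              nrow(object$train_log)))
  invisible(object)
}

#' @export
coef.iat_model <- function(object, ...) object$params

#' Plot the IAT training-loss curve
#' @param x an `iat_model`.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.iat_model <- function(x, ...) {
  graphics::plot(x$train_log$epoch, x$train_log$loss, type = "b",
                 xlab = "epoch", ylab = "mean training loss", ...)
  invisible(x)
}
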