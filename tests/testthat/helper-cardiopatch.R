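# Shared fixtures: everything is generated in code at test time.

# Small, fast dataset for structural tests (6 s records).
quick_dataset <- function(n = 24, seed = 3, duration = 6, ...) {
  make_dataset(n = n, seed = seed, duration = duration, ...)
}

# Miniature IAT sized for sub-second training in unit tests.
tiny_iat_config <- function(epochs = 3, ...) {
  iat_config(slice_len = 10, embed_dim = 16, n_heads = 2, n_layers = 1,
             mlp_dim = 32, conv_kernel = 7, conv_kernel_local = 7,
             conv_channels = 2, epochs = epochs,
             batch_size = 8, window_s = 4, dropout = 0.1, ...)
}

tiny_pos_config <- function(epochs = 3, ...) {
  position_config(frame_len = 25, fc_dim = 8, conv_channels = 8,
                  conv_kernel = 3, gru_hidden = 8, disc_hidden = 4,
                  epochs = epochs, batch_size = 8, ...)
}

# Direct access to the compiled kernels for structural tests.
cp <- asNamespace("cardiopatch")

# Indices (1-based) covered by half-open 0-based fiducial spans.
span_index <- function(on, off) {
  unlist(mapply(function(a, b) if (b > a) (a + 1):b else integer(0), on, off,
                SIMPLIFY = FALSE))
}
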