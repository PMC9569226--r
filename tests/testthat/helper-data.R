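# Small in-code fixtures shared across test files.

# a standardized (zero-mean, unit-sd columns) random regression instance
make_standardized_instance <- function(N, D, seed, k_signal = 5L,
                                       noise_sd = 1) {
  set.seed(seed)
  X <- matrix(stats::rnorm(N * D), N, D)
  X <- scale(X)
  attr(X, "scaled:center") <- NULL
  attr(X, "scaled:scale") <- NULL
  beta <- c(stats::rnorm(k_signal), rep(0, D - k_signal))
  y <- drop(X %*% beta) + stats::rnorm(N, sd = noise_sd)
  list(X = X, y = y - mean(y), beta = beta)
}

# tiny two-view dataset with mixed classes for network tests
make_tiny_mv <- function(N = 24L, seed = 1L) {
  gen <- generate_multiview(synth_config(N = N, region_counts = c(5L, 4L),
                                         s = 3L, seed = seed))
  gen
}

# a tiny initialized fusion network over a tiny dataset
make_tiny_net <- function(gen, widths = c(4L, 3L), K = 3L, seed = 2L,
                          mode = "fuse") {
  spec <- encoder_spec(widths, pretrain = FALSE)
  w <- vapply(gen$data$views, ncol, integer(1L))
  mvnet_init(w, spec, K = K, position = length(widths), mode = mode,
             seed = seed)
}

# mixed-class batch rows for a block-ordered synthetic dataset
mixed_rows <- function(gen, per_class = 4L) {
  y <- gen$data$labels
  c(which(y == levels(y)[1L])[seq_len(per_class)],
    which(y == levels(y)[2L])[seq_len(per_class)])
}
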