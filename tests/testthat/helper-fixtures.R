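# Shared fixtures: hand-built epochs, tiny architectures, separable
# feature sets. Everything is generated in code at test time.

# A raw epoch holding an arbitrary 3 x n sample matrix.
make_epoch <- function(samples, class_index = 0L, fs = 256,
                       subject = "T1") {
  cossvep:::new_epoch(samples, class_index, fs, subject)
}

# Pure sinusoid epoch on all three channels.
sine_epoch <- function(freq, fs = 256, duration = 4, class_index = 0L) {
  t <- (seq_len(fs * duration) - 1) / fs
  x <- sin(2 * pi * freq * t)
  make_epoch(rbind(x, x, x), class_index, fs)
}

# Small architecture for gradient and engine tests.
tiny_spec <- function(bins = 10) {
  cossvep:::new_cnn_spec(c(list(
    cossvep:::conv_layer(4L, c(3L, 1L), "preserve"),
    cossvep:::conv_layer(5L, c(3L, 1L), "valid"),
    cossvep:::conv_layer(6L, c(1L, 3L), "valid")
  ), cossvep:::classifier_head()), c(3L, bins), name = "tiny")
}

# Linearly separable labeled feature matrices: each class has a distinct
# high block of columns plus small uniform noise.
separable_features <- function(n, rows = 3, bins = 16, seed = 1) {
  cossvep:::with_seed(seed, {
    block <- bins %/% 4
    lapply(seq_len(n), function(i) {
      cls <- (i - 1L) %% 4L
      v <- matrix(stats::runif(rows * bins, 0, 0.2), rows, bins)
      cols <- (cls * block + 1):((cls + 1) * block)
      v[, cols] <- v[, cols] + 0.8
      cossvep:::new_features(v, seq_len(bins), cls, "F1", normalized = TRUE)
    })
  })
}

# Deterministic normalized feature object from a matrix.
feat_from_matrix <- function(v, class_index = 0L, subject = "S1",
                             normalized = TRUE, freq = NULL) {
  cossvep:::new_features(v, freq %||% seq_len(ncol(v)), class_index,
                         subject, normalized = normalized)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
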