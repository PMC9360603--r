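# Declarative compact CNN architectures for single-subject and fused
# inputs, with shape tracing against the printed layer tables.

conv_layer <- function(filters, kernel, padding, activation = "relu",
                       batch_norm = TRUE) {
  list(kind = "conv2d", filters = as.integer(filters),
       kernel = as.integer(kernel), padding = padding,
       activation = activation, batch_norm = batch_norm)
}

dense_layer <- function(units, activation = "none") {
  list(kind = "dense", units = as.integer(units), activation = activation)
}

new_cnn_spec <- function(layers, input_shape, n_classes = 4L, name = "cnn") {
  spec <- structure(list(
    layers = layers,
    input_shape = as.integer(input_shape),
    n_classes = as.integer(n_classes),
    name = name
  ), class = "cnn_spec")
  shape_trace(spec)  # errors if the stack is not shape-traceable
  spec
}

#' @export
print.cnn_spec <- function(x, ...) {
  cat(sprintf("<cnn_spec> %s: input (%d, %d), %d layers, %d classes, %s parameters\n",
              x$name, x$input_shape[1], x$input_shape[2], length(x$layers),
              x$n_classes, format(count_parameters(x), big.mark = ",")))
  tr <- shape_trace(x)
  conv_i <- 0
  for (i in seq_along(x$layers)) {
    l <- x$layers[[i]]
    desc <- switch(l$kind,
      conv2d = {
        conv_i <- conv_i + 1
        sprintf("conv2d %d x (%d,%d) %s -> (%d, %d)", l$filters, l$kernel[1],
                l$kernel[2], l$padding, tr[[conv_i + 1]][1], tr[[conv_i + 1]][2])
      },
      flatten = sprintf("flatten -> %d", attr(tr, "flatten_len")),
      dense = sprintf("dense %d (%s)", l$units, l$activation),
      dropout = sprintf("dropout %.2f", l$rate))
    cat(sprintf("  [%d] %s\n", i, desc))
  }
  invisible(x)
}

# Symmetric "same" padding amounts (beg, end) for kernel size k.
pad_amounts <- function(k) c((k - 1) %/% 2, k %/% 2)

#' Trace feature-map shapes through an architecture
#'
#' Propagates the spatial input shape through the convolutional stack,
#' reproducing the feature-size column of the printed layer tables: one
#' (rows, cols) entry for the input and one per convolution. The flatten
#' length and dense sizes are attached as attributes; an untraceable stack
#' (a dimension collapsing below 1) is a configuration error.
#'
#' @param spec A `cnn_spec`.
#' @return List of integer pairs, with attributes `flatten_len` and
#'   `dense_units`.
#' @export
shape_trace <- function(spec) {
  stopifnot(inherits(spec, "cnn_spec"))
  h <- spec$input_shape[1]; w <- spec$input_shape[2]
  maps <- 1L
  trace <- list(c(h, w))
  flatten_len <- NA_integer_
  dense_units <- integer(0)
  for (l in spec$layers) {
    if (l$kind == "conv2d") {
      if (l$padding == "valid") {
        h <- h - l$kernel[1] + 1L
        w <- w - l$kernel[2] + 1L
      }
      if (h < 1 || w < 1)
        stop_config("architecture not shape-traceable: feature map collapsed ",
                    "to (", h, ", ", w, ")")
      maps <- l$filters
      trace[[length(trace) + 1]] <- c(h, w)
    } else if (l$kind == "flatten") {
      flatten_len <- h * w * maps
    } else if (l$kind == "dense") {
      dense_units <- c(dense_units, l$units)
    }
  }
  if (length(dense_units) == 0 ||
      dense_units[length(dense_units)] != spec$n_classes)
    stop_config("stack must end in a dense layer with n_classes units")
  structure(trace, flatten_len = as.integer(flatten_len),
            dense_units = dense_units)
}

#' Count trainable parameters of an architecture
#'
#' Convolution weights and biases, batch-norm scale/shift pairs, and dense
#' weights/biases (batch-norm running statistics are not trained).
#'
#' @param spec A `cnn_spec`.
#' @return Integer parameter count.
#' @export
count_parameters <- function(spec) {
  stopifnot(inherits(spec, "cnn_spec"))
  tr <- shape_trace(spec)
  maps <- 1L
  total <- 0
  width <- NA_integer_
  for (l in spec$layers) {
    if (l$kind == "conv2d") {
      total <- total + prod(l$kernel) * maps * l$filters + l$filters
      if (isTRUE(l$batch_norm)) total <- total + 2 * l$filters
      maps <- l$filters
    } else if (l$kind == "flatten") {
      width <- attr(tr, "flatten_len")
    } else if (l$kind == "dense") {
      total <- total + width * l$units + l$units
      width <- l$units
    }
  }
  as.integer(total)
}

classifier_head <- function(n_classes = 4L) {
  list(list(kind = "flatten"),
       dense_layer(8L, "none"),
       list(kind = "dropout", rate = 0.5),
       dense_layer(n_classes, "softmax"))
}

#' Single-subject compact CNN
#'
#' Four convolutions — 16 x (3,1) preserving, 32 x (3,1) valid (collapsing
#' the three electrode rows to one), 32 x (1,3) preserving, 64 x (1,3)
#' valid — each followed by batch normalization and ReLU, then flatten, a
#' linear dense layer of 8 units, dropout 0.5, and a 4-way softmax.
#'
#' @param input_shape `(channels, bins)`; channels must be 3 and bins >= 5.
#' @return A `cnn_spec`.
#' @export
#' @examples
#' spec <- build_single_cnn(c(3, 78))
#' shape_trace(spec)
build_single_cnn <- function(input_shape = c(3, 78)) {
  if (input_shape[1] != 3)
    stop_config("single-subject network expects 3 input channels")
  if (input_shape[2] < 5)
    stop_config("at least 5 frequency bins are required, got ", input_shape[2])
  new_cnn_spec(c(list(
    conv_layer(16L, c(3L, 1L), "preserve"),
    conv_layer(32L, c(3L, 1L), "valid"),
    conv_layer(32L, c(1L, 3L), "preserve"),
    conv_layer(64L, c(1L, 3L), "valid")
  ), classifier_head()), input_shape, name = "single")
}

#' Parallel-fusion compact CNN
#'
#' For K = 2 this is exactly the printed two-subject stack: 16 x (6,1)
#' preserving, then channel-collapsing valid convolutions 32 x (3,1),
#' 64 x (3,1), 64 x (2,1) taking 6 -> 4 -> 2 -> 1 rows, then frequency
#' convolutions 128 x (1,3) preserving and 256 x (1,3) valid. For K > 2
#' the same scheme generalizes: a (3K,1) preserving input convolution,
#' (3,1) valid collapses (a final (2,1) if two rows remain) with filter
#' counts doubling from 32 and the last collapse repeating its
#' predecessor's count when finishing at (2,1), then the two frequency
#' convolutions at 2x and 4x the last collapse count.
#'
#' @param n_subjects Number of fused subjects K (>= 2; use
#'   [build_single_cnn()] for one subject).
#' @param bins Frequency bins per subject B.
#' @return A `cnn_spec` with input shape `(3K, B)`.
#' @export
build_parallel_cnn <- function(n_subjects = 2, bins = 78) {
  if (n_subjects < 2)
    stop_config("parallel fusion network requires >= 2 subjects; ",
                "use build_single_cnn() for a single subject")
  if (bins < 5) stop_config("at least 5 frequency bins are required")
  rows <- 3L * as.integer(n_subjects)
  layers <- list(conv_layer(16L, c(rows, 1L), "preserve"))
  r <- rows
  filters <- 16L
  while (r > 1) {
    if (r > 2) {
      filters <- filters * 2L
      layers[[length(layers) + 1]] <- conv_layer(filters, c(3L, 1L), "valid")
      r <- r - 2L
    } else {
      layers[[length(layers) + 1]] <- conv_layer(filters, c(2L, 1L), "valid")
      r <- r - 1L
    }
  }
  layers[[length(layers) + 1]] <- conv_layer(filters * 2L, c(1L, 3L), "preserve")
  layers[[length(layers) + 1]] <- conv_layer(filters * 4L, c(1L, 3L), "valid")
  new_cnn_spec(c(layers, classifier_head()), c(rows, bins), name = "parallel")
}

#' Serial-fusion compact CNN
#'
#' Same shape pattern as the single-subject network with tripled filter
#' counts for two subjects — 48 x (3,1) preserving, 96 x (3,1) valid,
#' 96 x (1,3) preserving, 192 x (1,3) valid — consuming the 3 x (K B)
#' serially concatenated input.
#'
#' @param n_subjects Number of fused subjects K (>= 2).
#' @param bins Frequency bins per subject B.
#' @param total_bins Total input columns; defaults to `n_subjects * bins`
#'   but may be given directly to build a net for an arbitrary serial
#'   input length.
#' @return A `cnn_spec` with input shape `(3, total_bins)`.
#' @export
build_serial_cnn <- function(n_subjects = 2, bins = 78,
                             total_bins = n_subjects * bins) {
  if (n_subjects < 2)
    stop_config("serial fusion network requires >= 2 subjects; ",
                "use build_single_cnn() for a single subject")
  if (total_bins < 5) stop_config("at least 5 input columns are required")
  new_cnn_spec(c(list(
    conv_layer(48L, c(3L, 1L), "preserve"),
    conv_layer(96L, c(3L, 1L), "valid"),
    conv_layer(96L, c(1L, 3L), "preserve"),
    conv_layer(192L, c(1L, 3L), "valid")
  ), classifier_head()), c(3L, as.integer(total_bins)), name = "serial")
}

#' Build the architecture matching a fusion mode
#'
#' @param mode One of `"single"`, `"parallel"`, `"serial"`, `"average"`
#'   (averaging shares the single-subject structure).
#' @param n_subjects Number of fused subjects (ignored for single/average).
#' @param bins Frequency bins per subject.
#' @return A `cnn_spec`.
#' @export
build_cnn_for_mode <- function(mode, n_subjects = 2, bins = 78) {
  switch(mode,
    single = ,
    average = build_single_cnn(c(3, bins)),
    parallel = build_parallel_cnn(n_subjects, bins),
    serial = build_serial_cnn(n_subjects, bins),
    stop_config("unknown mode: ", mode))
}
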