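# Two-stage transfer-learning protocol: Adam pretraining on a large
# source set, shallow-layer freezing, fine-tuning on a small target set.

#' Training configuration
#'
#' Defaults follow the published protocol: Adam with learning rate 0.001,
#' 80 epochs and mini-batches of 16 for pretraining; for fine-tuning the
#' epoch count is reset to 40 and the rate lowered to 1e-4 (the protocol
#' asks only for "a small" rate; one tenth of the pretraining rate is the
#' documented default).
#'
#' @param stage `"pretrain"` or `"finetune"`.
#' @param learning_rate Adam step size (> 0).
#' @param epochs Number of passes over the training set (>= 1).
#' @param batch_size Mini-batch size (>= 1).
#' @param seed Integer seed driving shuffling, dropout and (for fresh
#'   models) weight initialization.
#' @return An object of class `train_config`.
#' @export
train_config <- function(stage = c("pretrain", "finetune"),
                         learning_rate = NULL, epochs = NULL,
                         batch_size = 16, seed = 1L) {
  stage <- match.arg(stage)
  learning_rate <- learning_rate %||% switch(stage, pretrain = 0.001,
                                             finetune = 1e-4)
  epochs <- epochs %||% switch(stage, pretrain = 80L, finetune = 40L)
  if (learning_rate <= 0) stop_config("learning_rate must be positive")
  if (epochs < 1) stop_config("epochs must be >= 1")
  if (batch_size < 1) stop_config("batch_size must be >= 1")
  structure(list(stage = stage, learning_rate = as.double(learning_rate),
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 optimizer = "adam", seed = as.integer(seed)),
            class = "train_config")
}

#' Convert a feature list to a training array and labels
#'
#' @param features List of `ssvep_features` or `ssvep_fused` (all the same
#'   shape).
#' @return List with `x` (N x H x W array) and `y` (0-based labels).
#' @export
feature_set <- function(features) {
  stopifnot(length(features) > 0)
  d <- dim(features[[1]]$values)
  x <- array(0, c(length(features), d[1], d[2]))
  for (i in seq_along(features)) x[i, , ] <- features[[i]]$values
  y <- vapply(features, function(f) f$class_index, integer(1))
  list(x = x, y = y)
}

adam_init <- function(params) {
  lapply(params, function(p) {
    if (is.null(p)) return(NULL)
    lapply(p[intersect(names(p), c("W", "b", "gamma", "beta"))],
           function(v) list(m = v * 0, v = v * 0))
  })
}

# Core optimization loop: seeded shuffling, Adam updates skipping frozen
# layers, batch-norm running statistics updated only on trainable layers.
train_loop <- function(model, x, y, config) {
  n <- dim(x)[1]
  yoh <- one_hot(y, model$spec$n_classes)
  frozen <- model$frozen_layers %||% integer(0)
  state <- adam_init(model$params)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  lr <- config$learning_rate
  step <- 0L
  with_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      perm <- sample(n)
      starts <- seq(1, n, by = config$batch_size)
      for (s in starts) {
        idx <- perm[s:min(s + config$batch_size - 1, n)]
        xb <- x[idx, , , drop = FALSE]
        yb <- yoh[idx, , drop = FALSE]
        fw <- forward_internal(model, xb, train = TRUE, collect = TRUE)
        model <- fw$model
        dlogits <- (fw$probs - yb) / length(idx)
        grads <- backward_internal(model, fw$caches, dlogits, length(idx))
        step <- step + 1L
        corr1 <- 1 - b1^step
        corr2 <- 1 - b2^step
        for (i in seq_along(model$params)) {
          if (i %in% frozen || is.null(grads[[i]])) next
          for (nm in names(state[[i]])) {
            g <- grads[[i]][[nm]]
            st <- state[[i]][[nm]]
            st$m <- b1 * st$m + (1 - b1) * g
            st$v <- b2 * st$v + (1 - b2) * g * g
            state[[i]][[nm]] <- st
            model$params[[i]][[nm]] <- model$params[[i]][[nm]] -
              lr * (st$m / corr1) / (sqrt(st$v / corr2) + eps)
          }
        }
      }
    }
  })
  model
}

#' Pretrain a network on a source feature set
#'
#' Stage one of the transfer protocol: all layers trainable, Adam on the
#' cross-entropy loss. Reproducible: the same spec, data and seed give
#' bit-identical parameters.
#'
#' @param spec A `cnn_spec`.
#' @param features List of `ssvep_features`/`ssvep_fused`, or a list with
#'   elements `x` and `y` as returned by [feature_set()].
#' @param config A [train_config()] with `stage = "pretrain"`.
#' @return A trained `cnn_model`.
#' @export
pretrain <- function(spec, features, config = train_config("pretrain")) {
  stopifnot(inherits(spec, "cnn_spec"), inherits(config, "train_config"))
  if (config$stage != "pretrain")
    stop_config("pretrain() requires a config with stage = 'pretrain'")
  fs <- if (!is.null(features$x)) features else feature_set(features)
  x <- as_batch_array(fs$x, spec)
  model <- init_model(spec, seed = derive_seed(config$seed, 11L))
  train_loop(model, x, fs$y, config)
}

#' Freeze the shallow convolutional layers of a pretrained model
#'
#' The default policy freezes the first half of the convolution stack
#' (rounded down): for the single-subject network, convs 1–2 of 4; for the
#' two-subject parallel network, convs 1–3 of 6. Frozen layers take no
#' gradient updates and their batch-norm running statistics are pinned
#' (the layer runs in inference mode), so every frozen tensor is
#' bit-identical across fine-tuning.
#'
#' @param model A pretrained `cnn_model`.
#' @param policy `"first_half_convs"` or `"none"`.
#' @return The model with `frozen_layers` set.
#' @export
freeze_shallow <- function(model, policy = "first_half_convs") {
  stopifnot(inherits(model, "cnn_model"))
  conv_idx <- which(vapply(model$spec$layers, function(l)
    l$kind == "conv2d", logical(1)))
  model$frozen_layers <- switch(policy,
    first_half_convs = conv_idx[seq_len(length(conv_idx) %/% 2)],
    none = integer(0),
    stop_config("unknown freeze policy: ", policy))
  model
}

#' Fine-tune a frozen model on a small target set
#'
#' Stage two of the transfer protocol: only unfrozen layers are updated
#' (default 40 epochs at learning rate 1e-4); the optimizer state is
#' re-initialized at the stage boundary.
#'
#' @param model A `cnn_model` whose freeze set has been declared via
#'   [freeze_shallow()].
#' @param features Target feature list or [feature_set()] result.
#' @param config A [train_config()] with `stage = "finetune"`.
#' @return The fine-tuned `cnn_model`.
#' @export
finetune <- function(model, features, config = train_config("finetune")) {
  stopifnot(inherits(model, "cnn_model"), inherits(config, "train_config"))
  if (config$stage != "finetune")
    stop_config("finetune() requires a config with stage = 'finetune'")
  if (is.null(model$frozen_layers))
    stop_config("declare the freeze set with freeze_shallow() before fine-tuning")
  trainable <- setdiff(which(!vapply(model$params, is.null, logical(1))),
                       model$frozen_layers)
  if (!length(trainable))
    stop_config("no trainable layers remain after freezing")
  fs <- if (!is.null(features$x)) features else feature_set(features)
  x <- as_batch_array(fs$x, model$spec)
  train_loop(model, x, fs$y, config)
}

#' Save / load model checkpoints
#'
#' Checkpoints are JSON text holding the architecture spec, its integrity
#' hash, all parameter tensors and the freeze set; loading verifies the
#' hash and restores tensors exactly, so forward outputs round-trip
#' bit-identically.
#'
#' @param model A `cnn_model`.
#' @param path File path.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the restored `cnn_model`.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "cnn_model"))
  payload <- list(
    format = "cossvep-checkpoint-1",
    spec = unclass(model$spec),
    spec_hash = model$spec_hash,
    frozen_layers = model$frozen_layers %||% "unset",
    # hex-float encoding keeps tensors bit-exact across the text round-trip
    params = lapply(model$params, function(p) {
      if (is.null(p)) return(NULL)
      lapply(p, function(v) list(dim = dim(v) %||% length(v),
                                 data = sprintf("%a", as.vector(v))))
    })
  )
  writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                              null = "null"), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  payload <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                      error = function(e)
                        stop_integrity("unreadable checkpoint: ",
                                       conditionMessage(e)))
  if (!identical(payload$format %||% "", "cossvep-checkpoint-1"))
    stop_integrity("not a cossvep checkpoint: ", path)
  spec <- payload$spec
  spec$layers <- lapply(spec$layers, function(l) {
    if (!is.null(l$kernel)) l$kernel <- as.integer(unlist(l$kernel))
    if (!is.null(l$filters)) l$filters <- as.integer(l$filters)
    if (!is.null(l$units)) l$units <- as.integer(l$units)
    l
  })
  spec$input_shape <- as.integer(unlist(spec$input_shape))
  spec$n_classes <- as.integer(spec$n_classes)
  spec <- structure(spec, class = "cnn_spec")
  h <- spec_hash(spec)
  if (!identical(h, payload$spec_hash))
    stop_integrity("spec hash mismatch: checkpoint declares ",
                   payload$spec_hash, " but spec hashes to ", h)
  model <- init_model(spec, seed = 0L)
  for (i in seq_along(payload$params)) {
    p <- payload$params[[i]]
    if (is.null(p)) next
    for (nm in names(p)) {
      v <- as.double(unlist(p[[nm]]$data, use.names = FALSE))
      dm <- as.integer(unlist(p[[nm]]$dim))
      if (length(dm) > 1) dim(v) <- dm
      model$params[[i]][[nm]] <- v
    }
  }
  fl <- payload$frozen_layers
  model$frozen_layers <- if (identical(fl, "unset")) NULL else
    as.integer(unlist(fl))
  model
}
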