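# Deterministic pure-R CNN engine. Convolutions are computed as matrix
# products via precomputed im2col index maps; batch normalization, ReLU,
# dropout, dense layers and the softmax head follow the architecture spec.
# Gradients are exact (verified against numerical differentiation in the
# test suite) and optimization uses Adam.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.9

# Precompute im2col geometry for a conv layer applied to (h, w, c) input.
conv_geometry <- function(h, w, c, kernel, padding) {
  kh <- kernel[1]; kw <- kernel[2]
  if (padding == "preserve") {
    ph <- pad_amounts(kh); pw <- pad_amounts(kw)
  } else {
    ph <- c(0L, 0L); pw <- c(0L, 0L)
  }
  hp <- h + sum(ph); wp <- w + sum(pw)
  ho <- hp - kh + 1L; wo <- wp - kw + 1L
  p_out <- ho * wo
  k_in <- kh * kw * c
  # idx[p, k]: column in the flattened (hp*wp*c) padded input holding patch
  # element k of output position p (p = ho-major, k = kh-major).
  idx <- matrix(0L, p_out, k_in)
  for (ci in seq_len(c)) for (kwi in seq_len(kw)) for (khi in seq_len(kh)) {
    k <- khi + kh * ((kwi - 1L) + kw * (ci - 1L))
    hcoord <- rep(seq_len(ho) + khi - 1L, times = wo)
    wcoord <- rep(seq_len(wo) + kwi - 1L, each = ho)
    idx[, k] <- hcoord + hp * ((wcoord - 1L) + wp * (ci - 1L))
  }
  idxvec <- as.vector(idx)
  uidx <- sort(unique(idxvec))
  list(h = h, w = w, c = c, kh = kh, kw = kw, ph = ph, pw = pw,
       hp = hp, wp = wp, ho = ho, wo = wo, p_out = p_out, k_in = k_in,
       idxvec = idxvec, uidx = uidx, padded = any(c(ph, pw) > 0))
}

build_geometry <- function(spec) {
  h <- spec$input_shape[1]; w <- spec$input_shape[2]; c <- 1L
  geoms <- vector("list", length(spec$layers))
  width <- NA_integer_
  for (i in seq_along(spec$layers)) {
    l <- spec$layers[[i]]
    if (l$kind == "conv2d") {
      g <- conv_geometry(h, w, c, l$kernel, l$padding)
      geoms[[i]] <- g
      h <- g$ho; w <- g$wo; c <- l$filters
    } else if (l$kind == "flatten") {
      width <- h * w * c
      geoms[[i]] <- list(len = width)
    } else if (l$kind == "dense") {
      geoms[[i]] <- list(fan_in = width, units = l$units)
      width <- l$units
    }
  }
  geoms
}

#' Initialize an untrained model from an architecture spec
#'
#' He-normal weight initialization for convolutions and dense layers,
#' unit/zero batch-norm scale and shift, zero running statistics; all
#' draws come from the given seed, so initialization is reproducible.
#'
#' @param spec A `cnn_spec`.
#' @param seed Integer seed for weight initialization.
#' @return An object of class `cnn_model`.
#' @export
init_model <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "cnn_spec"))
  geoms <- build_geometry(spec)
  params <- with_seed(seed, lapply(seq_along(spec$layers), function(i) {
    l <- spec$layers[[i]]
    g <- geoms[[i]]
    if (l$kind == "conv2d") {
      fan_in <- g$k_in
      p <- list(W = matrix(stats::rnorm(g$k_in * l$filters, 0,
                                        sqrt(2 / fan_in)), g$k_in, l$filters),
                b = numeric(l$filters))
      if (isTRUE(l$batch_norm)) {
        p$gamma <- rep(1, l$filters)
        p$beta <- numeric(l$filters)
        p$rmean <- numeric(l$filters)
        p$rvar <- rep(1, l$filters)
      }
      p
    } else if (l$kind == "dense") {
      list(W = matrix(stats::rnorm(g$fan_in * l$units, 0,
                                   sqrt(2 / g$fan_in)), g$fan_in, l$units),
           b = numeric(l$units))
    } else NULL
  }))
  structure(list(spec = spec, params = params, geoms = geoms,
                 frozen_layers = NULL, spec_hash = spec_hash(spec)),
            class = "cnn_model")
}

#' @export
print.cnn_model <- function(x, ...) {
  cat(sprintf("<cnn_model> %s (spec %s), %s parameters%s\n",
              x$spec$name, x$spec_hash,
              format(count_parameters(x$spec), big.mark = ","),
              if (length(x$frozen_layers))
                paste0(", frozen layers {",
                       paste(x$frozen_layers, collapse = ", "), "}") else ""))
  invisible(x)
}

# Canonical hash of an architecture spec for checkpoint integrity.
spec_hash <- function(spec) {
  fnv1a_hash(jsonlite::toJSON(unclass(spec), auto_unbox = TRUE, digits = NA))
}

add_rowvec <- function(m, v) m + rep(v, each = nrow(m))

# Coerce a batch (list of matrices / single matrix / N x H x W array) to
# an (N, H, W) array checked against the spec input shape.
as_batch_array <- function(batch, spec) {
  shape <- spec$input_shape
  if (is.list(batch)) {
    mats <- lapply(batch, function(b) if (is.matrix(b)) b else b$values)
    arr <- array(0, c(length(mats), shape[1], shape[2]))
    for (i in seq_along(mats)) {
      m <- mats[[i]]
      if (!all(dim(m) == shape))
        stop_domain("input shape mismatch: expected (", shape[1], ", ",
                    shape[2], "), got (", nrow(m), ", ", ncol(m), ")")
      arr[i, , ] <- m
    }
    arr
  } else if (is.matrix(batch)) {
    as_batch_array(list(batch), spec)
  } else {
    d <- dim(batch)
    if (length(d) != 3 || d[2] != shape[1] || d[3] != shape[2])
      stop_domain("input shape mismatch: expected (N, ", shape[1], ", ",
                  shape[2], "), got (", paste(d, collapse = ", "), ")")
    batch
  }
}

# Full forward pass. Returns list(probs, caches); caches only when
# collect = TRUE (training). `train` switches batch-norm statistics and
# dropout on; frozen layers always run batch norm in inference mode and
# never update running statistics.
forward_internal <- function(model, x, train = FALSE, collect = FALSE) {
  spec <- model$spec
  n <- dim(x)[1]
  a <- x
  dim(a) <- c(dim(x), 1L)
  caches <- if (collect) vector("list", length(spec$layers)) else NULL
  for (i in seq_along(spec$layers)) {
    l <- spec$layers[[i]]
    g <- model$geoms[[i]]
    p <- model$params[[i]]
    if (l$kind == "conv2d") {
      if (g$padded) {
        xp <- array(0, c(n, g$hp, g$wp, g$c))
        xp[, g$ph[1] + seq_len(g$h), g$pw[1] + seq_len(g$w), ] <- a
      } else xp <- a
      dim(xp) <- c(n, g$hp * g$wp * g$c)
      has_bn <- isTRUE(l$batch_norm)
      use_batch_stats <- has_bn && train && !(i %in% model$frozen_layers)
      fwd <- cpp_layer_fwd(xp, g$idxvec, p$W, p$b,
                           p$gamma %||% numeric(0), p$beta %||% numeric(0),
                           p$rmean %||% numeric(0), p$rvar %||% numeric(0),
                           BN_EPS, g$p_out, has_bn, use_batch_stats,
                           identical(l$activation, "relu"), collect)
      if (use_batch_stats) {
        model$params[[i]]$rmean <- BN_MOMENTUM * p$rmean +
          (1 - BN_MOMENTUM) * as.vector(fwd$mu)
        model$params[[i]]$rvar <- BN_MOMENTUM * p$rvar +
          (1 - BN_MOMENTUM) * as.vector(fwd$var)
      }
      if (collect) {
        caches[[i]] <- list(out = fwd$out, xcol = fwd$Xcol, zn = fwd$zn,
                            inv = as.vector(fwd$inv),
                            batch_stats = use_batch_stats)
      }
      a <- fwd$out
      dim(a) <- c(n, g$ho, g$wo, l$filters)
    } else if (l$kind == "flatten") {
      dim(a) <- c(n, g$len)
    } else if (l$kind == "dense") {
      if (collect) caches[[i]] <- list(a_in = a)
      z <- add_rowvec(a %*% p$W, p$b)
      if (identical(l$activation, "softmax")) {
        zs <- z - apply(z, 1, max)
        e <- exp(zs)
        a <- e / rowSums(e)
      } else {
        a <- z
      }
    } else if (l$kind == "dropout") {
      if (train) {
        mask <- matrix(stats::runif(length(a)) >= l$rate,
                       nrow(a), ncol(a)) / (1 - l$rate)
        a <- a * mask
        if (collect) caches[[i]] <- list(mask = mask)
      }
    }
  }
  list(probs = a, caches = caches, model = model)
}

# Backward pass from the softmax-logit gradient. Returns a list of
# per-layer gradients mirroring model$params.
backward_internal <- function(model, caches, dlogits, n) {
  spec <- model$spec
  grads <- vector("list", length(spec$layers))
  d <- dlogits
  for (i in rev(seq_along(spec$layers))) {
    l <- spec$layers[[i]]
    g <- model$geoms[[i]]
    p <- model$params[[i]]
    cc <- caches[[i]]
    if (l$kind == "dense") {
      grads[[i]] <- list(W = crossprod(cc$a_in, d), b = colSums(d))
      d <- tcrossprod(d, p$W)
    } else if (l$kind == "dropout") {
      if (!is.null(cc)) d <- d * cc$mask
    } else if (l$kind == "flatten") {
      # no-op: the preceding conv branch reinterprets the linear layout
    } else if (l$kind == "conv2d") {
      dim(d) <- c(n * g$p_out, l$filters)
      has_bn <- isTRUE(l$batch_norm)
      cb <- cpp_layer_bwd(d, cc$out, cc$zn %||% matrix(0, 0, 0),
                          cc$inv %||% numeric(0),
                          p$gamma %||% numeric(0), cc$xcol, p$W, g$idxvec,
                          g$p_out, g$hp * g$wp * g$c, has_bn,
                          isTRUE(cc$batch_stats),
                          identical(l$activation, "relu"))
      gr <- list(W = cb$dW, b = as.vector(cb$db))
      if (has_bn) {
        gr$gamma <- as.vector(cb$dgamma)
        gr$beta <- as.vector(cb$dbeta)
      }
      grads[[i]] <- gr
      dxp <- cb$dxp
      if (g$padded) {
        dim(dxp) <- c(n, g$hp, g$wp, g$c)
        dxp <- dxp[, g$ph[1] + seq_len(g$h), g$pw[1] + seq_len(g$w), ,
                   drop = FALSE]
      }
      d <- dxp
      dim(d) <- c(n, g$h * g$w * g$c)
    }
  }
  grads
}

#' Forward pass: class probabilities for a batch
#'
#' Runs the network in evaluation mode (dropout disabled, batch norm using
#' running statistics), returning one probability row per example.
#'
#' @param model A `cnn_model`.
#' @param batch A list of feature matrices (or `ssvep_features` /
#'   `ssvep_fused` objects), a single matrix, or an (N, H, W) array
#'   matching the spec input shape.
#' @return N x n_classes matrix of softmax probabilities (rows sum to 1).
#' @export
forward <- function(model, batch) {
  stopifnot(inherits(model, "cnn_model"))
  x <- as_batch_array(batch, model$spec)
  forward_internal(model, x, train = FALSE, collect = FALSE)$probs
}

#' Predicted class indices for a batch
#'
#' @inheritParams forward
#' @return Integer vector of 0-based class indices.
#' @export
predict_classes <- function(model, batch) {
  max.col(forward(model, batch), ties.method = "first") - 1L
}

#' Mean cross-entropy loss
#'
#' `mean over examples of -sum_j y_j log(p_j)` with natural logarithm;
#' probabilities are clipped at 1e-12 so the loss is defined at p = 0.
#'
#' @param probabilities N x T matrix, rows summing to 1.
#' @param one_hot_labels N x T one-hot matrix.
#' @return Non-negative scalar loss.
#' @export
#' @examples
#' cross_entropy(matrix(0.25, 1, 4), diag(4)[1, , drop = FALSE])  # log(4)
cross_entropy <- function(probabilities, one_hot_labels) {
  probabilities <- as.matrix(probabilities)
  one_hot_labels <- as.matrix(one_hot_labels)
  if (!all(dim(probabilities) == dim(one_hot_labels)))
    stop_domain("probabilities and labels must have identical shape")
  if (any(abs(rowSums(probabilities) - 1) > 1e-6))
    stop_domain("probability rows must sum to 1")
  is01 <- all(one_hot_labels %in% c(0, 1))
  if (!is01 || any(rowSums(one_hot_labels) != 1))
    stop_domain("labels must be one-hot rows")
  p <- pmax(probabilities, 1e-12)
  mean(-rowSums(one_hot_labels * log(p)))
}

one_hot <- function(labels, n_classes = 4L) {
  m <- matrix(0, length(labels), n_classes)
  m[cbind(seq_along(labels), as.integer(labels) + 1L)] <- 1
  m
}
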