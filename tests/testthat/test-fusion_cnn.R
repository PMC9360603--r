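trace_pairs <- function(spec) lapply(shape_trace(spec), as.integer)

test_that("single-subject network reproduces the printed feature-size column", {
  spec <- build_single_cnn(c(3, 78))
  expect_identical(trace_pairs(spec),
                   list(c(3L, 78L), c(3L, 78L), c(1L, 78L), c(1L, 78L),
                        c(1L, 76L)))
  expect_identical(attr(shape_trace(spec), "flatten_len"), 4864L)
  filters <- vapply(Filter(function(l) l$kind == "conv2d", spec$layers),
                    function(l) l$filters, integer(1))
  expect_identical(filters, c(16L, 32L, 32L, 64L))
})

test_that("two-person parallel network reproduces the printed collapse 6->4->2->1", {
  spec <- build_parallel_cnn(2, 78)
  expect_identical(trace_pairs(spec),
                   list(c(6L, 78L), c(6L, 78L), c(4L, 78L), c(2L, 78L),
                        c(1L, 78L), c(1L, 78L), c(1L, 76L)))
  filters <- vapply(Filter(function(l) l$kind == "conv2d", spec$layers),
                    function(l) l$filters, integer(1))
  expect_identical(filters, c(16L, 32L, 64L, 64L, 128L, 256L))
})

test_that("two-person serial network reproduces the printed 234-column trace", {
  spec <- build_serial_cnn(total_bins = 234)
  expect_identical(trace_pairs(spec),
                   list(c(3L, 234L), c(3L, 234L), c(1L, 234L), c(1L, 234L),
                        c(1L, 232L)))
  filters <- vapply(Filter(function(l) l$kind == "conv2d", spec$layers),
                    function(l) l$filters, integer(1))
  expect_identical(filters, c(48L, 96L, 96L, 192L))

  # generic concatenation rule: 2 x 78 bins -> 156 columns, ending (1, 154)
  generic <- build_serial_cnn(2, 78)
  tr <- trace_pairs(generic)
  expect_identical(tr[[1]], c(3L, 156L))
  expect_identical(tr[[length(tr)]], c(1L, 154L))
})

test_that("parallel generalization collapses any 3K channel stack to one", {
  spec3 <- build_parallel_cnn(3, 78)
  tr <- trace_pairs(spec3)
  expect_identical(tr[[1]], c(9L, 78L))
  rows <- vapply(tr, `[`, integer(1), 1)
  expect_true(all(diff(rows) <= 0))
  expect_identical(tr[[length(tr)]], c(1L, 76L))
  spec4 <- build_parallel_cnn(4, 42)
  tr4 <- trace_pairs(spec4)
  expect_identical(tr4[[1]], c(12L, 42L))
  expect_identical(tr4[[length(tr4)]][1], 1L)
})

test_that("parameter counting matches closed-form layer arithmetic", {
  # hand-computed for the single-subject stack at B = 78:
  # conv weights+biases+BN pairs, dense 4864*8+8 and 8*4+4
  expect_identical(count_parameters(build_single_cnn(c(3, 78))),
                   96L + 1632L + 3168L + 6336L + 38920L + 36L)
  # networks are parameterized by B
  expect_lt(count_parameters(build_single_cnn(c(3, 42))),
            count_parameters(build_single_cnn(c(3, 78))))
})

test_that("invalid architecture requests are configuration errors", {
  expect_error(build_single_cnn(c(6, 78)), class = "cossvep_config_error")
  expect_error(build_single_cnn(c(3, 4)), class = "cossvep_config_error")
  expect_error(build_parallel_cnn(1, 78), class = "cossvep_config_error")
  expect_error(build_serial_cnn(1, 78), class = "cossvep_config_error")
  expect_error(build_cnn_for_mode("voting"), class = "cossvep_config_error")
  # untraceable stack: kernel wider than the input after valid convs
  expect_error(cossvep:::new_cnn_spec(c(list(
    cossvep:::conv_layer(4L, c(5L, 1L), "valid")
  ), cossvep:::classifier_head()), c(3L, 10L)),
  class = "cossvep_config_error")
})

test_that("forward passes emit valid softmax rows regardless of input", {
  spec <- tiny_spec()
  m <- init_model(spec, seed = 4)
  set.seed(8)
  batch <- array(rnorm(6 * 3 * 10), c(6, 3, 10))
  p <- forward(m, batch)
  expect_identical(dim(p), c(6L, 4L))
  expect_true(all(p >= 0 & p <= 1))
  expect_equal(rowSums(p), rep(1, 6), tolerance = 1e-6)

  # duplicated examples give identical rows (stateless evaluation mode)
  dup <- array(0, c(2, 3, 10)); dup[1, , ] <- batch[1, , ]; dup[2, , ] <- batch[1, , ]
  pd <- forward(m, dup)
  expect_identical(pd[1, ], pd[2, ])

  # all-zero input stays finite
  pz <- forward(m, matrix(0, 3, 10))
  expect_false(anyNA(pz))
  expect_equal(sum(pz), 1, tolerance = 1e-6)

  expect_error(forward(m, matrix(0, 3, 11)), class = "cossvep_domain_error")
  err <- tryCatch(forward(m, matrix(0, 4, 10)), condition = identity)
  expect_match(conditionMessage(err), "3")
})

test_that("cross-entropy reproduces its closed-form values and bounds", {
  y <- diag(4)[1, , drop = FALSE]
  expect_equal(cross_entropy(matrix(c(1, 0, 0, 0), 1), y), 0)
  expect_equal(cross_entropy(matrix(0.25, 1, 4), y), log(4))
  expect_equal(cross_entropy(matrix(c(0.5, 0.3, 0.1, 0.1), 1), y), -log(0.5))
  # lower bound with equality only at the one-hot prediction
  set.seed(11)
  for (i in 1:20) {
    p <- matrix(stats::runif(4), 1); p <- p / sum(p)
    expect_gte(cross_entropy(p, y), 0)
    if (p[1] < 1) expect_gt(cross_entropy(p, y), 0)
  }
  # clipped at p = 0 rather than returning Inf
  expect_true(is.finite(cross_entropy(matrix(c(0, 1, 0, 0), 1), y)))
  expect_error(cross_entropy(matrix(0.25, 1, 4), matrix(c(1, 1, 0, 0), 1)),
               class = "cossvep_domain_error")
  expect_error(cross_entropy(matrix(0.3, 1, 4), y),
               class = "cossvep_domain_error")
})

test_that("analytic gradients agree with numerical differentiation", {
  spec <- tiny_spec()
  m <- init_model(spec, seed = 2)
  set.seed(3)
  n <- 5
  x <- array(rnorm(n * 3 * 10), c(n, 3, 10))
  y <- cossvep:::one_hot(sample(0:3, n, TRUE))
  eps <- 1e-6

  check_mode <- function(train) {
    lossfun <- function(model) {
      if (train) set.seed(99)
      fw <- cossvep:::forward_internal(model, x, train = train, collect = FALSE)
      cross_entropy(fw$probs, y)
    }
    if (train) set.seed(99)
    fw <- cossvep:::forward_internal(m, x, train = train, collect = TRUE)
    gr <- cossvep:::backward_internal(fw$model, fw$caches, (fw$probs - y) / n, n)
    worst <- 0
    for (i in seq_along(m$params)) {
      p <- m$params[[i]]
      if (is.null(p)) next
      l <- spec$layers[[i]]
      nms <- intersect(names(p), c("W", "gamma", "beta"))
      if (l$kind == "dense") nms <- c(nms, "b")  # conv biases are BN-absorbed
      for (nm in nms) {
        v <- p[[nm]]
        for (j in sample(seq_along(v), min(6, length(v)))) {
          mp <- m; mp$params[[i]][[nm]][j] <- v[j] + eps
          mm <- m; mm$params[[i]][[nm]][j] <- v[j] - eps
          num <- (lossfun(mp) - lossfun(mm)) / (2 * eps)
          rel <- abs(num - gr[[i]][[nm]][j]) /
            max(1e-6, abs(num) + abs(gr[[i]][[nm]][j]))
          worst <- max(worst, rel)
        }
      }
    }
    worst
  }
  expect_lt(check_mode(train = FALSE), 1e-4)
  expect_lt(check_mode(train = TRUE), 1e-4)
})
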