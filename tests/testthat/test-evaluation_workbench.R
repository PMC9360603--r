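test_that("information transfer rate matches its closed form", {
  expect_equal(itr(1, 4, 3), 40)                      # 2 bits x 20 selections
  expect_equal(itr(0.25, 4, 3), 0)                    # chance level
  # 20 selections/min x (2 + 0.9 log2 0.9 + 0.1 log2(0.1/3)) bits
  expect_equal(itr(0.9, 4, 3), 27.450164, tolerance = 1e-6)
  expect_equal(itr(0, 2, 1), 60)                      # always-wrong binary is informative
  # monotone above chance, exactly zero at chance
  ps <- seq(0.25, 1, by = 0.05)
  vals <- itr(ps, 4, 3)
  expect_true(all(diff(vals) >= 0))
  expect_equal(vals[1], 0)
  # the bit rate is U-shaped: below-chance accuracy is again informative
  expect_equal(itr(0.1, 4, 3), 2.0907637, tolerance = 1e-6)
  expect_equal(itr(1, 4, 3, include_rest_s = 2), 24)  # 60/(3+2)*2
  expect_error(itr(1.2, 4, 3), class = "cossvep_domain_error")
  expect_error(itr(0.5, 4, 0), class = "cossvep_domain_error")
})

test_that("stratified folds partition every trial exactly once", {
  y <- rep(0:3, each = 10)
  folds <- cossvep:::stratified_folds(y, 10, seed = 3)
  expect_length(folds, 40)
  expect_equal(sort(unique(folds)), 1:10)
  for (f in 1:10) {
    idx <- which(folds == f)
    expect_length(idx, 4)
    expect_equal(sort(y[idx]), 0:3)  # one trial per class per fold
  }
  expect_error(cossvep:::stratified_folds(rep(0:3, each = 3), 10, 1),
               class = "cossvep_domain_error")
})

test_that("k-fold evaluation scores oracle and random pipelines correctly", {
  y <- rep(0:3, each = 10)
  x <- array(0, c(40, 3, 8))
  for (i in 1:40) x[i, 1, 1] <- y[i]
  oracle <- function(x_train, y_train, x_test, fold_seed) x_test[, 1, 1]
  rep_o <- kfold_evaluate(x, y, oracle, k = 10, seed = 2)
  expect_equal(rep_o$mean_accuracy, 1)
  expect_length(rep_o$fold_accuracies, 10)
  expect_equal(rep_o$itr_bits_per_min, itr(1, 4, rep_o$window_s))

  yy <- rep(0:3, each = 100)
  xx <- array(0, c(400, 3, 8))
  rand <- function(x_train, y_train, x_test, fold_seed) {
    cossvep:::with_seed(fold_seed, sample(0:3, dim(x_test)[1], replace = TRUE))
  }
  rep_r <- kfold_evaluate(xx, yy, rand, k = 10, seed = 4)
  expect_lt(abs(rep_r$mean_accuracy - 0.25), 0.05)
})

test_that("mode comparison aggregates accuracy and ITR per window", {
  mk <- function(mode, w, acc) cossvep:::new_eval_report(mode, w, rep(acc, 5),
                                                         2, 1)
  reports <- list()
  for (mode in c("single", "parallel", "serial", "average"))
    for (w in seq(3.0, 1.6, by = -0.2))
      reports[[length(reports) + 1]] <- mk(mode, w, if (mode == "single") 0.7 else 0.8)
  s <- compare_modes(reports)
  expect_identical(dim(s$accuracy), c(4L, 10L))  # mode + 8 windows + overall
  expect_equal(s$accuracy$overall[s$accuracy$mode == "single"], 0.7)
  expect_equal(s$accuracy$overall[s$accuracy$mode == "parallel"], 0.8)
  expect_identical(dim(s$itr), c(4L, 10L))

  one <- compare_modes(list(mk("single", 3, 0.9)))
  expect_identical(dim(one$accuracy), c(1L, 3L))

  # identical fold accuracies across modes -> identical overall means
  same <- list(mk("single", 3, 0.6), mk("parallel", 3, 0.6))
  cm <- compare_modes(same)
  expect_equal(cm$accuracy$overall[1], cm$accuracy$overall[2])

  uneven <- list(mk("single", 3, 0.9), mk("parallel", 3, 0.9),
                 mk("parallel", 2, 0.9))
  expect_error(compare_modes(uneven), class = "cossvep_domain_error")

  tsv <- withr::local_tempfile(fileext = ".tsv")
  js <- withr::local_tempfile(fileext = ".json")
  write_mode_summary(s, tsv, js)
  expect_identical(nrow(utils::read.delim(tsv)), 4L)
  expect_true(jsonlite::validate(paste(readLines(js), collapse = "")))
})

test_that("a scaled-down sweep runs end to end and fills every mode/window cell", {
  cfg <- simulation_config(snr_db = 10)
  tgt <- simulate_group(cfg, 2, 4, seed = 31)
  src <- simulate_group(cfg, 2, 4, seed = 32)
  reports <- time_window_sweep(
    tgt, src, modes = c("single", "average"), windows = c(3.0, 2.0),
    k = 2, seed = 6,
    pretrain_config = train_config("pretrain", epochs = 2, seed = 1),
    finetune_config = train_config("finetune", epochs = 2, seed = 1))
  expect_length(reports, 4)
  s <- compare_modes(reports)
  expect_identical(dim(s$accuracy), c(2L, 4L))
  expect_true(all(is.finite(s$accuracy$overall)))
})

test_that("dataset containers round-trip epochs exactly", {
  cfg <- simulation_config()
  ds <- simulate_subject_dataset(cfg, subject_profile("S3"), 2, seed = 12)
  dir <- withr::local_tempdir()
  write_subject_dataset(ds, dir, config = cfg)
  back <- read_subject_dataset(dir)
  expect_length(back, 8)
  expect_identical(vapply(back, function(e) e$class_index, integer(1)),
                   vapply(ds, function(e) e$class_index, integer(1)))
  expect_identical(back[[1]]$subject_id, "S3")
  expect_equal(back[[5]]$samples, ds[[5]]$samples, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(read_subject_dataset(file.path(dir, "missing")),
               class = "cossvep_domain_error")
})
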