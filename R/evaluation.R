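# Evaluation workbench: stratified k-fold cross-validation, information
# transfer rate, time-window sweeps, and mode comparison tables.

#' Information transfer rate
#'
#' The standard BCI definition: bits per selection
#' `log2(N) + P log2(P) + (1-P) log2((1-P)/(N-1))`, scaled to bits per
#' minute by `60 / T`, taking the limits by continuity at P = 0 and P = 1
#' and floored at zero (the formula itself is non-negative, reaching zero
#' exactly at chance P = 1/N). By default T is the analysis window alone;
#' pass `include_rest_s` to add
#' gaze-shift/rest time for a more conservative figure.
#'
#' @param accuracy Classification accuracy P in `[0, 1]` (vectorized).
#' @param n_classes Number of selectable targets N (>= 2).
#' @param selection_time Time per selection T in seconds (> 0).
#' @param include_rest_s Extra seconds added to T.
#' @return ITR in bits per minute.
#' @export
#' @examples
#' itr(1, 4, 3)    # 40 bits/min
#' itr(0.25, 4, 3) # chance -> 0
itr <- function(accuracy, n_classes = 4, selection_time,
                include_rest_s = 0) {
  if (n_classes < 2) stop_domain("n_classes must be >= 2")
  if (any(selection_time <= 0)) stop_domain("selection_time must be positive")
  if (any(accuracy < 0 | accuracy > 1)) stop_domain("accuracy must lie in [0, 1]")
  p <- accuracy
  bits <- log2(n_classes) +
    ifelse(p > 0, p * log2(p), 0) +
    ifelse(p < 1, (1 - p) * log2((1 - p) / (n_classes - 1)), 0)
  pmax(bits, 0) * 60 / (selection_time + include_rest_s)
}

# Stratified fold assignment: within each class, shuffled indices are
# dealt round-robin across the k folds. Every trial lands in exactly one
# test fold.
stratified_folds <- function(y, k, seed) {
  counts <- table(y)
  if (any(counts < k))
    stop_domain("each class needs at least k = ", k, " examples; smallest has ",
                min(counts))
  folds <- integer(length(y))
  with_seed(derive_seed(seed, 5L), {
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

new_eval_report <- function(mode, window_s, fold_acc, n_subjects, seed,
                            n_classes = 4) {
  structure(list(
    mode = mode,
    window_s = window_s,
    fold_accuracies = fold_acc,
    mean_accuracy = mean(fold_acc),
    itr_bits_per_min = itr(mean(fold_acc), n_classes, window_s),
    n_subjects = n_subjects,
    seed = seed
  ), class = "ssvep_eval")
}

#' @export
print.ssvep_eval <- function(x, ...) {
  cat(sprintf("<ssvep_eval> %s mode, %.1f s window: accuracy %.3f (folds %s), ITR %.1f bits/min\n",
              x$mode, x$window_s, x$mean_accuracy,
              paste(sprintf("%.2f", x$fold_accuracies), collapse = " "),
              x$itr_bits_per_min))
  invisible(x)
}

#' Stratified k-fold cross-validation of a train/predict pipeline
#'
#' Shuffled, stratified folds (seeded); the pipeline is called once per
#' fold with the training examples and the held-out test examples and must
#' return predicted 0-based labels.
#'
#' @param x N x H x W feature array (see [feature_set()]).
#' @param y 0-based labels, length N.
#' @param pipeline `function(x_train, y_train, x_test, fold_seed)` ->
#'   predicted labels.
#' @param k Number of folds.
#' @param seed Integer seed for fold assignment and per-fold training.
#' @param mode,window_s,n_subjects Metadata recorded in the report.
#' @return An `ssvep_eval` report.
#' @export
kfold_evaluate <- function(x, y, pipeline, k = 10, seed = 1L,
                           mode = "single", window_s = 3, n_subjects = 1) {
  folds <- stratified_folds(y, k, seed)
  fold_acc <- vapply(seq_len(k), function(f) {
    tr <- folds != f
    pred <- pipeline(x[tr, , , drop = FALSE], y[tr],
                     x[!tr, , , drop = FALSE], derive_seed(seed, 7L, f))
    mean(pred == y[!tr])
  }, numeric(1))
  new_eval_report(mode, window_s, fold_acc, n_subjects, seed)
}

#' Transfer-learning train/predict pipeline
#'
#' Returns a pipeline for [kfold_evaluate()]: each fold restarts from the
#' shared pretrained model (never trained on the target data), freezes the
#' shallow convolution stack, fine-tunes on the fold's training examples
#' and predicts the held-out ones.
#'
#' @param pretrained A pretrained `cnn_model`.
#' @param config Fine-tuning [train_config()] template; its seed is
#'   replaced by the fold seed.
#' @param freeze_policy Passed to [freeze_shallow()].
#' @return A pipeline function.
#' @export
tl_pipeline <- function(pretrained, config = train_config("finetune"),
                        freeze_policy = "first_half_convs") {
  force(pretrained); force(config); force(freeze_policy)
  function(x_train, y_train, x_test, fold_seed) {
    cfg <- config
    cfg$seed <- fold_seed
    m <- freeze_shallow(pretrained, freeze_policy)
    m <- finetune(m, list(x = x_train, y = y_train), cfg)
    predict_classes(m, x_test)
  }
}

#' From-scratch train/predict pipeline
#'
#' Baseline without transfer: a freshly initialized network trained only
#' on the fold's training examples (pretraining hyperparameters).
#'
#' @param spec A `cnn_spec`.
#' @param config Training [train_config()] template; its seed is replaced
#'   by the fold seed.
#' @return A pipeline function.
#' @export
scratch_pipeline <- function(spec, config = train_config("pretrain")) {
  force(spec); force(config)
  function(x_train, y_train, x_test, fold_seed) {
    cfg <- config
    cfg$seed <- fold_seed
    m <- pretrain(spec, list(x = x_train, y = y_train), cfg)
    predict_classes(m, x_test)
  }
}

# Featurize a group for one mode/window: returns feature_set()-style
# list(x, y). Single mode uses the first subject; fusion modes fuse all.
prepare_mode_features <- function(group, mode, window_s, band = band_spec()) {
  if (mode == "single") {
    feats <- featurize_dataset(group$subjects[[1]], window_s, band)
    return(feature_set(feats))
  }
  feats <- lapply(group$subjects, featurize_dataset, window_s = window_s,
                  band = band)
  fused <- fuse_dataset(align_group_trials(feats), mode)
  feature_set(fused)
}

# Pretraining set for a mode: pools source subjects for single/serial?
# No: single pools subjects' individual features; fusion modes fuse
# random subject groupings of the matching size (pairings do not affect
# the final classifier, so one random grouping per call suffices).
prepare_source_features <- function(source_group, mode, window_s,
                                    n_subjects = 2, band = band_spec(),
                                    seed = 1L) {
  feats <- lapply(source_group$subjects, featurize_dataset,
                  window_s = window_s, band = band)
  if (mode == "single") {
    return(feature_set(do.call(c, feats)))
  }
  ns <- length(feats)
  if (ns < n_subjects)
    stop_domain("source group has ", ns, " subjects; need >= ", n_subjects)
  grouping <- with_seed(derive_seed(seed, 13L), sample(ns))
  sets <- split(grouping, ceiling(seq_len(ns) / n_subjects))
  sets <- sets[vapply(sets, length, integer(1)) == n_subjects]
  fused <- do.call(c, lapply(sets, function(members) {
    fuse_dataset(align_group_trials(feats[members]), mode)
  }))
  feature_set(fused)
}

#' Time-window sweep over fusion modes
#'
#' For each analysis window the target and source groups are re-featurized
#' (the bin count, and hence the network input width, changes with the
#' window), a network is pretrained per mode on the source group, and the
#' target group is evaluated by stratified k-fold cross-validation with
#' per-fold fine-tuning.
#'
#' @param target_group,source_group Results of [simulate_group()] (or any
#'   lists with the same structure).
#' @param modes Subset of `c("single", "parallel", "serial", "average")`.
#' @param windows Analysis windows in seconds.
#' @param k Folds.
#' @param seed Integer seed.
#' @param pretrain_config,finetune_config [train_config()] templates.
#' @param band Frequency band for feature selection.
#' @return List of `ssvep_eval` reports (mode-major, window-minor).
#' @export
time_window_sweep <- function(target_group, source_group,
                              modes = c("single", "parallel"),
                              windows = seq(3.0, 1.6, by = -0.2),
                              k = 10, seed = 1L,
                              pretrain_config = train_config("pretrain"),
                              finetune_config = train_config("finetune"),
                              band = band_spec()) {
  n_target <- length(target_group$subjects)
  reports <- list()
  for (mode in modes) {
    ns <- if (mode == "single") 1L else n_target
    for (w in windows) {
      src <- prepare_source_features(source_group, mode, w,
                                     n_subjects = max(ns, 2L), band = band,
                                     seed = seed)
      tgt <- prepare_mode_features(target_group, mode, w, band = band)
      bins <- dim(tgt$x)[3] / if (mode == "serial") n_target else 1
      spec <- build_cnn_for_mode(mode, n_subjects = n_target, bins = bins)
      pcfg <- pretrain_config
      pcfg$seed <- derive_seed(seed, 17L, match(mode, modes), round(w * 10))
      base <- pretrain(spec, src, pcfg)
      rep <- kfold_evaluate(tgt$x, tgt$y,
                            tl_pipeline(base, finetune_config),
                            k = k, seed = seed, mode = mode, window_s = w,
                            n_subjects = ns)
      reports[[length(reports) + 1]] <- rep
    }
  }
  reports
}

#' Summarize evaluation reports across modes and windows
#'
#' @param reports List of `ssvep_eval` sharing one window set per mode.
#' @return List with `accuracy` and `itr` data frames (rows = mode,
#'   columns = window, plus an `overall` mean-accuracy column per mode).
#' @export
compare_modes <- function(reports) {
  if (!length(reports)) stop_domain("no reports to compare")
  modes <- unique(vapply(reports, function(r) r$mode, character(1)))
  windows <- sort(unique(vapply(reports, function(r) r$window_s, numeric(1))),
                  decreasing = TRUE)
  for (m in modes) {
    wm <- sort(vapply(Filter(function(r) r$mode == m, reports),
                      function(r) r$window_s, numeric(1)), decreasing = TRUE)
    if (!identical(wm, windows))
      stop_domain("mode ", m, " does not cover the shared window set")
  }
  acc <- matrix(NA_real_, length(modes), length(windows),
                dimnames = list(modes, sprintf("%.1fs", windows)))
  itr_m <- acc
  for (r in reports) {
    acc[r$mode, sprintf("%.1fs", r$window_s)] <- r$mean_accuracy
    itr_m[r$mode, sprintf("%.1fs", r$window_s)] <- r$itr_bits_per_min
  }
  acc_df <- data.frame(mode = modes, acc, overall = rowMeans(acc),
                       check.names = FALSE, row.names = NULL)
  itr_df <- data.frame(mode = modes, itr_m, overall = rowMeans(itr_m),
                       check.names = FALSE, row.names = NULL)
  list(accuracy = acc_df, itr = itr_df)
}

#' Write a mode-comparison summary to disk
#'
#' @param summary Result of [compare_modes()].
#' @param tsv_path,json_path Output paths (either may be `NULL` to skip).
#' @return `summary`, invisibly.
#' @export
write_mode_summary <- function(summary, tsv_path = NULL, json_path = NULL) {
  if (!is.null(tsv_path))
    utils::write.table(summary$accuracy, tsv_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  if (!is.null(json_path))
    writeLines(jsonlite::toJSON(summary, dataframe = "rows",
                                auto_unbox = TRUE, digits = NA), json_path)
  invisible(summary)
}
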