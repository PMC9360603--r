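# Packaged synthetic experiments: the standard study designs used to
# characterize the pipeline on simulated collaborative groups. These are
# the computations behind the package's reported numbers.

#' Single-subject transfer-learning benchmark at high SNR
#'
#' Simulates a source group and one target subject, pretrains the
#' single-subject network on the pooled source features, and evaluates the
#' transfer pipeline (freeze shallow convolutions, fine-tune per fold) by
#' stratified k-fold cross-validation on the target subject.
#'
#' @param snr_db Simulator SNR in dB.
#' @param n_source Number of source subjects.
#' @param trials_per_class Trials per class for every subject.
#' @param window_s Analysis window in seconds.
#' @param k Cross-validation folds.
#' @param seed Integer seed for all randomness.
#' @param pretrain_config,finetune_config [train_config()] templates.
#' @return An `ssvep_eval` report for the target subject.
#' @export
run_single_tl_benchmark <- function(snr_db = 15, n_source = 8,
                                    trials_per_class = 12, window_s = 3,
                                    k = 10, seed = 1L,
                                    pretrain_config = train_config("pretrain"),
                                    finetune_config = train_config("finetune")) {
  cfg <- simulation_config(snr_db = snr_db)
  src_grp <- simulate_group(cfg, n_source, trials_per_class,
                            seed = derive_seed(seed, 31L))
  tgt_grp <- simulate_group(cfg, 1, trials_per_class,
                            seed = derive_seed(seed, 32L))
  src <- prepare_source_features(src_grp, "single", window_s)
  tgt <- prepare_mode_features(tgt_grp, "single", window_s)
  pcfg <- pretrain_config
  pcfg$seed <- derive_seed(seed, 33L)
  base <- pretrain(build_single_cnn(c(3, dim(src$x)[3])), src, pcfg)
  kfold_evaluate(tgt$x, tgt$y, tl_pipeline(base, finetune_config),
                 k = k, seed = seed, mode = "single", window_s = window_s)
}

holdout_split <- function(y, test_fraction, seed) {
  folds <- stratified_folds(y, round(1 / test_fraction), seed)
  folds == 1
}

#' Fusion-benefit experiment: two-person parallel fusion vs single subject
#'
#' At each analysis window a single-subject and a two-subject parallel
#' network are pretrained once on a simulated source group (pooled
#' features / random subject pairings); then, for each evaluation seed, a
#' fresh two-subject target group is simulated and both modes are scored
#' on a stratified holdout (fine-tune on the training portion, test on the
#' held-out third).
#'
#' @param windows Analysis windows in seconds.
#' @param n_seeds Number of independent target groups per window.
#' @param snr_db Simulator SNR in dB (default: the simulator default,
#'   the package's "moderate" operating point).
#' @param n_source Number of source subjects.
#' @param trials_per_class Trials per class.
#' @param seed Master seed.
#' @param pretrain_config,finetune_config [train_config()] templates.
#' @return Data frame with one row per (window, seed, mode) holding the
#'   holdout accuracy.
#' @export
run_fusion_benefit <- function(windows = c(3.0, 2.2, 1.6), n_seeds = 10,
                               snr_db = NULL, n_source = 6,
                               trials_per_class = 12, seed = 1L,
                               pretrain_config = train_config("pretrain"),
                               finetune_config = train_config("finetune")) {
  cfg <- if (is.null(snr_db)) simulation_config() else
    simulation_config(snr_db = snr_db)
  src_grp <- simulate_group(cfg, n_source, trials_per_class,
                            seed = derive_seed(seed, 41L))
  out <- list()
  for (w in windows) {
    src_s <- prepare_source_features(src_grp, "single", w, seed = seed)
    src_p <- prepare_source_features(src_grp, "parallel", w,
                                     n_subjects = 2, seed = seed)
    bins <- dim(src_s$x)[3]
    pcfg <- pretrain_config
    pcfg$seed <- derive_seed(seed, 42L, round(w * 10))
    base_s <- pretrain(build_single_cnn(c(3, bins)), src_s, pcfg)
    pcfg$seed <- derive_seed(seed, 43L, round(w * 10))
    base_p <- pretrain(build_parallel_cnn(2, bins), src_p, pcfg)
    pl_s <- tl_pipeline(base_s, finetune_config)
    pl_p <- tl_pipeline(base_p, finetune_config)
    for (s in seq_len(n_seeds)) {
      tgt_grp <- simulate_group(cfg, 2, trials_per_class,
                                seed = derive_seed(seed, 44L, s))
      tgt_s <- prepare_mode_features(tgt_grp, "single", w)
      tgt_p <- prepare_mode_features(tgt_grp, "parallel", w)
      test <- holdout_split(tgt_s$y, 1 / 3, derive_seed(seed, 45L, s))
      fseed <- derive_seed(seed, 46L, s, round(w * 10))
      acc_s <- mean(pl_s(tgt_s$x[!test, , , drop = FALSE], tgt_s$y[!test],
                         tgt_s$x[test, , , drop = FALSE], fseed) ==
                      tgt_s$y[test])
      acc_p <- mean(pl_p(tgt_p$x[!test, , , drop = FALSE], tgt_p$y[!test],
                         tgt_p$x[test, , , drop = FALSE], fseed) ==
                      tgt_p$y[test])
      out[[length(out) + 1]] <- data.frame(
        window_s = w, seed = s, mode = c("single", "parallel"),
        accuracy = c(acc_s, acc_p))
    }
  }
  do.call(rbind, out)
}

#' Transfer-benefit experiment: fine-tuning vs training from scratch
#'
#' Pretrains the single-subject network once on a simulated source group,
#' then for each paired seed simulates a fresh target subject, fine-tunes
#' the pretrained model on a small training split (at most 24 trials) and
#' compares against an identically evaluated network trained from scratch
#' on the same trials.
#'
#' @param n_seeds Number of paired comparisons.
#' @param snr_db Simulator SNR in dB (default: simulator default).
#' @param n_source Number of source subjects (>= 6 for a meaningful
#'   source domain).
#' @param trials_per_class Trials per class for the target subject; the
#'   training split uses half of them.
#' @param window_s Analysis window.
#' @param seed Master seed.
#' @param pretrain_config,finetune_config [train_config()] templates.
#' @return Data frame with one row per seed: accuracy with transfer and
#'   from scratch.
#' @export
run_transfer_benefit <- function(n_seeds = 10, snr_db = NULL, n_source = 6,
                                 trials_per_class = 12, window_s = 3,
                                 seed = 1L,
                                 pretrain_config = train_config("pretrain"),
                                 finetune_config = train_config("finetune")) {
  cfg <- if (is.null(snr_db)) simulation_config() else
    simulation_config(snr_db = snr_db)
  src_grp <- simulate_group(cfg, n_source, trials_per_class,
                            seed = derive_seed(seed, 51L))
  src <- prepare_source_features(src_grp, "single", window_s)
  bins <- dim(src$x)[3]
  spec <- build_single_cnn(c(3, bins))
  pcfg <- pretrain_config
  pcfg$seed <- derive_seed(seed, 52L)
  base <- pretrain(spec, src, pcfg)
  pl_tl <- tl_pipeline(base, finetune_config)
  pl_scratch <- scratch_pipeline(spec, pretrain_config)
  out <- lapply(seq_len(n_seeds), function(s) {
    tgt_grp <- simulate_group(cfg, 1, trials_per_class,
                              seed = derive_seed(seed, 53L, s))
    tgt <- prepare_mode_features(tgt_grp, "single", window_s)
    test <- holdout_split(tgt$y, 1 / 2, derive_seed(seed, 54L, s))
    fseed <- derive_seed(seed, 55L, s)
    acc_tl <- mean(pl_tl(tgt$x[!test, , , drop = FALSE], tgt$y[!test],
                         tgt$x[test, , , drop = FALSE], fseed) == tgt$y[test])
    acc_sc <- mean(pl_scratch(tgt$x[!test, , , drop = FALSE], tgt$y[!test],
                              tgt$x[test, , , drop = FALSE], fseed) ==
                     tgt$y[test])
    data.frame(seed = s, transfer = acc_tl, scratch = acc_sc)
  })
  do.call(rbind, out)
}
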