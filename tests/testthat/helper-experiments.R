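# Cached synthetic experiments shared by the acceptance-level tests.
# Problem sizes follow the package's standard study designs (see the
# methods vignette): source groups of 6-8 subjects, 12 trials per class,
# 10 evaluation seeds, windows spanning the long/medium/short range.

.experiment_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .experiment_cache)) {
    assign(key, expr, envir = .experiment_cache)
  }
  get(key, envir = .experiment_cache)
}

single_tl_report <- function() {
  cached("single_tl", run_single_tl_benchmark(
    snr_db = 15, n_source = 8, trials_per_class = 12, window_s = 3,
    k = 10, seed = 1))
}

fusion_benefit_table <- function() {
  cached("fusion_benefit", run_fusion_benefit(
    windows = c(3.0, 2.2, 1.6), n_seeds = 10, seed = 1))
}

transfer_benefit_table <- function() {
  cached("transfer_benefit", run_transfer_benefit(n_seeds = 10, seed = 1))
}
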