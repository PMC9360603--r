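make_members <- function(k, bins = 78, class_index = 1L, seed = 2) {
  cossvep:::with_seed(seed, lapply(seq_len(k), function(s) {
    feat_from_matrix(matrix(stats::runif(3 * bins), 3, bins), class_index,
                     subject = paste0("S", s))
  }))
}

test_that("parallel fusion stacks channels in member order", {
  ms <- make_members(2)
  fz <- fuse_parallel(ms)
  expect_identical(dim(fz$values), c(6L, 78L))
  expect_identical(fz$kind, "parallel")
  expect_identical(fz$member_ids, c("S1", "S2"))
  expect_equal(fz$values[1:3, ], ms[[1]]$values, ignore_attr = TRUE)
  expect_equal(fz$values[4:6, ], ms[[2]]$values, ignore_attr = TRUE)

  expect_identical(dim(fuse_parallel(make_members(3))$values), c(9L, 78L))
  one <- make_members(1)
  expect_equal(fuse_parallel(one)$values, one[[1]]$values, ignore_attr = TRUE)
})

test_that("serial fusion concatenates along the frequency axis per channel", {
  ms <- make_members(2)
  fz <- fuse_serial(ms)
  expect_identical(dim(fz$values), c(3L, 156L))
  expect_equal(fz$values[, 1:78], ms[[1]]$values, ignore_attr = TRUE)
  expect_equal(fz$values[, 79:156], ms[[2]]$values, ignore_attr = TRUE)
  one <- make_members(1)
  expect_equal(fuse_serial(one)$values, one[[1]]$values, ignore_attr = TRUE)
})

test_that("averaging is the element-wise mean bounded by the members", {
  ms <- make_members(2)
  fz <- fuse_average(ms)
  expect_identical(dim(fz$values), c(3L, 78L))
  expect_equal(fz$values, (ms[[1]]$values + ms[[2]]$values) / 2,
               ignore_attr = TRUE)
  same <- list(ms[[1]], ms[[1]])
  expect_equal(fuse_average(same)$values, ms[[1]]$values, ignore_attr = TRUE)
  a <- feat_from_matrix(matrix(0, 3, 5)); b <- feat_from_matrix(matrix(1, 3, 5))
  expect_true(all(fuse_average(list(a, b))$values == 0.5))
})

test_that("fusion preconditions are enforced", {
  ms <- make_members(2)
  bad_bins <- list(ms[[1]], feat_from_matrix(matrix(0.5, 3, 40), 1L))
  expect_error(fuse_parallel(bad_bins), class = "cossvep_domain_error")
  bad_label <- list(ms[[1]], feat_from_matrix(matrix(0.5, 3, 78), 2L))
  expect_error(fuse_serial(bad_label), class = "cossvep_domain_error")
  unnorm <- list(ms[[1]],
                 feat_from_matrix(matrix(0.5, 3, 78), 1L, normalized = FALSE))
  expect_error(fuse_average(unnorm), class = "cossvep_domain_error")
})

test_that("fusion shape algebra and value conservation hold across K and B", {
  for (k in 1:4) for (bins in c(42L, 52L, 78L)) {
    ms <- make_members(k, bins, seed = k * 100 + bins)
    par <- fuse_parallel(ms); ser <- fuse_serial(ms); avg <- fuse_average(ms)
    expect_identical(dim(par$values), c(3L * k, bins))
    expect_identical(dim(ser$values), c(3L, k * bins))
    expect_identical(dim(avg$values), c(3L, bins))
    pool <- sort(unlist(lapply(ms, function(m) m$values)))
    expect_equal(sort(as.vector(par$values)), pool)  # pure rearrangement
    expect_equal(sort(as.vector(ser$values)), pool)
    lo <- Reduce(pmin, lapply(ms, function(m) m$values))
    hi <- Reduce(pmax, lapply(ms, function(m) m$values))
    expect_true(all(avg$values >= lo - 1e-12 & avg$values <= hi + 1e-12))
  }
})

test_that("group alignment zips trials and reports the first mismatch", {
  cfg <- simulation_config()
  grp <- simulate_group(cfg, 2, 12, seed = 9)
  tuples <- align_group_trials(grp$subjects)
  expect_length(tuples, 48)
  expect_length(tuples[[1]], 2)
  expect_identical(tuples[[7]][[1]]$class_index, tuples[[7]][[2]]$class_index)

  solo <- align_group_trials(grp$subjects[1])
  expect_length(solo[[1]], 1)

  broken <- grp$subjects
  broken[[2]][[5]]$class_index <- (broken[[2]][[5]]$class_index + 1L) %% 4L
  err <- tryCatch(align_group_trials(broken), condition = identity)
  expect_s3_class(err, "cossvep_alignment_error")
  expect_match(conditionMessage(err), "trial 5")
})

test_that("averaging independent-noise members raises the peak-to-background ratio", {
  # equal evoked signal, independent noise; peak-to-background measured as
  # the value at the stimulation bin over the largest off-harmonic value
  cfg <- simulation_config(snr_db = -8)
  prof <- subject_profile()
  n_trials <- 60
  k <- 3
  pbr <- function(vals, fax, f0) {
    df <- fax[2] - fax[1]
    harm <- abs(outer(fax, f0 * (1:3), "-")) <= df
    on_bin <- which.min(abs(fax - f0))
    mean(vals[, on_bin]) / max(vals[, !apply(harm, 1, any)])
  }
  member_pbr <- matrix(0, n_trials, k)
  fused_pbr <- numeric(n_trials)
  for (i in seq_len(n_trials)) {
    cls <- (i - 1) %% 4
    f0 <- cfg$stim_freqs[cls + 1]
    ms <- lapply(seq_len(k), function(s) {
      featurize(simulate_trial(cfg, cls, prof, seed = 7000 + i * 10 + s), 3)
    })
    fax <- ms[[1]]$freq_axis
    member_pbr[i, ] <- vapply(ms, function(m) pbr(m$values, fax, f0),
                              numeric(1))
    fused_pbr[i] <- pbr(fuse_average(ms)$values, fax, f0)
  }
  expect_gte(mean(fused_pbr), stats::median(colMeans(member_pbr)))
})
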