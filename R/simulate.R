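# Synthetic SSVEP generator: harmonic responses over correlated
# pink-plus-white occipital background noise, with per-subject variability.

#' Simulation configuration for synthetic SSVEP recordings
#'
#' Describes the stimulation protocol and signal model used by
#' [simulate_trial()] and friends: a four-target flicker paradigm recorded
#' from the occipital electrodes O1, Oz and O2. Each target evokes a
#' steady-state response at its flicker frequency and harmonics, riding on
#' broadband background EEG modelled as a mixture of pink (1/f) and white
#' noise shared partially across channels.
#'
#' @param stim_freqs Stimulation frequencies in Hz, one per target class.
#' @param stim_phases Stimulation phases in radians, one per target class.
#' @param sampling_rate Sampling rate in Hz.
#' @param trial_duration Stimulation length per trial in seconds.
#' @param n_harmonics Number of harmonics (including the fundamental)
#'   carried by the evoked response.
#' @param snr_db Ratio of total evoked-response power to total background
#'   noise power across the three channels, in decibels.
#' @param pink_fraction Proportion of background noise power that is 1/f
#'   ("pink"); the remainder is white.
#' @param channel_gains Relative evoked-response gains for (O1, Oz, O2);
#'   Oz is conventionally the strongest SSVEP site.
#' @param channel_noise_cor Correlation of background noise between
#'   channels, modelled through a shared noise source.
#' @param seed Default seed recorded with the configuration (individual
#'   generator calls take their own seed).
#'
#' @return An object of class `ssvep_config`.
#' @export
#' @examples
#' cfg <- simulation_config(snr_db = 0)
#' cfg$stim_freqs
simulation_config <- function(stim_freqs = c(8.6, 10, 12, 15),
                              stim_phases = c(1.35, 0.35, 0.9, 0.35) * pi,
                              sampling_rate = 256,
                              trial_duration = 4,
                              n_harmonics = 3,
                              snr_db = -15,
                              pink_fraction = 0.7,
                              channel_gains = c(0.9, 1.0, 0.9),
                              channel_noise_cor = 0.5,
                              seed = 1L) {
  if (length(stim_freqs) != length(stim_phases))
    stop_config("stim_freqs and stim_phases must have equal length")
  if (any(stim_freqs <= 0)) stop_config("stimulation frequencies must be positive")
  if (sampling_rate <= 2 * max(stim_freqs) * n_harmonics)
    stop_config("sampling_rate must exceed twice the highest harmonic frequency (",
                max(stim_freqs) * n_harmonics, " Hz)")
  if (trial_duration <= 0) stop_config("trial_duration must be positive")
  if (length(channel_gains) != 3 || any(channel_gains <= 0))
    stop_config("channel_gains must be 3 positive values for O1/Oz/O2")
  if (pink_fraction < 0 || pink_fraction > 1)
    stop_config("pink_fraction must lie in [0, 1]")
  if (channel_noise_cor < 0 || channel_noise_cor >= 1)
    stop_config("channel_noise_cor must lie in [0, 1)")
  structure(list(
    stim_freqs = as.double(stim_freqs),
    stim_phases = as.double(stim_phases),
    sampling_rate = as.double(sampling_rate),
    trial_duration = as.double(trial_duration),
    n_harmonics = as.integer(n_harmonics),
    snr_db = as.double(snr_db),
    pink_fraction = as.double(pink_fraction),
    channel_gains = as.double(channel_gains),
    channel_noise_cor = as.double(channel_noise_cor),
    seed = as.integer(seed)
  ), class = "ssvep_config")
}

#' Subject profile describing individual signal variability
#'
#' Captures the minimal inter-subject differences the fusion methods are
#' meant to average out: overall signal amplitude, a subject-specific SNR
#' offset, and a small response latency.
#'
#' @param subject_id Identifier string.
#' @param amplitude_scale Overall multiplicative amplitude (applies to the
#'   whole recording, leaving SNR unchanged); must be positive.
#' @param snr_offset_db Added to the configuration SNR for this subject.
#' @param latency_jitter Response latency in seconds.
#'
#' @return An object of class `ssvep_profile`.
#' @export
subject_profile <- function(subject_id = "S1", amplitude_scale = 1,
                            snr_offset_db = 0, latency_jitter = 0) {
  if (amplitude_scale <= 0) stop_config("amplitude_scale must be positive")
  structure(list(
    subject_id = as.character(subject_id),
    amplitude_scale = as.double(amplitude_scale),
    snr_offset_db = as.double(snr_offset_db),
    latency_jitter = as.double(latency_jitter)
  ), class = "ssvep_profile")
}

new_epoch <- function(samples, class_index, sampling_rate, subject_id) {
  rownames(samples) <- c("O1", "Oz", "O2")
  structure(list(
    samples = samples,
    channel_labels = c("O1", "Oz", "O2"),
    class_index = as.integer(class_index),
    sampling_rate = as.double(sampling_rate),
    subject_id = as.character(subject_id)
  ), class = "ssvep_epoch")
}

#' @export
print.ssvep_epoch <- function(x, ...) {
  cat(sprintf("<ssvep_epoch> subject %s, class %d, %d ch x %d samples @ %g Hz\n",
              x$subject_id, x$class_index, nrow(x$samples), ncol(x$samples),
              x$sampling_rate))
  invisible(x)
}

# Unit-variance pink (1/f) noise of length n via spectral shaping.
pink_noise <- function(n) {
  nf <- n %/% 2
  spec <- complex(real = stats::rnorm(nf), imaginary = stats::rnorm(nf))
  spec <- spec / sqrt(seq_len(nf))          # amplitude ~ f^{-1/2} -> power ~ 1/f
  full <- complex(length.out = n)
  full[2:(nf + 1)] <- spec
  if (n %% 2 == 0) full[nf + 1] <- complex(real = Re(spec[nf]) * sqrt(2))
  m <- if (n %% 2 == 0) nf else nf + 1
  full[n - (2:m) + 2] <- Conj(full[2:m])
  x <- Re(stats::fft(full, inverse = TRUE)) / n
  x / stats::sd(x)
}

# One channel of background noise: pink/white mixture, unit variance.
noise_channel <- function(n, pink_fraction) {
  p <- if (pink_fraction > 0) pink_noise(n) else numeric(n)
  w <- if (pink_fraction < 1) stats::rnorm(n) else numeric(n)
  sqrt(pink_fraction) * p + sqrt(1 - pink_fraction) * w
}

# Noise-free evoked response (3 x n), unit base amplitude before SNR scaling.
ssvep_signal <- function(config, class_index, profile, n) {
  f <- config$stim_freqs[class_index + 1]
  phi <- config$stim_phases[class_index + 1]
  t <- (seq_len(n) - 1) / config$sampling_rate
  base <- numeric(n)
  for (h in seq_len(config$n_harmonics)) {
    base <- base + (1 / h) * sin(2 * pi * h * f * (t - profile$latency_jitter) +
                                   h * phi)
  }
  outer(config$channel_gains, base)
}

#' Simulate one SSVEP trial
#'
#' Generates a 3-channel epoch for one target class: the harmonic evoked
#' response for that class (amplitude decaying as 1/h across harmonics,
#' phase h times the stimulus phase) plus correlated pink-and-white
#' background noise. The evoked response is scaled so that the realized
#' ratio of evoked power to noise power, summed over channels, equals the
#' configured SNR plus the subject's offset exactly; the profile's
#' amplitude scale is then applied to the whole epoch, so it changes
#' absolute amplitude but not SNR. Bit-identical output for identical
#' arguments.
#'
#' @param config A [simulation_config()].
#' @param class_index Target class, 0-based (0..3 for the default
#'   four-target protocol).
#' @param profile A [subject_profile()].
#' @param seed Integer seed for the noise draw.
#'
#' @return An `ssvep_epoch` with a 3 x (sampling_rate x trial_duration)
#'   sample matrix in microvolt-like units.
#' @export
#' @examples
#' ep <- simulate_trial(simulation_config(), class_index = 1,
#'                      profile = subject_profile(), seed = 7)
#' dim(ep$samples)
simulate_trial <- function(config, class_index, profile = subject_profile(),
                           seed = config$seed) {
  stopifnot(inherits(config, "ssvep_config"), inherits(profile, "ssvep_profile"))
  if (!is.numeric(class_index) || length(class_index) != 1 ||
      class_index %% 1 != 0 || class_index < 0 ||
      class_index >= length(config$stim_freqs))
    stop_domain("class_index must be an integer in 0..",
                length(config$stim_freqs) - 1)
  n <- round(config$sampling_rate * config$trial_duration)
  sig <- ssvep_signal(config, class_index, profile, n)
  noise <- with_seed(seed, {
    shared <- noise_channel(n, config$pink_fraction)
    rho <- config$channel_noise_cor
    t(vapply(1:3, function(i) {
      sqrt(rho) * shared + sqrt(1 - rho) * noise_channel(n, config$pink_fraction)
    }, numeric(n)))
  })
  snr_lin <- 10^((config$snr_db + profile$snr_offset_db) / 10)
  p_sig <- sum(sig^2)
  p_noise <- sum(noise^2)
  alpha <- sqrt(snr_lin * p_noise / p_sig)
  samples <- profile$amplitude_scale * (alpha * sig + noise)
  new_epoch(samples, class_index, config$sampling_rate, profile$subject_id)
}

# Shared per-group trial schedule: balanced classes, shuffled by seed only.
class_schedule <- function(n_classes, trials_per_class, seed) {
  with_seed(derive_seed(seed, 1L), sample(rep(seq_len(n_classes) - 1L,
                                              trials_per_class)))
}

simulate_subject_epochs <- function(config, profile, schedule, seed,
                                    subject_index) {
  lapply(seq_along(schedule), function(k) {
    simulate_trial(config, schedule[k], profile,
                   seed = derive_seed(seed, subject_index, k))
  })
}

#' Simulate a balanced dataset for one subject
#'
#' @inheritParams simulate_trial
#' @param trials_per_class Number of trials per target class (>= 1).
#'
#' @return List of `ssvep_epoch`, `4 * trials_per_class` long, in the
#'   shuffled presentation order; the class schedule depends only on the
#'   seed, so different profiles under the same seed see identical labels.
#' @export
simulate_subject_dataset <- function(config, profile = subject_profile(),
                                     trials_per_class, seed = config$seed) {
  if (trials_per_class < 1) stop_domain("trials_per_class must be >= 1")
  schedule <- class_schedule(length(config$stim_freqs), trials_per_class, seed)
  simulate_subject_epochs(config, profile, schedule, seed, subject_index = 0L)
}

#' Simulate a collaborative group fixating the same stimuli
#'
#' All subjects view the same stimulus sequence (the collaborative-gaze
#' assumption), so trial k carries the same class label for every subject,
#' while each subject has an independent noise realization and an
#' individual profile (log-normal amplitude scale, sd 0.2 on the log
#' scale; Gaussian SNR offset, sd 2 dB; Gaussian latency, sd 10 ms) drawn
#' deterministically from the seed.
#'
#' @inheritParams simulate_subject_dataset
#' @param n_subjects Number of simultaneous subjects (>= 1).
#'
#' @return List with `subjects` (per-subject epoch lists sharing one label
#'   sequence), `profiles`, and `labels` (the shared schedule, 0-based).
#' @export
simulate_group <- function(config, n_subjects, trials_per_class,
                           seed = config$seed) {
  if (n_subjects < 1) stop_domain("n_subjects must be >= 1")
  if (trials_per_class < 1) stop_domain("trials_per_class must be >= 1")
  schedule <- class_schedule(length(config$stim_freqs), trials_per_class, seed)
  profiles <- with_seed(derive_seed(seed, 2L), lapply(seq_len(n_subjects),
    function(s) {
      subject_profile(
        subject_id = paste0("S", s),
        amplitude_scale = exp(stats::rnorm(1, 0, 0.2)),
        snr_offset_db = stats::rnorm(1, 0, 2),
        latency_jitter = stats::rnorm(1, 0, 0.010)
      )
    }))
  subjects <- lapply(seq_len(n_subjects), function(s) {
    simulate_subject_epochs(config, profiles[[s]], schedule, seed,
                            subject_index = s)
  })
  list(subjects = subjects, profiles = profiles, labels = schedule)
}
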