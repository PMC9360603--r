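# Dataset container: one numeric array file (CSV, one row per epoch) plus
# a JSON sidecar with labels and sampling metadata.

#' Write a subject's epochs to the dataset container
#'
#' Stores `epochs x (3 * samples)` values in `data.csv` (each epoch's
#' 3 x n sample matrix flattened column-major) and the metadata — labels,
#' sampling rate, channel labels, stimulation frequencies, subject id — in
#' `meta.json` alongside.
#'
#' @param epochs List of `ssvep_epoch` for one subject.
#' @param dir Output directory (created if missing).
#' @param config Optional [simulation_config()] whose stimulation
#'   frequencies and seed are recorded in the sidecar.
#' @return `dir`, invisibly.
#' @export
write_subject_dataset <- function(epochs, dir, config = NULL) {
  stopifnot(length(epochs) > 0)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n_samples <- ncol(epochs[[1]]$samples)
  mat <- t(vapply(epochs, function(e) {
    if (ncol(e$samples) != n_samples)
      stop_domain("epochs have inconsistent sample counts")
    as.vector(e$samples)
  }, numeric(3 * n_samples)))
  utils::write.table(mat, file.path(dir, "data.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  meta <- list(
    subject_id = epochs[[1]]$subject_id,
    labels = vapply(epochs, function(e) e$class_index, integer(1)),
    sampling_rate = epochs[[1]]$sampling_rate,
    n_channels = 3L,
    n_samples = n_samples,
    channel_labels = epochs[[1]]$channel_labels,
    stim_freqs = if (!is.null(config)) config$stim_freqs else NULL,
    seed = if (!is.null(config)) config$seed else NULL
  )
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA,
                              null = "null"), file.path(dir, "meta.json"))
  invisible(dir)
}

#' Read a subject's epochs from the dataset container
#'
#' @param dir Directory holding `data.csv` and `meta.json`.
#' @return List of `ssvep_epoch`.
#' @export
read_subject_dataset <- function(dir) {
  data_path <- file.path(dir, "data.csv")
  meta_path <- file.path(dir, "meta.json")
  if (!file.exists(data_path) || !file.exists(meta_path))
    stop_domain("dataset container not found in ", dir)
  meta <- jsonlite::fromJSON(meta_path)
  mat <- as.matrix(utils::read.table(data_path, sep = ",", header = FALSE))
  if (ncol(mat) != meta$n_channels * meta$n_samples)
    stop_integrity("data.csv width does not match sidecar metadata")
  lapply(seq_len(nrow(mat)), function(i) {
    s <- matrix(mat[i, ], nrow = meta$n_channels, ncol = meta$n_samples)
    new_epoch(s, meta$labels[i], meta$sampling_rate, meta$subject_id)
  })
}

#' THU benchmark dataset loader (layout stub)
#'
#' Documents the directory layout expected for the public 40-target SSVEP
#' benchmark corpus when used as a pretraining source: one container
#' directory per subject (as written by [write_subject_dataset()]),
#' restricted to the occipital channels O1/Oz/O2 and the four target
#' frequencies used here, named `S1`, `S2`, .... This convenience loader
#' simply reads every such subdirectory; it is untested against the
#' original distribution files, which ship in a binary format this package
#' does not parse — convert them externally into the container layout.
#'
#' @param dir Root directory of converted per-subject containers.
#' @return List of per-subject epoch lists.
#' @export
read_thu_benchmark <- function(dir) {
  subs <- list.dirs(dir, recursive = FALSE)
  if (!length(subs))
    stop_domain("no per-subject container directories found under ", dir)
  lapply(subs, read_subject_dataset)
}
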