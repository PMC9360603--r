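# Multi-subject feature fusion: parallel channel stacking, serial
# frequency concatenation, and element-wise averaging.

new_fused <- function(values, kind, member_ids, class_index, bins_per_subject) {
  structure(list(
    values = values,
    kind = kind,
    member_ids = as.character(member_ids),
    class_index = as.integer(class_index),
    bins_per_subject = as.integer(bins_per_subject)
  ), class = "ssvep_fused")
}

#' @export
print.ssvep_fused <- function(x, ...) {
  cat(sprintf("<ssvep_fused> %s fusion of {%s}, class %d, %d x %d\n",
              x$kind, paste(x$member_ids, collapse = ", "), x$class_index,
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

check_fusable <- function(features) {
  if (!length(features)) stop_domain("no features to fuse")
  for (f in features) {
    stopifnot(inherits(f, "ssvep_features"))
    if (!f$normalized)
      stop_domain("fusion requires normalized features (subject ",
                  f$subject_id, " is unnormalized)")
  }
  bins <- vapply(features, function(f) ncol(f$values), integer(1))
  if (length(unique(bins)) != 1)
    stop_domain("members have differing bin counts: ",
                paste(bins, collapse = ", "))
  cls <- vapply(features, function(f) f$class_index, integer(1))
  if (length(unique(cls)) != 1)
    stop_domain("members carry differing class labels: ",
                paste(cls, collapse = ", "))
  invisible(features)
}

#' Parallel feature connection (channel-axis stacking)
#'
#' Stacks the K members' 3 x B feature matrices along the channel axis in
#' caller order (S1-O1, S1-Oz, S1-O2, S2-O1, ...), producing a (3K) x B
#' matrix: fusion in the spatial domain, adding feature lead channels.
#'
#' @param features Ordered list of normalized `ssvep_features` for the same
#'   trial, all with the same bin count and class label.
#' @return An `ssvep_fused` with `kind = "parallel"`.
#' @export
fuse_parallel <- function(features) {
  check_fusable(features)
  vals <- do.call(rbind, lapply(features, function(f) f$values))
  rownames(vals) <- unlist(lapply(features, function(f)
    paste(f$subject_id, f$channel_labels %||% c("O1", "Oz", "O2"), sep = "-")))
  new_fused(vals, "parallel",
            vapply(features, function(f) f$subject_id, character(1)),
            features[[1]]$class_index, ncol(features[[1]]$values))
}

#' Serial feature connection (frequency-axis concatenation)
#'
#' Concatenates the K members' spectra along the frequency axis per
#' channel, producing a 3 x (K B) matrix: the channel count is unchanged
#' while the spectral extent grows.
#'
#' @inheritParams fuse_parallel
#' @return An `ssvep_fused` with `kind = "serial"`.
#' @export
fuse_serial <- function(features) {
  check_fusable(features)
  vals <- do.call(cbind, lapply(features, function(f) f$values))
  rownames(vals) <- c("O1", "Oz", "O2")
  new_fused(vals, "serial",
            vapply(features, function(f) f$subject_id, character(1)),
            features[[1]]$class_index, ncol(features[[1]]$values))
}

#' Feature averaging
#'
#' Element-wise arithmetic mean of the K members' normalized feature
#' matrices; the result keeps the single-subject 3 x B shape and is
#' consumable by the single-person network.
#'
#' @inheritParams fuse_parallel
#' @return An `ssvep_fused` with `kind = "average"`.
#' @export
fuse_average <- function(features) {
  check_fusable(features)
  vals <- Reduce(`+`, lapply(features, function(f) f$values)) / length(features)
  rownames(vals) <- c("O1", "Oz", "O2")
  new_fused(vals, "average",
            vapply(features, function(f) f$subject_id, character(1)),
            features[[1]]$class_index, ncol(features[[1]]$values))
}

#' Align per-subject trial lists into per-trial tuples
#'
#' Enforces the collaborative-gaze assumption: all subjects' lists must be
#' equally long with identical label sequences; tuple k then collects every
#' subject's trial k.
#'
#' @param group List of per-subject lists of `ssvep_epoch` or
#'   `ssvep_features` (anything carrying `class_index`).
#' @return List of per-trial lists, one entry per subject.
#' @export
align_group_trials <- function(group) {
  if (!length(group)) stop_alignment("empty group")
  lens <- vapply(group, length, integer(1))
  if (length(unique(lens)) != 1)
    stop_alignment("subjects have differing trial counts: ",
                   paste(lens, collapse = ", "))
  labels <- lapply(group, function(subj)
    vapply(subj, function(tr) tr$class_index, integer(1)))
  ref <- labels[[1]]
  for (s in seq_along(labels)[-1]) {
    bad <- which(labels[[s]] != ref)
    if (length(bad))
      stop_alignment("label mismatch at trial ", bad[1], " (subject ", s,
                     "): ", labels[[s]][bad[1]], " vs ", ref[bad[1]])
  }
  lapply(seq_len(lens[1]), function(k) lapply(group, `[[`, k))
}

#' Fuse aligned per-trial feature tuples
#'
#' @param tuples Output of [align_group_trials()] on featurized data.
#' @param mode One of `"parallel"`, `"serial"`, `"average"`.
#' @return List of `ssvep_fused`, one per trial.
#' @export
fuse_dataset <- function(tuples, mode = c("parallel", "serial", "average")) {
  mode <- match.arg(mode)
  fuser <- switch(mode, parallel = fuse_parallel, serial = fuse_serial,
                  average = fuse_average)
  lapply(tuples, fuser)
}
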