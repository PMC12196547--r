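#' Scale a segmented step to a distance-free coordinate frame
#'
#' Recordings are made at varying camera distances, so raw pixel
#' coordinates carry an arbitrary scale. Each step is rescaled by its own
#' vertical extent: with statistics taken over all frames and all joints
#' of the step,
#' \deqn{x' = (x - \mathrm{mean}(x)) / (\max(y) - \min(y)), \qquad
#'       y' = (y - \min(y)) / (\max(y) - \min(y)),}
#' so x' is zero-mean, y' spans \[0, 1\], and the aspect ratio is
#' preserved (both axes share the divisor). Confidence values are left
#' untouched. The result is invariant to translation and uniform scaling
#' of the raw pixels.
#'
#' @param step numeric array `frames x joints x 3` (a slice of a
#'   `keypoint_sequence`, margins x/y/conf).
#' @return The scaled array, same shape.
#' @export
scale_step <- function(step) {
  stopifnot(is.array(step), length(dim(step)) == 3L, dim(step)[3] == 3L)
  yr <- range(step[, , 2])
  div <- yr[2] - yr[1]
  if (div <= 0) {
    stop("degenerate step: y coordinates have zero range; step rejected", call. = FALSE)
  }
  out <- step
  out[, , 1] <- (step[, , 1] - mean(step[, , 1])) / div
  out[, , 2] <- (step[, , 2] - yr[1]) / div
  out
}

#' Resample a step to a fixed frame count
#'
#' Every channel (x, y and confidence of every joint) is piecewise-linearly
#' interpolated at `target_len` uniformly spaced positions spanning the
#' original frame range, endpoints included. The same rule is used for
#' both up- and down-sampling, so resampling is deterministic and
#' preserves endpoints and the monotonicity of monotone channels.
#'
#' @param step numeric array `frames x joints x 3` with at least 2 frames.
#' @param target_len output frame count (default 50).
#' @param trim if `TRUE`, steps longer than `target_len` are trimmed to the
#'   first `target_len` frames instead of being interpolated.
#' @return Array `target_len x joints x 3`.
#' @export
resample_step <- function(step, target_len = 50, trim = FALSE) {
  stopifnot(is.array(step), length(dim(step)) == 3L)
  n <- dim(step)[1]
  if (n < 2) stop("single-frame step rejected", call. = FALSE)
  if (trim && n >= target_len) {
    return(step[seq_len(target_len), , , drop = FALSE])
  }
  if (n == target_len) {
    return(step)
  }
  xout <- seq(1, n, length.out = target_len)
  out <- array(0, dim = c(target_len, dim(step)[2], dim(step)[3]))
  for (j in seq_len(dim(step)[2])) {
    for (ch in seq_len(dim(step)[3])) {
      out[, j, ch] <- approx(seq_len(n), step[, j, ch], xout = xout)$y
    }
  }
  dimnames(out) <- dimnames(step)
  out
}

# step array (50 x 13 x 3) -> 50 x 39 feature matrix, columns interleaved
# per joint: j0_x, j0_y, j0_c, j1_x, ...
.step_to_features <- function(step) {
  matrix(aperm(step, c(1, 3, 2)), nrow = dim(step)[1])
}

#' Build a step-sample dataset from segmented recordings
#'
#' Applies joint reduction, per-step scaling ([scale_step()]) and length
#' resampling ([resample_step()]) to every step boundary of every
#' recording, producing fixed-shape `target_len x 39` feature matrices
#' (13 joints x (x', y', conf)) per view. Degenerate steps (zero y range
#' or a single frame) are skipped.
#'
#' @param recordings list of `dual_view_recording` objects.
#' @param boundaries list of boundary tibbles (as from [extract_steps()]),
#'   parallel to `recordings`.
#' @param labels integer vector parallel to `recordings`; 0 = healthy
#'   control (HC), 1 = Parkinson's disease (PD).
#' @param target_len frames per step after resampling (default 50).
#' @param trim see [resample_step()].
#' @return An object of class `step_dataset`: a list with `info` (tibble:
#'   `sample_id, subject_id, label, raw_length`) and arrays `frontal`,
#'   `lateral` of dimension `target_len x 39 x n_samples`.
#' @export
build_step_dataset <- function(recordings, boundaries, labels, target_len = 50,
                               trim = FALSE) {
  stopifnot(
    length(recordings) == length(boundaries),
    length(recordings) == length(labels)
  )
  front <- list()
  lat <- list()
  info <- list()
  for (r in seq_along(recordings)) {
    rec <- recordings[[r]]
    f <- rec$frontal
    l <- rec$lateral
    if (f$joint_layout == "coco17") f <- suppressWarnings(select_joints(f))
    if (l$joint_layout == "coco17") l <- suppressWarnings(select_joints(l))
    bd <- boundaries[[r]]
    if (nrow(bd) == 0) next
    for (i in seq_len(nrow(bd))) {
      span <- bd$start_frame[i]:bd$end_frame[i]
      if (length(span) < 2) next
      sf <- tryCatch(
        resample_step(scale_step(f$coords[span, , , drop = FALSE]), target_len, trim),
        error = function(e) NULL
      )
      sl <- tryCatch(
        resample_step(scale_step(l$coords[span, , , drop = FALSE]), target_len, trim),
        error = function(e) NULL
      )
      if (is.null(sf) || is.null(sl)) next
      front[[length(front) + 1L]] <- .step_to_features(sf)
      lat[[length(lat) + 1L]] <- .step_to_features(sl)
      info[[length(info) + 1L]] <- tibble::tibble(
        subject_id = f$subject_id, label = as.integer(labels[r]),
        raw_length = length(span)
      )
    }
  }
  if (length(front) == 0) {
    stop("no valid steps found in the supplied recordings", call. = FALSE)
  }
  info <- dplyr::bind_rows(info)
  info$sample_id <- seq_len(nrow(info))
  info <- dplyr::relocate(info, "sample_id")
  structure(
    list(
      info = info,
      frontal = array(unlist(front), dim = c(target_len, ncol(front[[1]]), length(front))),
      lateral = array(unlist(lat), dim = c(target_len, ncol(lat[[1]]), length(lat)))
    ),
    class = "step_dataset"
  )
}

#' @export
print.step_dataset <- function(x, ...) {
  cat(
    "<step_dataset>", dim(x$frontal)[3], "steps from",
    dplyr::n_distinct(x$info$subject_id), "subjects |",
    dim(x$frontal)[1], "x", dim(x$frontal)[2], "per view |",
    sum(x$info$label == 1), "PD /", sum(x$info$label == 0), "HC\n"
  )
  invisible(x)
}

#' @export
as_tibble.step_dataset <- function(x, ...) x$info

#' Subset a step dataset by sample index
#' @param ds a `step_dataset`.
#' @param idx integer or logical sample index.
#' @export
subset_steps <- function(ds, idx) {
  structure(
    list(
      info = ds$info[idx, , drop = FALSE],
      frontal = ds$frontal[, , idx, drop = FALSE],
      lateral = ds$lateral[, , idx, drop = FALSE]
    ),
    class = "step_dataset"
  )
}

#' Fit z-score statistics on a training set
#'
#' Column-wise (per feature, per view) mean and standard deviation,
#' computed over all frames and samples of the supplied dataset — in a
#' cross-validated run, the training folds only, so that validation data
#' never leak into the statistics. Zero-variance columns are flagged and
#' later passed through centred only.
#'
#' @param ds a `step_dataset` restricted to the training samples.
#' @return An object of class `zscore_stats`.
#' @export
zscore_fit <- function(ds) {
  if (dim(ds$frontal)[3] < 2) stop("need at least 2 samples to fit z-scores", call. = FALSE)
  col_stats <- function(a) {
    m <- apply(a, 2, mean)
    s <- apply(a, 2, sd)
    list(mu = m, sigma = s)
  }
  fs <- col_stats(ds$frontal)
  ls <- col_stats(ds$lateral)
  if (any(fs$sigma == 0) || any(ls$sigma == 0)) {
    warning("zero-variance feature column(s); passing through centred only")
  }
  structure(list(frontal = fs, lateral = ls), class = "zscore_stats")
}

#' Apply stored z-score statistics to a dataset
#'
#' @param ds a `step_dataset`.
#' @param stats a `zscore_stats` object from [zscore_fit()].
#' @return The standardized `step_dataset`.
#' @export
zscore_apply <- function(ds, stats) {
  stopifnot(inherits(stats, "zscore_stats"))
  std <- function(a, st) {
    s <- ifelse(st$sigma == 0, 1, st$sigma)
    sweep(sweep(a, 2, st$mu, "-"), 2, s, "/")
  }
  out <- ds
  out$frontal <- std(ds$frontal, stats$frontal)
  out$lateral <- std(ds$lateral, stats$lateral)
  out
}
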