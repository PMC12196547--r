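#' Construct a keypoint sequence
#'
#' A keypoint sequence holds one camera view of one recording: an ordered
#' stack of per-frame joint observations, each joint an (x, y, confidence)
#' triple in pixel/unitless units. Coordinates follow the image convention
#' by default (y grows downward).
#'
#' @param coords numeric array of dimension `frames x joints x 3`, the last
#'   margin ordered (x, y, conf).
#' @param subject_id character scalar identifying the person recorded.
#' @param view `"frontal"` or `"lateral"`.
#' @param fps frames per second (default 30).
#' @param joint_layout `"coco17"` or `"reduced13"`.
#' @param frame_index optional integer vector of original frame numbers;
#'   defaults to `1:frames`. Must be strictly increasing and gap-free.
#' @return An object of class `keypoint_sequence`.
#' @export
keypoint_sequence <- function(coords, subject_id, view = c("lateral", "frontal"),
                              fps = 30, joint_layout = c("coco17", "reduced13"),
                              frame_index = NULL) {
  view <- match.arg(view)
  joint_layout <- match.arg(joint_layout)
  if (!is.array(coords) || length(dim(coords)) != 3L || dim(coords)[3] != 3L) {
    stop("`coords` must be a frames x joints x 3 array", call. = FALSE)
  }
  if (dim(coords)[1] < 1L) stop("sequence must contain at least one frame", call. = FALSE)
  if (dim(coords)[2] != .n_joints(joint_layout)) {
    stop(
      "layout '", joint_layout, "' expects ", .n_joints(joint_layout),
      " joints, got ", dim(coords)[2],
      call. = FALSE
    )
  }
  if (!(fps > 0)) stop("`fps` must be positive", call. = FALSE)
  conf <- coords[, , 3]
  if (anyNA(coords)) stop("keypoint coordinates contain NA", call. = FALSE)
  if (any(conf < 0 | conf > 1)) {
    stop("confidence values must lie in [0, 1]", call. = FALSE)
  }
  if (is.null(frame_index)) frame_index <- seq_len(dim(coords)[1])
  if (length(frame_index) != dim(coords)[1]) {
    stop("`frame_index` length must match frame count", call. = FALSE)
  }
  if (any(diff(frame_index) <= 0)) {
    stop("frame index must be strictly increasing", call. = FALSE)
  }
  if (any(diff(frame_index) != 1)) {
    stop("frame index contains gaps; fill or re-extract the recording", call. = FALSE)
  }
  dimnames(coords) <- list(NULL, .joint_names(joint_layout), c("x", "y", "conf"))
  structure(
    list(
      subject_id = as.character(subject_id), view = view, fps = fps,
      joint_layout = joint_layout, coords = coords,
      frame_index = as.integer(frame_index)
    ),
    class = "keypoint_sequence"
  )
}

#' @export
print.keypoint_sequence <- function(x, ...) {
  cat(
    "<keypoint_sequence> subject", x$subject_id, "|", x$view, "view |",
    n_frames(x), "frames @", x$fps, "fps |", x$joint_layout, "layout\n"
  )
  invisible(x)
}

#' Number of frames in a keypoint sequence
#' @param seq a `keypoint_sequence`.
#' @export
n_frames <- function(seq) dim(seq$coords)[1]

#' @export
as_tibble.keypoint_sequence <- function(x, ...) {
  wide <- .coords_to_wide(x$coords)
  tibble::as_tibble(cbind(data.frame(frame = x$frame_index), wide))
}

# frames x joints x 3 array -> data.frame with j<k>_x/_y/_c columns
.coords_to_wide <- function(coords) {
  nj <- dim(coords)[2]
  out <- matrix(aperm(coords, c(1, 3, 2)), nrow = dim(coords)[1])
  colnames(out) <- as.vector(vapply(
    seq_len(nj) - 1L,
    function(j) paste0("j", j, c("_x", "_y", "_c")), character(3)
  ))
  as.data.frame(out)
}

.wide_to_coords <- function(mat, nj) {
  aperm(array(as.matrix(mat), dim = c(nrow(mat), 3, nj)), c(1, 3, 2))
}

#' Read a keypoint file
#'
#' Two plain-text dialects are supported: CSV with a header
#' `frame,j0_x,j0_y,j0_c,...` (one row per frame) and JSON-lines with one
#' object `{"frame": n, "joints": [[x, y, c], ...]}` per line. The dialect
#' is chosen from the file extension (`.csv` vs `.jsonl`/`.ndjson`) unless
#' `format` is given. Files must contain 17 joints per frame (COCO layout)
#' or 13 (reduced layout).
#'
#' @param path file path.
#' @param view `"frontal"` or `"lateral"`.
#' @param subject_id subject identifier; defaults to the file stem.
#' @param fps frames per second.
#' @param format `"auto"`, `"csv"` or `"jsonl"`.
#' @return A [keypoint_sequence()].
#' @export
read_keypoints <- function(path, view, subject_id = NULL, fps = 30,
                           format = c("auto", "csv", "jsonl")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.(jsonl|ndjson)$", path, ignore.case = TRUE)) "jsonl" else "csv"
  }
  if (is.null(subject_id)) subject_id <- sub("\\.[^.]+$", "", basename(path))
  if (format == "csv") {
    df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
    if (!"frame" %in% names(df)) stop("missing 'frame' column in ", path, call. = FALSE)
    ncoord <- ncol(df) - 1L
    if (ncoord %% 3L != 0L) {
      stop("malformed keypoint CSV ", path, ": ", ncoord,
        " coordinate columns is not a multiple of 3",
        call. = FALSE
      )
    }
    nj <- ncoord %/% 3L
    bad <- which(!stats::complete.cases(df))
    if (length(bad) > 0) {
      stop("malformed row at line ", bad[1] + 1L, " of ", path, call. = FALSE)
    }
    coords <- .wide_to_coords(df[, -1, drop = FALSE], nj)
    frame_index <- df$frame
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    recs <- lapply(seq_along(lines), function(i) {
      rec <- tryCatch(jsonlite::fromJSON(lines[i]),
        error = function(e) stop("malformed row at line ", i, " of ", path, call. = FALSE)
      )
      if (is.null(rec$frame) || is.null(rec$joints)) {
        stop("malformed row at line ", i, " of ", path, call. = FALSE)
      }
      rec
    })
    nj <- nrow(recs[[1]]$joints)
    coords <- array(0, dim = c(length(recs), nj, 3))
    for (i in seq_along(recs)) {
      jm <- as.matrix(recs[[i]]$joints)
      if (!identical(dim(jm), c(nj, 3L))) {
        stop("malformed row at line ", i, " of ", path, call. = FALSE)
      }
      coords[i, , ] <- jm
    }
    frame_index <- vapply(recs, function(r) as.integer(r$frame), integer(1))
  }
  if (any(diff(frame_index) <= 0)) {
    stop("non-monotone frame index in ", path, call. = FALSE)
  }
  layout <- switch(as.character(nj),
    "17" = "coco17",
    "13" = "reduced13",
    stop("expected 17 or 13 joints per frame, got ", nj, " in ", path, call. = FALSE)
  )
  keypoint_sequence(coords, subject_id, view,
    fps = fps, joint_layout = layout,
    frame_index = frame_index
  )
}

#' Write a keypoint sequence to disk
#'
#' Inverse of [read_keypoints()]; the round trip preserves coordinates to
#' full double precision in both dialects.
#'
#' @param seq a [keypoint_sequence()].
#' @param path destination path; extension selects the dialect unless
#'   `format` is given.
#' @param format `"auto"`, `"csv"` or `"jsonl"`.
#' @return `path`, invisibly.
#' @export
write_keypoints <- function(seq, path, format = c("auto", "csv", "jsonl")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(jsonl|ndjson)$", path, ignore.case = TRUE)) "jsonl" else "csv"
  }
  if (format == "csv") {
    df <- cbind(data.frame(frame = seq$frame_index), .coords_to_wide(seq$coords))
    readr::write_csv(df, path, progress = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    for (i in seq_len(n_frames(seq))) {
      writeLines(jsonlite::toJSON(
        list(frame = seq$frame_index[i], joints = unname(seq$coords[i, , ])),
        auto_unbox = TRUE, digits = NA
      ), con)
    }
  }
  invisible(path)
}

#' Reduce a COCO-17 sequence to the 13 gait joints
#'
#' Drops both eyes and both ears; the remaining joints keep the COCO
#' relative order (see [reduced13_joints]). The reduction is a pure
#' projection: retained joints are untouched.
#'
#' @param seq a `keypoint_sequence` in `coco17` layout. An already reduced
#'   sequence is returned unchanged with a warning.
#' @return The sequence in `reduced13` layout.
#' @export
select_joints <- function(seq) {
  stopifnot(inherits(seq, "keypoint_sequence"))
  if (seq$joint_layout == "reduced13") {
    warning("sequence already in reduced13 layout; returning unchanged")
    return(seq)
  }
  keypoint_sequence(seq$coords[, .reduced13_idx, , drop = FALSE],
    subject_id = seq$subject_id, view = seq$view, fps = seq$fps,
    joint_layout = "reduced13", frame_index = seq$frame_index
  )
}

#' Pair synchronized frontal and lateral recordings
#'
#' The two views are assumed temporally aligned at recording time; any
#' residual length mismatch (e.g. trailing frames dropped by the pose
#' estimator in one view) is resolved by truncating both to the common
#' length. No resynchronization is attempted.
#'
#' @param frontal,lateral `keypoint_sequence` objects for the same subject
#'   with matching fps.
#' @return An object of class `dual_view_recording` with elements
#'   `frontal` and `lateral` of equal frame count.
#' @export
make_dual_view <- function(frontal, lateral) {
  stopifnot(inherits(frontal, "keypoint_sequence"), inherits(lateral, "keypoint_sequence"))
  if (frontal$view != "frontal" || lateral$view != "lateral") {
    stop("arguments must be a frontal and a lateral sequence, in that order",
      call. = FALSE
    )
  }
  if (frontal$subject_id != lateral$subject_id) {
    stop(
      "cannot pair recordings of different subjects: '",
      frontal$subject_id, "' vs '", lateral$subject_id, "'",
      call. = FALSE
    )
  }
  if (frontal$fps != lateral$fps) {
    stop("frame rates differ between views", call. = FALSE)
  }
  n <- min(n_frames(frontal), n_frames(lateral))
  trunc_seq <- function(s) {
    if (n_frames(s) == n) {
      s
    } else {
      keypoint_sequence(s$coords[seq_len(n), , , drop = FALSE],
        subject_id = s$subject_id,
        view = s$view, fps = s$fps, joint_layout = s$joint_layout,
        frame_index = s$frame_index[seq_len(n)]
      )
    }
  }
  structure(
    list(frontal = trunc_seq(frontal), lateral = trunc_seq(lateral)),
    class = "dual_view_recording"
  )
}

#' @export
print.dual_view_recording <- function(x, ...) {
  cat(
    "<dual_view_recording> subject", x$frontal$subject_id, "|",
    n_frames(x$frontal), "aligned frames\n"
  )
  invisible(x)
}

#' Read a subject priors table
#'
#' Physiological prior information, one row per subject, with columns
#' `subject_id, sex, age, height, weight, bmi, shoe_size, step_duration`
#' (sex coded +1 male / -1 female; height cm; weight kg; shoe size EU;
#' step duration seconds). A missing `bmi` column is recomputed as
#' weight / (height in m)^2.
#'
#' @param path CSV file path.
#' @return A tibble with the columns above.
#' @export
read_priors <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  needed <- c("subject_id", "sex", "age", "height", "weight", "shoe_size", "step_duration")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0) {
    stop("priors file lacks column(s): ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  if (!"bmi" %in% names(df)) {
    df$bmi <- df$weight / (df$height / 100)^2
  }
  if (!all(df$sex %in% c(-1, 1))) {
    stop("`sex` must be coded +1 (male) / -1 (female)", call. = FALSE)
  }
  dplyr::select(
    df, "subject_id", "sex", "age", "height", "weight", "bmi",
    "shoe_size", "step_duration"
  )
}

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble
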