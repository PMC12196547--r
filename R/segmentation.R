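#' Savitzky-Golay filter parameters
#'
#' @param window_size odd window length in frames (default 45).
#' @param poly_order polynomial order (default 6); must be below the window
#'   size.
#' @export
filter_params <- function(window_size = 45, poly_order = 6) {
  if (window_size %% 2 != 1) stop("`window_size` must be odd", call. = FALSE)
  if (poly_order >= window_size) {
    stop("`poly_order` must be smaller than `window_size`", call. = FALSE)
  }
  structure(list(window_size = as.integer(window_size), poly_order = as.integer(poly_order)),
    class = "filter_params"
  )
}

#' Peak selection parameters
#'
#' `window_size` is the local-extremum neighbourhood of the sliding-window
#' peak search, `min_separation` the minimum frame gap enforced between
#' retained peaks, and `prominence_threshold` the minimum peak prominence.
#' When `prominence_threshold` is `NULL` it is derived per recording as
#' mean body height / 20 (see [mean_body_height()]).
#'
#' @param window_size sliding window width in frames (default 30).
#' @param min_separation minimum distance between peaks in frames (default 30).
#' @param prominence_threshold minimum prominence in signal units, or `NULL`.
#' @export
peak_params <- function(window_size = 30, min_separation = 30,
                        prominence_threshold = NULL) {
  stopifnot(window_size > 0, min_separation > 0)
  if (!is.null(prominence_threshold) && prominence_threshold < 0) {
    stop("`prominence_threshold` must be non-negative", call. = FALSE)
  }
  structure(
    list(
      window_size = as.integer(window_size),
      min_separation = as.integer(min_separation),
      prominence_threshold = prominence_threshold
    ),
    class = "peak_params"
  )
}

#' Savitzky-Golay smoothing
#'
#' Local least-squares polynomial smoothing: each output sample is the
#' value at the window centre of the polynomial of order `poly_order`
#' fitted to the surrounding `window_size` samples. Near the series edges
#' the window is truncated to the available samples (no padding), so no
#' data are invented where gait events may sit. The filter reproduces any
#' polynomial of degree `<= poly_order` exactly and preserves extremum
#' locations of smooth periodic signals.
#'
#' @param x numeric series, at least `window_size` long.
#' @param params a [filter_params()] object.
#' @return Smoothed series of the same length.
#' @export
sg_smooth <- function(x, params = filter_params()) {
  stopifnot(inherits(params, "filter_params"))
  n <- length(x)
  w <- params$window_size
  p <- params$poly_order
  if (n < w) {
    stop("series of length ", n, " is shorter than the smoothing window (", w,
      "); skip this recording",
      call. = FALSE
    )
  }
  h <- (w - 1L) %/% 2L
  # interior: single convolution row of the least-squares projector;
  # positions are scaled to [-1, 1] to keep the Vandermonde system
  # well-conditioned, which leaves the fitted value at the centre unchanged
  V <- outer((-h:h) / h, 0:p, "^")
  coef <- qr.solve(V, diag(w))[1L, ] # value at position 0 = intercept of the fit
  out <- as.numeric(stats::filter(x, rev(coef), sides = 2))
  # edges: explicit truncated-window fits
  edge_fit <- function(i) {
    lo <- max(1L, i - h)
    hi <- min(n, i + h)
    Ve <- outer((seq(lo, hi) - i) / h, 0:p, "^")
    fit <- qr.coef(qr(Ve), x[lo:hi])
    fit[1]
  }
  edge_idx <- c(seq_len(min(h, n)), seq(max(1L, n - h + 1L), n))
  edge_idx <- unique(edge_idx[edge_idx >= 1 & edge_idx <= n])
  out[edge_idx] <- vapply(edge_idx, edge_fit, numeric(1))
  out
}

#' Ankle elevation series
#'
#' Extracts the selected ankle's elevation over time from a lateral-view
#' sequence. Under the image convention (`y_axis = "down"`, the default)
#' pixel y grows downward, so elevation is the negated y coordinate and
#' foot landings are local minima of elevation.
#'
#' @param seq lateral-view `keypoint_sequence` in `reduced13` layout.
#' @param side `"left"` or `"right"`.
#' @param y_axis `"down"` (image convention) or `"up"`.
#' @return Numeric vector, one elevation value per frame.
#' @export
foot_elevation <- function(seq, side = c("right", "left"), y_axis = c("down", "up")) {
  side <- match.arg(side)
  y_axis <- match.arg(y_axis)
  stopifnot(inherits(seq, "keypoint_sequence"))
  if (seq$view != "lateral") {
    stop("foot elevation requires the lateral view", call. = FALSE)
  }
  if (seq$joint_layout != "reduced13") {
    stop("reduce the sequence with select_joints() first", call. = FALSE)
  }
  y <- seq$coords[, .joint_index(seq, paste0(side, "_ankle")), 2]
  if (y_axis == "down") -y else y
}

#' Mean body height of a recording
#'
#' Per-frame height is the absolute difference between the head (nose)
#' y coordinate and the midpoint of the two ankle y coordinates; the mean
#' over frames scales the default peak prominence threshold
#' (mean height / 20).
#'
#' @param seq lateral-view `keypoint_sequence` in `reduced13` layout.
#' @return Mean height in pixel units.
#' @export
mean_body_height <- function(seq) {
  stopifnot(inherits(seq, "keypoint_sequence"))
  if (seq$joint_layout != "reduced13") {
    stop("reduce the sequence with select_joints() first", call. = FALSE)
  }
  y_head <- seq$coords[, .joint_index(seq, "nose"), 2]
  y_mid <- (seq$coords[, .joint_index(seq, "left_ankle"), 2] +
    seq$coords[, .joint_index(seq, "right_ankle"), 2]) / 2
  mean(abs(y_head - y_mid))
}

# Local maxima of `x` with prominence, sliding-window candidate search.
# Returns a data.frame(index, height, prominence), unfiltered.
.find_peaks <- function(x, window_size) {
  n <- length(x)
  h <- window_size %/% 2L
  cand <- logical(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - h)
    hi <- min(n, i + h)
    cand[i] <- x[i] >= max(x[lo:hi])
  }
  # collapse plateau runs of equal value to their first index
  idx <- which(cand)
  if (length(idx) > 1) {
    drop <- c(FALSE, diff(idx) == 1 & diff(x[idx]) == 0)
    idx <- idx[!drop]
  }
  if (length(idx) == 0) {
    return(data.frame(index = integer(0), height = numeric(0), prominence = numeric(0)))
  }
  prom <- vapply(idx, function(i) {
    # extend left/right until the signal exceeds the peak or the edge
    left_min <- NA_real_
    j <- i - 1L
    m <- Inf
    while (j >= 1L && x[j] <= x[i]) {
      m <- min(m, x[j])
      j <- j - 1L
    }
    if (is.finite(m)) left_min <- m
    right_min <- NA_real_
    j <- i + 1L
    m <- Inf
    while (j <= n && x[j] <= x[i]) {
      m <- min(m, x[j])
      j <- j + 1L
    }
    if (is.finite(m)) right_min <- m
    base <- max(left_min, right_min, na.rm = TRUE)
    if (!is.finite(base)) 0 else x[i] - base
  }, numeric(1))
  data.frame(index = idx, height = x[idx], prominence = prom)
}

#' Detect foot-landing frames
#'
#' Landings are local minima of the (smoothed) elevation series. The
#' series is negated so that a sliding-window peak search can be applied:
#' candidates must be the maximum of their surrounding window, carry a
#' prominence above the threshold (suppressing flat, stationary spans),
#' and respect the minimum separation. When two candidates conflict the
#' deeper landing wins; exact ties keep the earlier frame. Each retained
#' minimum is then relocalized by a least-squares quadratic fit over its
#' surrounding half-window — the raw argmin rides on residual noise,
#' while the vertex of the local parabola averages it out; the shift is
#' capped at 3 frames and skipped at the series edges, and the result is
#' rounded back to a frame index.
#'
#' @param elevation numeric elevation series (smooth it first with
#'   [sg_smooth()]).
#' @param params a [peak_params()] object; `prominence_threshold` must be
#'   set (callers working from a recording use mean height / 20).
#' @param refine apply the quadratic vertex relocalization (default TRUE).
#' @return Strictly increasing integer frame indices.
#' @export
detect_landings <- function(elevation, params = peak_params(prominence_threshold = 0),
                            refine = TRUE) {
  if (length(elevation) == 0) stop("empty elevation series", call. = FALSE)
  thr <- params$prominence_threshold
  if (is.null(thr)) {
    stop("`prominence_threshold` is NULL; derive it from the recording first",
      call. = FALSE
    )
  }
  pk <- .find_peaks(-elevation, params$window_size)
  pk <- pk[pk$prominence > max(thr, 0), , drop = FALSE]
  if (nrow(pk) == 0) {
    return(integer(0))
  }
  # greedy min-separation filter: deeper (higher on the negated curve)
  # first, ties broken by prominence then by earlier frame
  ord <- order(-pk$height, -pk$prominence, pk$index)
  kept <- integer(0)
  for (i in ord) {
    if (all(abs(pk$index[i] - kept) >= params$min_separation)) {
      kept <- c(kept, pk$index[i])
    }
  }
  kept <- sort(kept)
  if (refine) {
    n <- length(elevation)
    m <- params$window_size %/% 2L
    refined <- vapply(kept, function(i) {
      lo <- i - m
      hi <- i + m
      if (lo < 1 || hi > n) {
        return(as.numeric(i)) # truncated window would bias the vertex
      }
      tt <- (lo:hi) - i
      cf <- stats::lm.fit(cbind(1, tt, tt^2), elevation[lo:hi])$coefficients
      if (is.na(cf[3]) || cf[3] <= 0) {
        return(as.numeric(i))
      }
      v <- -cf[2] / (2 * cf[3])
      i + max(-3, min(3, v))
    }, numeric(1))
    cand <- as.integer(round(refined))
    # refinement must not break ordering or the separation contract
    if (all(diff(cand) >= params$min_separation)) kept <- cand
  }
  as.integer(kept)
}

# Frames whose centred sliding window has peak-to-trough elevation
# amplitude below the threshold are stationary.
.stationary_mask <- function(elevation, window_size, threshold) {
  n <- length(elevation)
  h <- window_size %/% 2L
  out <- logical(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - h)
    hi <- min(n, i + h)
    win <- elevation[lo:hi]
    out[i] <- (max(win) - min(win)) < threshold
  }
  out
}

#' Segment a recording into single steps
#'
#' A single step runs from a right-foot landing to the next left-foot
#' landing. Both ankles' lateral-view elevation curves are smoothed with a
#' Savitzky-Golay filter and their minima located by the sliding-window
#' peak search; each right landing is paired with the first left landing
#' that follows it before the next right landing. Steps intersecting
#' stationary spans (windowed elevation amplitude below the prominence
#' threshold) are discarded, as are steps outside the admissible duration
#' range. The same frame boundaries apply to the temporally aligned
#' frontal view.
#'
#' @param rec a `dual_view_recording` (or a lateral `keypoint_sequence`).
#' @param fp [filter_params()].
#' @param pp [peak_params()]; a `NULL` prominence threshold is resolved to
#'   mean body height / 20 of the lateral sequence.
#' @param y_axis pixel y orientation, `"down"` (default) or `"up"`.
#' @param min_len,max_len admissible step duration in frames; steps outside
#'   `[min_len, max_len]` are dropped (guards against missed landings).
#' @param stationary_window width (frames) of the sliding window of the
#'   stationary test. It must span roughly one single step: near every
#'   elevation extremum a sinusoid is locally flat, so a window much
#'   shorter than the gait period would flag normal landings as
#'   stationary. Default `3 * min_separation + 1`, comfortably above one
#'   single step even for slow gait.
#' @return A tibble of class `step_boundaries` with columns `start_frame`,
#'   `end_frame`; segmentation curves are attached as attributes for
#'   [autoplot()].
#' @export
extract_steps <- function(rec, fp = filter_params(), pp = peak_params(),
                          y_axis = c("down", "up"), min_len = 20, max_len = 120,
                          stationary_window = 3 * pp$min_separation + 1) {
  y_axis <- match.arg(y_axis)
  lat <- if (inherits(rec, "dual_view_recording")) rec$lateral else rec
  stopifnot(inherits(lat, "keypoint_sequence"))
  if (lat$view != "lateral") stop("lateral view required for segmentation", call. = FALSE)
  if (lat$joint_layout == "coco17") lat <- suppressWarnings(select_joints(lat))

  elev_r <- sg_smooth(foot_elevation(lat, "right", y_axis), fp)
  elev_l <- sg_smooth(foot_elevation(lat, "left", y_axis), fp)
  thr <- pp$prominence_threshold
  if (is.null(thr)) thr <- mean_body_height(lat) / 20
  ppr <- peak_params(pp$window_size, pp$min_separation, thr)

  right <- detect_landings(elev_r, ppr)
  left <- detect_landings(elev_l, ppr)
  # the two ankles oscillate in antiphase, so each curve is tested on its
  # own; a frame is stationary only when both feet are flat around it
  stationary <- .stationary_mask(elev_r, stationary_window, thr) &
    .stationary_mask(elev_l, stationary_window, thr)

  boundaries <- list()
  if (length(right) > 0 && length(left) > 0) {
    next_right <- c(right[-1], Inf)
    for (k in seq_along(right)) {
      l_ok <- left[left > right[k] & left < next_right[k]]
      if (length(l_ok) == 0) next
      boundaries[[length(boundaries) + 1L]] <- c(right[k], l_ok[1])
    }
  }
  res <- if (length(boundaries) > 0) {
    bm <- do.call(rbind, boundaries)
    keep <- vapply(seq_len(nrow(bm)), function(i) {
      len <- bm[i, 2] - bm[i, 1]
      len >= min_len && len <= max_len && !any(stationary[bm[i, 1]:bm[i, 2]])
    }, logical(1))
    tibble::tibble(start_frame = as.integer(bm[keep, 1]), end_frame = as.integer(bm[keep, 2]))
  } else {
    tibble::tibble(start_frame = integer(0), end_frame = integer(0))
  }
  structure(res,
    class = c("step_boundaries", class(res)),
    elevation_right = elev_r, elevation_left = elev_l,
    landings_right = right, landings_left = left,
    stationary = stationary, threshold = thr,
    subject_id = lat$subject_id
  )
}
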