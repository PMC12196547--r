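# Internal: run code under a temporary RNG seed, restoring global state.
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Gait parameters for the synthetic generator
#'
#' Phenomenological description of one subject's walk, sufficient to
#' exercise segmentation, normalization, fusion and training; this is not
#' a biomechanical simulation.
#'
#' @param class `"HC"` or `"PD"` (carried through to labels).
#' @param cadence steps per second; one single step (right-foot landing to
#'   the following left-foot landing) lasts `fps / cadence` frames, so the
#'   full gait cycle lasts twice that.
#' @param stride_amp peak foot-lift amplitude in pixels.
#' @param step_len forward travel per single step, pixels.
#' @param sway_amp lateral sway amplitude in the frontal view, pixels.
#' @param tremor_sd standard deviation of white coordinate noise, pixels.
#' @param conf_shape length-2 Beta shape parameters for the per-joint
#'   confidence channel.
#' @param stationary_pad frames of standing still prepended and appended.
#' @export
gait_params <- function(class = c("HC", "PD"), cadence = 0.6, stride_amp = 40,
                        step_len = 90, sway_amp = 15, tremor_sd = 0.8,
                        conf_shape = c(18, 2), stationary_pad = 60) {
  class <- match.arg(class)
  stopifnot(cadence > 0, stride_amp >= 0, step_len >= 0, sway_amp >= 0, tremor_sd >= 0)
  structure(
    list(
      class = class, cadence = cadence, stride_amp = stride_amp,
      step_len = step_len, sway_amp = sway_amp, tremor_sd = tremor_sd,
      conf_shape = conf_shape, stationary_pad = as.integer(stationary_pad)
    ),
    class = "gait_params"
  )
}

# joint heights above ground (px) for a ~350 px body, reduced13 order is
# derived from these plus eyes/ears near the nose
.joint_geometry <- function() {
  list(
    height = c(
      nose = 345, left_eye = 350, right_eye = 350, left_ear = 347,
      right_ear = 347, left_shoulder = 290, right_shoulder = 290,
      left_elbow = 240, right_elbow = 240, left_wrist = 190, right_wrist = 190,
      left_hip = 180, right_hip = 180, left_knee = 90, right_knee = 90,
      left_ankle = 5, right_ankle = 5
    ),
    # signed x offsets from the body midline in the frontal view
    frontal_dx = c(
      nose = 0, left_eye = 6, right_eye = -6, left_ear = 12, right_ear = -12,
      left_shoulder = 40, right_shoulder = -40, left_elbow = 50,
      right_elbow = -50, left_wrist = 55, right_wrist = -55,
      left_hip = 25, right_hip = -25, left_knee = 22, right_knee = -22,
      left_ankle = 20, right_ankle = -20
    )
  )
}

#' Generate one synthetic dual-view recording
#'
#' Kinematics: both ankles follow sinusoidal elevation curves in antiphase
#' (half-cycle shift), so foot landings are exact zeros of elevation; the
#' rest of the skeleton (hips, knees, torso, head, arms) is interpolated
#' smoothly around a body that advances at constant speed. The lateral
#' view is the sagittal projection (x = forward progress, y = vertical,
#' image convention y-down); the frontal view is the coronal projection
#' with lateral sway and a distance-dependent scale drift (the subject
#' approaches the camera), which makes the two views' feature
#' distributions genuinely different. Oscillation amplitude ramps in over
#' the first gait cycle and out over the last one so walking joins the
#' stationary pads continuously; only landings inside the steady span are
#' recorded as ground truth.
#'
#' @param params a [gait_params()] object.
#' @param duration_s recording length in seconds (including pads); must
#'   allow at least two full gait cycles of walking.
#' @param fps frames per second.
#' @param seed integer RNG seed; the same seed reproduces the recording
#'   bit for bit.
#' @param subject_id subject identifier.
#' @return A list with `recording` (a `dual_view_recording`, coco17
#'   layout) and `truth` (list: `boundaries` tibble of true
#'   `start_frame`/`end_frame`, `landings_right`, `landings_left`,
#'   `label`, `step_frames`).
#' @export
synth_subject <- function(params, duration_s = 30, fps = 30, seed = 1,
                          subject_id = "S1") {
  stopifnot(inherits(params, "gait_params"))
  .with_seed(seed, {
    n <- round(duration_s * fps)
    pad <- params$stationary_pad
    half <- fps / params$cadence # frames per single step
    period <- 2 * half # frames per gait cycle
    walk0 <- pad + 1L # first walking frame (1-based)
    walk1 <- n - pad # last walking frame
    if ((walk1 - walk0 + 1) < 2 * period + 2) {
      stop("duration too short for two gait cycles plus pads", call. = FALSE)
    }
    geom <- .joint_geometry()
    ground_y <- 500
    t <- seq_len(n)
    tw <- pmin(pmax(t - walk0, 0), walk1 - walk0) # clamped walking time
    phase <- 2 * pi * tw / period
    # amplitude envelope: 0 in pads, ramps over half a cycle at each end,
    # so every ground-truth landing has full-amplitude swing peaks on both
    # sides (truth keeps a full-period margin from the ramps)
    env <- pmin(1, pmin(tw, (walk1 - walk0) - tw) / (period / 2))
    env[t < walk0 | t > walk1] <- 0

    elev_r <- params$stride_amp / 2 * (1 - cos(phase)) * env
    elev_l <- params$stride_amp / 2 * (1 + cos(phase)) * env
    speed <- params$step_len / half
    body_x <- 150 + speed * tw
    swing_r <- params$step_len / 2 * sin(phase) * env
    swing_l <- -params$step_len / 2 * sin(phase) * env

    nj <- length(coco17_joints)
    lat <- array(0, dim = c(n, nj, 3))
    fro <- array(0, dim = c(n, nj, 3))
    bob <- 3 * sin(2 * phase) * env
    for (j in seq_len(nj)) {
      nm <- coco17_joints[j]
      h <- geom$height[[nm]]
      if (nm == "right_ankle") {
        y <- ground_y - h - elev_r
        x <- body_x + swing_r
      } else if (nm == "left_ankle") {
        y <- ground_y - h - elev_l
        x <- body_x + swing_l
      } else if (nm == "right_knee") {
        y <- ground_y - h - elev_r / 2 - 4 * (1 - cos(phase)) * env
        x <- body_x + swing_r / 2
      } else if (nm == "left_knee") {
        y <- ground_y - h - elev_l / 2 - 4 * (1 + cos(phase)) * env
        x <- body_x + swing_l / 2
      } else if (nm %in% c("right_wrist", "right_elbow")) {
        y <- ground_y - h + bob
        x <- body_x + 0.25 * swing_l # arms swing opposite the legs
      } else if (nm %in% c("left_wrist", "left_elbow")) {
        y <- ground_y - h + bob
        x <- body_x + 0.25 * swing_r
      } else {
        y <- ground_y - h + bob
        x <- body_x
      }
      lat[, j, 1] <- x
      lat[, j, 2] <- y
      # frontal view: midline + sway + fixed lateral offset, same heights,
      # scale drifting as the subject approaches the camera
      scale_t <- 0.85 + 0.3 * tw / max(tw)
      cx <- 960 + params$sway_amp * sin(pi * tw / period) * env + geom$frontal_dx[[nm]]
      fro[, j, 1] <- 960 + (cx - 960) * scale_t
      fro[, j, 2] <- ground_y - (ground_y - y) * scale_t
    }
    lat[, , 1:2] <- lat[, , 1:2] + rnorm(n * nj * 2, sd = params$tremor_sd)
    fro[, , 1:2] <- fro[, , 1:2] + rnorm(n * nj * 2, sd = params$tremor_sd)
    lat[, , 3] <- rbeta(n * nj, params$conf_shape[1], params$conf_shape[2])
    fro[, , 3] <- rbeta(n * nj, params$conf_shape[1], params$conf_shape[2])

    # ground truth: landings in the steady (env == 1) span
    steady0 <- walk0 + period
    steady1 <- walk1 - period
    k <- seq(1, floor((walk1 - walk0) / period))
    r_land <- walk0 + k * period
    l_land <- r_land + half
    keep <- r_land >= steady0 - 1e-9 & l_land <= steady1 + 1e-9
    truth <- tibble::tibble(
      start_frame = r_land[keep],
      end_frame = l_land[keep]
    )
    rec <- make_dual_view(
      keypoint_sequence(fro, subject_id, "frontal", fps, "coco17"),
      keypoint_sequence(lat, subject_id, "lateral", fps, "coco17")
    )
    list(
      recording = rec,
      truth = list(
        boundaries = truth,
        landings_right = r_land[r_land >= steady0 - 1e-9 & r_land <= steady1 + 1e-9],
        landings_left = l_land[l_land >= steady0 - 1e-9 & l_land <= steady1 + 1e-9],
        label = if (params$class == "PD") 1L else 0L,
        step_frames = half
      )
    )
  })
}

#' Generate a synthetic cohort with class-dependent gait
#'
#' Per-subject gait parameters are drawn from class-conditional
#' distributions. Relative to healthy controls, the PD class has reduced
#' foot-lift amplitude and step length, elevated high-frequency tremor
#' noise and a slightly longer single-step duration; `effect_size` scales
#' all class mean shifts (0 = identical distributions, the null cohort;
#' 1 = the default separation). Subject priors (sex, age, height, weight,
#' BMI, shoe size, realized step duration) are drawn with class-dependent
#' means so that priors correlate with the label.
#'
#' @param n_subjects number of subjects (>= 2 per class after the split).
#' @param pd_frac fraction of PD subjects (default 0.28, matching a
#'   roughly 0.72:0.28 class imbalance).
#' @param effect_size scale of all class mean differences.
#' @param duration_s recording length per subject, seconds.
#' @param fps frames per second.
#' @param seed integer RNG seed.
#' @return A list of class `synth_cohort`: `recordings` (list of
#'   `dual_view_recording`), `truth` (list, per subject), `labels`
#'   (0 HC / 1 PD), `priors` (tibble as in [read_priors()]), `params`
#'   (list of realized [gait_params()]).
#' @export
synth_cohort <- function(n_subjects = 60, pd_frac = 0.28, effect_size = 1,
                         duration_s = 30, fps = 30, seed = 1) {
  n_pd <- round(n_subjects * pd_frac)
  n_hc <- n_subjects - n_pd
  if (n_pd < 2 || n_hc < 2) stop("need at least 2 subjects per class", call. = FALSE)
  labels <- c(rep(0L, n_hc), rep(1L, n_pd))
  e <- effect_size
  .with_seed(seed, {
    subj_seeds <- sample.int(2^30, n_subjects)
    out <- list(recordings = list(), truth = list(), params = list())
    priors <- list()
    # two full gait cycles (4 single steps) plus pads must fit the recording
    max_step_frames <- floor((duration_s * fps - 2 * 60 - 2) / 4)
    for (i in seq_len(n_subjects)) {
      pd <- labels[i] == 1L
      step_frames <- min(max_step_frames, max(25, rnorm(1, mean = 50 + 4 * e * pd, sd = 3)))
      par <- gait_params(
        class = if (pd) "PD" else "HC",
        cadence = fps / step_frames,
        stride_amp = max(5, rnorm(1, 40 - 12 * e * pd, 3)),
        step_len = max(20, rnorm(1, 90 - 30 * e * pd, 8)),
        sway_amp = max(0, rnorm(1, 15, 2)),
        tremor_sd = max(0.05, rnorm(1, 0.8 + 1.2 * e * pd, 0.15))
      )
      sid <- sprintf("S%03d", i)
      sub <- synth_subject(par, duration_s, fps, seed = subj_seeds[i], subject_id = sid)
      out$recordings[[i]] <- sub$recording
      out$truth[[i]] <- sub$truth
      out$params[[i]] <- par
      sex <- sample(c(1, -1), 1)
      height <- rnorm(1, 165.6 - 0.3 * e * pd, 7.3)
      weight <- rnorm(1, 69.2 - 2.9 * e * pd, 12)
      priors[[i]] <- tibble::tibble(
        subject_id = sid, sex = sex,
        age = rnorm(1, 55.8 + 6.9 * e * pd, 9.5),
        height = height, weight = weight,
        bmi = weight / (height / 100)^2,
        shoe_size = rnorm(1, if (sex == 1) 41.5 else 37.5, 1),
        step_duration = step_frames / fps
      )
    }
    structure(
      list(
        recordings = out$recordings, truth = out$truth, labels = labels,
        priors = dplyr::bind_rows(priors), params = out$params
      ),
      class = "synth_cohort"
    )
  })
}

#' @export
print.synth_cohort <- function(x, ...) {
  cat(
    "<synth_cohort>", length(x$recordings), "subjects (",
    sum(x$labels == 1), "PD /", sum(x$labels == 0), "HC )\n"
  )
  invisible(x)
}

#' Segment and normalize a synthetic cohort into a step dataset
#'
#' Convenience pipeline: runs [extract_steps()] on every recording and
#' assembles the [build_step_dataset()] result.
#'
#' @param cohort a [synth_cohort()] result.
#' @param use_truth if `TRUE`, use the generator's true boundaries instead
#'   of detected ones (useful to isolate the model from segmentation).
#' @param ... passed to [extract_steps()].
#' @return A `step_dataset`.
#' @export
cohort_step_dataset <- function(cohort, use_truth = FALSE, ...) {
  boundaries <- if (use_truth) {
    lapply(cohort$truth, function(tr) {
      dplyr::mutate(tr$boundaries,
        start_frame = as.integer(round(.data$start_frame)),
        end_frame = as.integer(round(.data$end_frame))
      )
    })
  } else {
    lapply(cohort$recordings, extract_steps, ...)
  }
  build_step_dataset(cohort$recordings, boundaries, cohort$labels)
}
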