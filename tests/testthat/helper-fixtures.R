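# Shared fixture builders. Everything is generated in code; nothing is
# read from disk except the bundled reference fold table.

# a small, fast network configuration used by network/objective tests
tiny_config <- function(depth = 2) {
  model_config(
    seq_len = 6, embed_dim = 6, heads = 2, ffn_dim = 8, dropout = 0,
    depth = depth, state_dim = 4, chunk_size = 3
  )
}

random_inputs <- function(cfg, n = 3, seed = 1) {
  set.seed(seed)
  list(
    frontal = array(rnorm(cfg$seq_len * cfg$embed_dim * n),
      dim = c(cfg$seq_len, cfg$embed_dim, n)
    ),
    lateral = array(rnorm(cfg$seq_len * cfg$embed_dim * n),
      dim = c(cfg$seq_len, cfg$embed_dim, n)
    )
  )
}

# minimal valid keypoint array: frames x joints x (x, y, conf)
random_coords <- function(frames, joints = 17, seed = 1) {
  set.seed(seed)
  coords <- array(0, dim = c(frames, joints, 3))
  coords[, , 1] <- matrix(rnorm(frames * joints, 500, 50), frames)
  coords[, , 2] <- matrix(rnorm(frames * joints, 400, 60), frames)
  coords[, , 3] <- matrix(runif(frames * joints), frames)
  coords
}

# lateral recording whose ankle elevation minima sit at chosen frames:
# right ankle y follows -cos with minima of elevation at `right_minima`,
# left ankle likewise; all other joints static
crafted_recording <- function(n_frames, right_period, left_period,
                              right_phase0, left_phase0, amp = 40,
                              subject_id = "crafted") {
  mk_view <- function(view) {
    coords <- array(0, dim = c(n_frames, 17, 3))
    t <- seq_len(n_frames) - 1
    heights <- c(
      345, 350, 350, 347, 347, 290, 290, 240, 240, 190, 190,
      180, 180, 90, 90, 5, 5
    )
    for (j in 1:17) {
      coords[, j, 1] <- 300 + j
      coords[, j, 2] <- 500 - heights[j]
      coords[, j, 3] <- 0.9
    }
    # elevation = amp/2 (1 - cos(...)), minima where the cosine peaks
    er <- amp / 2 * (1 - cos(2 * pi * (t - right_phase0) / right_period))
    el <- amp / 2 * (1 - cos(2 * pi * (t - left_phase0) / left_period))
    coords[, 17, 2] <- 495 - er # right_ankle
    coords[, 16, 2] <- 495 - el # left_ankle
    keypoint_sequence(coords, subject_id, view, joint_layout = "coco17")
  }
  make_dual_view(mk_view("frontal"), mk_view("lateral"))
}

# random step slices for normalization tests
random_step <- function(len, joints = 13, seed = 1) {
  set.seed(seed)
  step <- array(0, dim = c(len, joints, 3))
  step[, , 1] <- matrix(rnorm(len * joints, 300, 40), len)
  step[, , 2] <- matrix(rnorm(len * joints, 400, 80), len)
  step[, , 3] <- matrix(runif(len * joints), len)
  step
}

# tremor level for a given RMS signal-to-noise ratio of the elevation curve
tremor_for_snr <- function(stride_amp, snr) stride_amp / (2 * sqrt(2)) / snr
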