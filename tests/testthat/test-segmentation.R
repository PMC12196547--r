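test_that("SG smoothing reproduces polynomials and matches per-window fits", {
  fp <- filter_params()
  # degree-0: constants pass through untouched
  expect_equal(sg_smooth(rep(3.2, 100), fp), rep(3.2, 100), tolerance = 1e-9)
  # any polynomial up to the filter order is reproduced exactly,
  # including the truncated edge windows
  t <- seq(0, 1, length.out = 120)
  for (deg in c(1, 3, 6)) {
    y <- rowSums(outer(t, 0:deg, "^"))
    expect_equal(sg_smooth(y, fp), y, tolerance = 1e-7)
  }
  # degree above the order is NOT reproduced (the filter does smooth)
  y8 <- (10 * (t - 0.5))^8
  expect_gt(max(abs(sg_smooth(y8, fp) - y8)), 1e-3)
  # noisy series: every interior value equals the centred LS fit of its
  # own window (direct lm oracle)
  set.seed(42)
  x <- sin(seq(0, 6 * pi, length.out = 200)) + rnorm(200, sd = 0.3)
  sm <- sg_smooth(x, fp)
  h <- (fp$window_size - 1) %/% 2
  for (i in c(23, 77, 140, 178)) {
    win <- (i - h):(i + h)
    fit <- lm(y ~ poly(tt, fp$poly_order, raw = TRUE),
      data = data.frame(y = x[win], tt = win - i)
    )
    expect_equal(sm[i], unname(coef(fit)[1]), tolerance = 1e-6)
  }
})

test_that("SG interior coefficients agree with the signal package", {
  skip_if_not_installed("signal")
  set.seed(7)
  x <- cumsum(rnorm(300))
  fp <- filter_params(21, 4)
  ours <- sg_smooth(x, fp)
  ref <- signal::sgolayfilt(x, p = 4, n = 21)
  interior <- 30:270
  expect_equal(ours[interior], ref[interior], tolerance = 1e-8)
})

test_that("landing detection finds cosine minima and honours parameters", {
  t <- 0:299
  elevation <- -cos(2 * pi * t / 60)
  found <- detect_landings(elevation, peak_params(prominence_threshold = 0.5))
  # analytic minima at t = 0, 60, ..., 240 (1-based indices 1, 61, ...);
  # the truncated series may add one extra minimum at its very end
  for (m in seq(1, 241, by = 60)) expect_true(min(abs(found - m)) <= 1)
  extras <- found[sapply(found, function(f) min(abs(f - seq(1, 241, by = 60)))) > 1]
  expect_true(all(extras >= 299))
  # flat series yields nothing even at zero threshold
  expect_identical(detect_landings(rep(1, 100), peak_params(prominence_threshold = 0)), integer(0))
  expect_error(detect_landings(numeric(0)), "empty")
  # returned indices respect the minimum separation
  expect_true(all(diff(found) >= 30))
})

test_that("minimum separation keeps the deeper of two close minima", {
  # two minima 10 frames apart, the second one deeper; brute-force over
  # the candidate set confirms the deeper one is the admissible optimum
  t <- 1:200
  elevation <- 5 - 3 * exp(-(t - 100)^2 / 8) - 5 * exp(-(t - 110)^2 / 8)
  found <- detect_landings(elevation,
    peak_params(min_separation = 30, prominence_threshold = 1),
    refine = FALSE
  )
  cand <- c(100, 110)
  subsets <- list(100, 110, c(100, 110))
  admissible <- Filter(function(s) length(s) < 2 || min(diff(s)) >= 30, subsets)
  best <- admissible[[which.min(vapply(admissible, function(s) min(elevation[s]), numeric(1)))]]
  expect_equal(found, as.integer(best))
})

test_that("mean body height scales the prominence threshold", {
  coords <- array(0, dim = c(5, 13, 3))
  coords[, , 3] <- 0.9
  coords[, 1, 2] <- 0 # nose
  coords[, 12, 2] <- 100 # left ankle
  coords[, 13, 2] <- 100 # right ankle
  seq13 <- keypoint_sequence(coords, "s", "lateral", joint_layout = "reduced13")
  expect_equal(mean_body_height(seq13), 100)
  expect_equal(mean_body_height(seq13) / 20, 5.0)
  seq2 <- seq13
  seq2$coords[, , 2] <- seq2$coords[, , 2] * 2
  expect_equal(mean_body_height(seq2), 200)
})

test_that("foot elevation follows the configured pixel-y orientation", {
  coords <- array(0.5, dim = c(100, 13, 3))
  y <- 400 + 30 * cos(2 * pi * (0:99) / 50)
  coords[, 13, 2] <- y # right ankle: y maxima at frames 1, 51
  seq13 <- keypoint_sequence(coords, "s", "lateral", joint_layout = "reduced13")
  down <- foot_elevation(seq13, "right", "down")
  expect_equal(down, -y)
  expect_equal(which.min(down[10:60]) + 9L, 51L) # y maximum = elevation minimum
  expect_equal(foot_elevation(seq13, "right", "up"), y)
  expect_error(
    foot_elevation(keypoint_sequence(array(0.5, c(5, 13, 3)), "s", "frontal",
      joint_layout = "reduced13"
    ), "right"),
    "lateral"
  )
})

test_that("steps pair each right landing with the next left landing", {
  # right-ankle minima at frames 31, 91, ...; left at 61, 121, ...
  rec <- crafted_recording(160,
    right_period = 60, left_period = 60,
    right_phase0 = 30, left_phase0 = 60
  )
  bd <- extract_steps(rec,
    pp = peak_params(prominence_threshold = 5),
    min_len = 20, max_len = 120
  )
  expect_gte(nrow(bd), 2)
  hits <- function(a, b) any(abs(bd$start_frame - a) <= 1 & abs(bd$end_frame - b) <= 1)
  expect_true(hits(31, 61))
  expect_true(hits(91, 121))
  # boundaries are ordered and non-overlapping
  expect_true(all(diff(bd$start_frame) > 0))
  expect_true(all(bd$end_frame > bd$start_frame))
  expect_true(all(head(bd$end_frame, -1) <= tail(bd$start_frame, -1)))
})

test_that("a right landing without a following left landing is discarded", {
  # left minima all BEFORE the right ones within each cycle
  rec <- crafted_recording(140,
    right_period = 200, left_period = 200,
    right_phase0 = 100, left_phase0 = 60
  )
  bd <- extract_steps(rec, pp = peak_params(prominence_threshold = 5))
  expect_identical(nrow(bd), 0L)
})

test_that("segmentation is invariant to uniform vertical translation", {
  sub <- synth_subject(gait_params(), duration_s = 16, seed = 3, subject_id = "s")
  rec <- sub$recording
  rec2 <- rec
  rec2$lateral$coords[, , 2] <- rec2$lateral$coords[, , 2] + 137
  bd1 <- extract_steps(rec)
  bd2 <- extract_steps(rec2)
  expect_identical(bd1$start_frame, bd2$start_frame)
  expect_identical(bd1$end_frame, bd2$end_frame)
})

test_that("stationary recordings produce no boundaries", {
  # a standing subject: realistic joint heights, millimetre-level jitter
  set.seed(8)
  heights <- c(
    345, 350, 350, 347, 347, 290, 290, 240, 240, 190, 190,
    180, 180, 90, 90, 5, 5
  )
  coords <- array(0, dim = c(400, 17, 3))
  for (j in 1:17) {
    coords[, j, 1] <- 300 + j + rnorm(400, sd = 0.3)
    coords[, j, 2] <- 500 - heights[j] + rnorm(400, sd = 0.3)
    coords[, j, 3] <- 0.9
  }
  still <- make_dual_view(
    keypoint_sequence(coords, "s", "frontal"),
    keypoint_sequence(coords, "s", "lateral")
  )
  expect_identical(nrow(extract_steps(still)), 0L)
})
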