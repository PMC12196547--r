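test_that("keypoint files round-trip through both dialects", {
  coords <- random_coords(3)
  seq0 <- keypoint_sequence(coords, "s1", "lateral")
  for (ext in c("csv", "jsonl")) {
    path <- file.path(withr::local_tempdir(), paste0("kp.", ext))
    write_keypoints(seq0, path)
    back <- read_keypoints(path, "lateral", subject_id = "s1")
    expect_equal(back$coords, seq0$coords, tolerance = 1e-12)
    expect_identical(back$frame_index, seq0$frame_index)
    expect_identical(n_frames(back), 3L)
  }
})

test_that("malformed keypoint files are rejected with informative errors", {
  dir <- withr::local_tempdir()
  # 16 joints per frame
  bad <- file.path(dir, "bad16.csv")
  df <- as.data.frame(matrix(runif(2 * 48), nrow = 2))
  names(df) <- as.vector(vapply(0:15, function(j) paste0("j", j, c("_x", "_y", "_c")), character(3)))
  readr::write_csv(cbind(data.frame(frame = 1:2), df), bad)
  expect_error(read_keypoints(bad, "lateral"), "17 or 13")
  # non-monotone frame index
  seq0 <- keypoint_sequence(random_coords(3), "s1", "lateral")
  good <- file.path(dir, "kp.csv")
  write_keypoints(seq0, good)
  tab <- readr::read_csv(good, show_col_types = FALSE)
  tab$frame <- c(1, 3, 2)
  readr::write_csv(tab, good)
  expect_error(read_keypoints(good, "lateral"), "monotone")
  # row with a missing cell names its line
  tab$frame <- 1:3
  tab$j0_x[2] <- NA
  readr::write_csv(tab, good)
  expect_error(read_keypoints(good, "lateral"), "line 3")
})

test_that("joint reduction drops eyes and ears and nothing else", {
  seq17 <- keypoint_sequence(random_coords(4), "s1", "lateral")
  seq13 <- select_joints(seq17)
  expect_identical(seq13$joint_layout, "reduced13")
  expect_identical(dim(seq13$coords)[2], 13L)
  expect_identical(13L * 3L, 39L) # feature width used by the model input
  kept <- setdiff(coco17_joints, c("left_eye", "right_eye", "left_ear", "right_ear"))
  expect_identical(dimnames(seq13$coords)[[2]], kept)
  # pure projection: retained joints are bitwise identical
  expect_identical(
    seq13$coords[, , ],
    seq17$coords[, match(kept, coco17_joints), ]
  )
  expect_warning(select_joints(seq13), "already")
})

test_that("excluded joints cannot influence downstream features", {
  co <- synth_subject(gait_params(), duration_s = 16, seed = 5, subject_id = "s1")
  rec <- co$recording
  rec2 <- rec
  for (v in c("frontal", "lateral")) {
    rec2[[v]]$coords[, 2:5, 1:2] <- rec2[[v]]$coords[, 2:5, 1:2] + 1e4
  }
  bd <- extract_steps(rec)
  ds1 <- build_step_dataset(list(rec), list(bd), labels = 0L)
  ds2 <- build_step_dataset(list(rec2), list(extract_steps(rec2)), labels = 0L)
  expect_equal(ds1$frontal, ds2$frontal, tolerance = 1e-12)
  expect_equal(ds1$lateral, ds2$lateral, tolerance = 1e-12)
})

test_that("dual-view pairing truncates to the common length symmetrically", {
  f <- keypoint_sequence(random_coords(300, seed = 1), "s1", "frontal")
  l <- keypoint_sequence(random_coords(298, seed = 2), "s1", "lateral")
  rec <- make_dual_view(f, l)
  expect_identical(n_frames(rec$frontal), 298L)
  expect_identical(n_frames(rec$lateral), 298L)
  # equal-length input passes through unchanged
  l2 <- keypoint_sequence(random_coords(300, seed = 2), "s1", "lateral")
  rec2 <- make_dual_view(f, l2)
  expect_identical(rec2$frontal$coords, f$coords)
  # swapping which view is longer yields the same common length
  f2 <- keypoint_sequence(random_coords(298, seed = 1), "s1", "frontal")
  l3 <- keypoint_sequence(random_coords(300, seed = 2), "s1", "lateral")
  expect_identical(n_frames(make_dual_view(f2, l3)$frontal), 298L)
  # mismatched subjects refuse to pair
  g <- keypoint_sequence(random_coords(300), "OTHER", "frontal")
  expect_error(make_dual_view(g, l), "different subjects")
})

test_that("priors tables are validated and BMI recomputed when absent", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "priors.csv")
  df <- data.frame(
    subject_id = c("a", "b"), sex = c(1, -1), age = c(60, 55),
    height = c(170, 160), weight = c(70, 60), shoe_size = c(42, 37),
    step_duration = c(1.6, 1.7)
  )
  readr::write_csv(df, path)
  pri <- read_priors(path)
  expect_equal(pri$bmi, df$weight / (df$height / 100)^2)
  df$sex <- c(1, 2)
  readr::write_csv(df, path)
  expect_error(read_priors(path), "sex")
})
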