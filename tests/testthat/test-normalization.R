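test_that("step scaling enforces the coordinate conventions exactly", {
  # hand case: y in {0, 2}, x in {1, 3} -> y' in {0, 1}, x' in {-0.5, 0.5}
  step <- array(0, dim = c(2, 1, 3))
  step[, 1, 1] <- c(1, 3)
  step[, 1, 2] <- c(0, 2)
  step[, 1, 3] <- c(0.9, 0.8)
  sc <- scale_step(step)
  expect_equal(as.numeric(sc[, 1, 1]), c(-0.5, 0.5))
  expect_equal(as.numeric(sc[, 1, 2]), c(0, 1))
  expect_equal(sc[, , 3], step[, , 3]) # confidences untouched

  # forced invariants on random steps
  for (s in 1:5) {
    st <- random_step(sample(20:80, 1), seed = s)
    out <- scale_step(st)
    expect_equal(min(out[, , 2]), 0, tolerance = 1e-9)
    expect_equal(max(out[, , 2]), 1, tolerance = 1e-9)
    expect_equal(mean(out[, , 1]), 0, tolerance = 1e-9)
    # aspect ratio preserved: both axes share the divisor
    expect_equal(
      diff(range(out[, , 1])) / diff(range(out[, , 2])),
      diff(range(st[, , 1])) / diff(range(st[, , 2])),
      tolerance = 1e-9
    )
  }
})

test_that("step scaling is invariant to translation and uniform scaling", {
  st <- random_step(40, seed = 3)
  ref <- scale_step(st)
  moved <- st
  moved[, , 1] <- st[, , 1] * 2 + 123
  moved[, , 2] <- st[, , 2] * 2 - 55
  out <- scale_step(moved)
  expect_equal(out[, , 1:2], ref[, , 1:2], tolerance = 1e-9)
})

test_that("degenerate steps are rejected", {
  flat <- random_step(10)
  flat[, , 2] <- 7
  expect_error(scale_step(flat), "degenerate")
  one <- random_step(10)[1, , , drop = FALSE]
  expect_error(resample_step(one), "single-frame")
})

test_that("resampling interpolates linearly with both endpoints kept", {
  # 2-frame step (0, 2) -> 50 values linearly spaced 0..2
  st <- array(0, dim = c(2, 1, 3))
  st[, 1, 1] <- c(0, 2)
  out <- resample_step(st, 50)
  expect_equal(as.numeric(out[, 1, 1]), seq(0, 2, length.out = 50))
  # interpolating halfway between (0,0) and (1,2) gives 1
  expect_equal(out[which.min(abs(seq(0, 1, length.out = 50) - 0.5)), 1, 1],
    2 * seq(0, 1, length.out = 50)[25],
    tolerance = 1e-12
  )
  # matching length is the identity
  st50 <- random_step(50, seed = 2)
  expect_equal(resample_step(st50, 50), st50)
  # monotone channels stay monotone, endpoints preserved, under down- and
  # up-sampling alike
  for (len in c(23, 50, 87)) {
    stm <- random_step(len, seed = len)
    stm[, 1, 1] <- sort(stm[, 1, 1])
    out <- resample_step(stm, 50)
    expect_equal(dim(out), c(50, 13, 3))
    expect_true(all(diff(out[, 1, 1]) >= -1e-12))
    expect_equal(out[1, , ], stm[1, , ])
    expect_equal(out[50, , ], stm[len, , ])
  }
})

test_that("trim mode reproduces plain truncation", {
  st <- random_step(70, seed = 4)
  out <- resample_step(st, 50, trim = TRUE)
  expect_equal(out, st[1:50, , ])
})

test_that("the full preprocessing path only emits 50 x 39 matrices", {
  co <- synth_cohort(n_subjects = 6, duration_s = 16, seed = 21)
  ds <- cohort_step_dataset(co)
  expect_identical(dim(ds$frontal)[1:2], c(50L, 39L))
  expect_identical(dim(ds$lateral)[1:2], c(50L, 39L))
  expect_identical(dim(ds$frontal)[3], nrow(ds$info))
  expect_true(all(ds$info$label %in% c(0L, 1L)))
})

test_that("z-scoring uses stored training statistics without leakage", {
  co <- synth_cohort(n_subjects = 6, duration_s = 16, seed = 22)
  ds <- cohort_step_dataset(co)
  idx <- ds$info$sample_id[seq_len(floor(nrow(ds$info) / 2))]
  tr <- subset_steps(ds, idx)
  st <- zscore_fit(tr)
  std_tr <- zscore_apply(tr, st)
  # training portion standardized per column
  expect_equal(mean(apply(std_tr$frontal, 2, mean)), 0, tolerance = 1e-8)
  expect_equal(as.numeric(apply(std_tr$lateral, 2, sd)), rep(1, 39), tolerance = 1e-2)
  # idempotence oracle: reapplying stored stats to a copy reproduces output
  expect_equal(zscore_apply(tr, st), std_tr)
  # stats differ from those of the full dataset (so they cannot have leaked)
  st_full <- zscore_fit(ds)
  expect_false(isTRUE(all.equal(st$frontal$mu, st_full$frontal$mu)))
})
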