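test_that("the learning-rate schedule hits its anchors", {
  cfg <- train_config()
  expect_equal(learning_rate(0, cfg), 1e-8)
  expect_equal(learning_rate(200, cfg), 1e-4)
  expect_equal(learning_rate(599, cfg), 1e-4)
  expect_equal(learning_rate(1000, cfg), 1e-6)
  # linear inside the warm-up and decay phases
  expect_equal(learning_rate(100, cfg), 1e-8 + (1e-4 - 1e-8) / 2)
  expect_equal(learning_rate(800, cfg), 1e-4 + (1e-6 - 1e-4) / 2)
  expect_error(learning_rate(-1, cfg), "out of range")
  expect_error(learning_rate(1001, cfg), "out of range")
  expect_error(train_config(warmup_end = 700, constant_end = 600), "phases")
  # the scaled protocol keeps the anchor ratios
  r <- reduced_train_config(epochs = 60, lr_peak = 1e-3)
  expect_equal(learning_rate(0, r), 1e-7)
  expect_equal(learning_rate(60, r), 1e-5)
  expect_equal(learning_rate(30, r), 1e-3)
})

test_that("grouped folds partition subjects, never samples", {
  co <- synth_cohort(n_subjects = 10, duration_s = 16, seed = 31)
  ds <- cohort_step_dataset(co)
  folds <- grouped_kfold(ds$info, k = 5, seed = 1)
  # exactly 2 subjects per fold for 10 subjects / 5 folds
  expect_equal(as.integer(table(folds$fold)), rep(2L, 5))
  # every subject assigned exactly once
  expect_setequal(folds$subject_id, unique(ds$info$subject_id))
  expect_false(any(duplicated(folds$subject_id)))
  # sample-level view: folds are disjoint and cover everything
  fold_of <- folds$fold[match(ds$info$subject_id, folds$subject_id)]
  expect_false(anyNA(fold_of))
  expect_equal(sort(unique(fold_of)), 1:5)
  # deterministic under the seed
  expect_identical(folds, grouped_kfold(ds$info, k = 5, seed = 1))
  expect_error(grouped_kfold(ds$info[1, ], k = 5), "fewer subjects")
})

test_that("a short training run emits all artifacts and checkpoints the best F1", {
  co <- synth_cohort(n_subjects = 8, duration_s = 16, effect_size = 1.5, seed = 41)
  ds <- cohort_step_dataset(co)
  folds <- grouped_kfold(ds$info, k = 4, seed = 2)
  fold_of <- folds$fold[match(ds$info$subject_id, folds$subject_id)]
  tr <- subset_steps(ds, fold_of != 1)
  va <- subset_steps(ds, fold_of == 1)
  st <- zscore_fit(tr)
  fit <- train_fusion(
    zscore_apply(tr, st), zscore_apply(va, st),
    model_cfg = model_config(dropout = 0.1),
    train_cfg = reduced_train_config(epochs = 5, batch_size = 64),
    seed = 3, stats = st
  )
  expect_s3_class(fit, "fusion_fit")
  expect_equal(nrow(fit$log), 5)
  expect_true(all(c("loss", "loss_w", "loss_mmd", "val_f1") %in% names(fit$log)))
  # best-F1 checkpoint equals the maximum of the logged validation series
  logged <- ifelse(is.na(fit$log$val_f1), 0, fit$log$val_f1)
  best_f1 <- ifelse(is.na(fit$val_metrics$f1), 0, fit$val_metrics$f1)
  expect_equal(best_f1, max(logged))
  expect_equal(fit$best_epoch, which.max(logged) - 1L)
  # prediction plumbing: one row per validation sample, proper probabilities
  pred <- fit$val_predictions
  expect_equal(nrow(pred), sum(fold_of == 1))
  expect_equal(pred$p_hc + pred$p_pd, rep(1, nrow(pred)), tolerance = 1e-5)
  # checkpoint round trip
  path <- file.path(withr::local_tempdir(), "fit.rds")
  save_checkpoint(fit, path)
  back <- load_checkpoint(path)
  expect_equal(back$params, fit$params)
  p1 <- fusion_predict(back, va)
  expect_equal(p1$p_pd, fusion_predict(fit, va)$p_pd, tolerance = 1e-6)
  # tidy/glance accessors
  expect_s3_class(tidy(fit), "tbl_df")
  expect_equal(glance(fit)$best_epoch, fit$best_epoch)
})
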