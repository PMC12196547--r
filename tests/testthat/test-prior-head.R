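make_priors <- function(n, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    subject_id = sprintf("P%02d", seq_len(n)),
    sex = sample(c(1, -1), n, replace = TRUE),
    age = rnorm(n, 60, 9),
    height = rnorm(n, 166, 7),
    weight = rnorm(n, 68, 12),
    bmi = rnorm(n, 24.5, 3),
    shoe_size = rnorm(n, 40, 2),
    step_duration = rnorm(n, 1.7, 0.2)
  )
}

test_that("prior standardization centres every field on the training set", {
  pri <- make_priors(40)
  sp <- standardize_priors(pri)
  expect_equal(unname(colMeans(sp$z)), rep(0, 7), tolerance = 1e-10)
  expect_equal(unname(apply(sp$z, 2, sd)), rep(1, 7), tolerance = 1e-10)
  # ages {50, 70} against stored stats mu 60 sigma 10 -> {-1, +1}
  two <- make_priors(2)
  two$age <- c(50, 70)
  stats60 <- sp$stats
  stats60$mu["age"] <- 60
  stats60$sigma["age"] <- 10
  sp2 <- standardize_priors(two, stats60)
  expect_equal(unname(sp2$z[, "age"]), c(-1, 1))
  # stored statistics transfer to held-out subjects
  held <- make_priors(5, seed = 2)
  z_held <- standardize_priors(held, sp$stats)$z
  expect_equal(z_held[, "age"], (held$age - sp$stats$mu["age"]) / sp$stats$sigma["age"],
    ignore_attr = TRUE
  )
  # constant fields are flagged and passed through centred
  pri$sex <- 1
  expect_warning(spc <- standardize_priors(pri), "constant")
  expect_equal(unname(spc$z[, "sex"]), rep(0, 40))
  # incomplete vectors are refused
  pri2 <- make_priors(4)
  pri2$bmi[2] <- NA
  expect_error(standardize_priors(pri2), "missing")
  expect_error(standardize_priors(pri2[, -3]), "age")
})

test_that("prior adjustment respects the double-softmax form", {
  # zero weights: softmax is monotone, so the argmax never changes
  z <- matrix(rnorm(7), 1)
  W0 <- matrix(0, 7, 2)
  out <- adjust_with_priors(c(0.7, 0.3), z, W0, mode = "softmax")
  expect_gt(out[1], out[2])
  # hand case: base (0.7, 0.3) + adjustment (0, 0.2) -> softmax(0.7, 0.5)
  Wa <- matrix(0, 7, 2)
  z1 <- matrix(c(1, rep(0, 6)), 1)
  Wa[1, 2] <- 0.2
  out2 <- adjust_with_priors(c(0.7, 0.3), z1, Wa, mode = "softmax")
  expect_equal(as.numeric(out2), exp(c(0.7, 0.5)) / sum(exp(c(0.7, 0.5))),
    tolerance = 1e-12
  )
  # a large positive PD-column adjustment saturates the PD probability
  Wb <- matrix(0, 7, 2)
  Wb[1, 2] <- 100
  expect_gt(adjust_with_priors(c(0.9, 0.1), z1, Wb, mode = "softmax")[2], 0.999)
})

test_that("fitting the head moves only the head and finds a dominant prior", {
  # cohort where age alone carries the label; the frozen model is
  # uninformative (all probabilities 0.5)
  set.seed(33)
  n <- 120
  pri <- make_priors(n, seed = 33)
  labels <- as.integer(pri$age > 60)
  base <- matrix(0.5, n, 2)
  head <- fit_prior_head(base,
    priors = pri, labels = labels, epochs = 300,
    lr = 0.05
  )
  expect_s3_class(head, "prior_head")
  expect_identical(rownames(head$W), prior_fields)
  expect_identical(dim(head$W), c(7L, 2L))
  td <- tidy(head)
  expect_equal(nrow(td), 7)
  influence <- td$pd_influence
  names(influence) <- td$prior
  expect_identical(names(which.max(abs(influence))), "age")
  expect_gt(influence[["age"]], 0) # older pushes toward PD
  # adjusted predictions actually separate the classes
  z <- standardize_priors(pri, head$stats)$z
  adj <- adjust_with_priors(base, z, head)
  expect_gt(roc_auc(adj[, 2], labels), 0.9)
})

test_that("the frozen model is untouched by prior fine-tuning", {
  co <- synth_cohort(n_subjects = 8, duration_s = 16, effect_size = 1, seed = 77)
  ds <- cohort_step_dataset(co)
  st <- zscore_fit(ds)
  fit <- train_fusion(zscore_apply(ds, st), zscore_apply(ds, st),
    train_cfg = reduced_train_config(epochs = 2, batch_size = 64),
    seed = 5, stats = st
  )
  before <- fit$params
  head <- fit_prior_head(fit, ds = ds, priors = co$priors, epochs = 20)
  expect_identical(fit$params, before)
  # adjusted prediction pipeline runs end to end
  pred <- fusion_predict(fit, ds)
  z <- standardize_priors(
    co$priors[match(pred$subject_id, co$priors$subject_id), ],
    head$stats
  )$z
  adj <- adjust_with_priors(as.matrix(pred[, c("p_hc", "p_pd")]), z, head)
  expect_equal(rowSums(adj), rep(1, nrow(adj)), tolerance = 1e-9)
})
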