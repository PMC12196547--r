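#' Training configuration
#'
#' Optimization schedule: AdamW with a piecewise-linear learning-rate
#' profile — linear warm-up from `lr_start` to `lr_peak` over
#' `[0, warmup_end)`, constant `lr_peak` over `[warmup_end,
#' constant_end)`, linear decay to `lr_end` over `[constant_end, epochs]`.
#' The defaults are the full-scale protocol (1000 epochs, batch 3072,
#' 1e-8 to 1e-4 to 1e-6); [reduced_train_config()] gives a
#' proportionally scaled short protocol for CPU-sized experiments.
#'
#' @param epochs total epochs.
#' @param batch_size minibatch size.
#' @param lr_start,lr_peak,lr_end learning-rate schedule anchors.
#' @param warmup_end,constant_end phase boundaries in epochs.
#' @param beta1,beta2,eps AdamW moment parameters.
#' @param mmd_subsample number of samples per minibatch used by the MMD
#'   estimator (the regularizer is estimated on a random subset to bound
#'   its quadratic cost).
#' @param shape warm-up/decay interpolation, `"linear"` (default) or
#'   `"cosine"` for the decay phase.
#' @export
train_config <- function(epochs = 1000, batch_size = 3072,
                         lr_start = 1e-8, lr_peak = 1e-4, lr_end = 1e-6,
                         warmup_end = 200, constant_end = 600,
                         beta1 = 0.9, beta2 = 0.99, eps = 1e-8,
                         mmd_subsample = 64, shape = c("linear", "cosine")) {
  shape <- match.arg(shape)
  if (!(warmup_end <= constant_end && constant_end <= epochs)) {
    stop("schedule phases must satisfy warmup_end <= constant_end <= epochs",
      call. = FALSE
    )
  }
  structure(
    list(
      epochs = as.integer(epochs), batch_size = as.integer(batch_size),
      lr_start = lr_start, lr_peak = lr_peak, lr_end = lr_end,
      warmup_end = as.integer(warmup_end), constant_end = as.integer(constant_end),
      beta1 = beta1, beta2 = beta2, eps = eps,
      mmd_subsample = as.integer(mmd_subsample), shape = shape
    ),
    class = "train_config"
  )
}

#' Proportionally scaled short training protocol
#'
#' The full protocol scaled to a CPU-sized experiment: the phase
#' boundaries keep their 20/40/40 proportions and the learning-rate
#' anchors keep their ratios to the peak (start = peak * 1e-4,
#' end = peak * 1e-2). The peak itself is raised because far fewer
#' optimizer steps are taken.
#'
#' @param epochs total epochs (default 60).
#' @param batch_size minibatch size (default 256).
#' @param lr_peak peak learning rate (default 1e-3).
#' @param ... passed to [train_config()].
#' @export
reduced_train_config <- function(epochs = 60, batch_size = 256, lr_peak = 1e-3, ...) {
  train_config(
    epochs = epochs, batch_size = batch_size,
    lr_start = lr_peak * 1e-4, lr_peak = lr_peak, lr_end = lr_peak * 1e-2,
    warmup_end = round(epochs * 0.2), constant_end = round(epochs * 0.6),
    ...
  )
}

#' Learning rate at a given epoch
#'
#' @param epoch epoch index, `0 <= epoch <= epochs`.
#' @param cfg a [train_config()].
#' @return Learning rate.
#' @export
learning_rate <- function(epoch, cfg = train_config()) {
  if (any(epoch < 0 | epoch > cfg$epochs)) {
    stop("epoch out of range [0, ", cfg$epochs, "]", call. = FALSE)
  }
  warm <- cfg$warmup_end
  const <- cfg$constant_end
  out <- numeric(length(epoch))
  for (i in seq_along(epoch)) {
    e <- epoch[i]
    out[i] <- if (e < warm) {
      cfg$lr_start + (cfg$lr_peak - cfg$lr_start) * e / warm
    } else if (e < const) {
      cfg$lr_peak
    } else if (cfg$shape == "cosine") {
      cfg$lr_end + (cfg$lr_peak - cfg$lr_end) *
        (1 + cos(pi * (e - const) / (cfg$epochs - const))) / 2
    } else {
      cfg$lr_peak + (cfg$lr_end - cfg$lr_peak) * (e - const) / (cfg$epochs - const)
    }
  }
  out
}

# ---------------------------------------------------------------------------
# AdamW

.adamw_init <- function(params) {
  list(
    m = lapply(params, function(p) p * 0),
    v = lapply(params, function(p) p * 0),
    t = 0L
  )
}

.adamw_update <- function(params, grads, state, lr, cfg) {
  state$t <- state$t + 1L
  bc1 <- 1 - cfg$beta1^state$t
  bc2 <- 1 - cfg$beta2^state$t
  for (k in names(params)) {
    g <- grads[[k]]
    if (!is.matrix(params[[k]])) g <- as.numeric(g)
    state$m[[k]] <- cfg$beta1 * state$m[[k]] + (1 - cfg$beta1) * g
    state$v[[k]] <- cfg$beta2 * state$v[[k]] + (1 - cfg$beta2) * g^2
    params[[k]] <- params[[k]] -
      lr * (state$m[[k]] / bc1) / (sqrt(state$v[[k]] / bc2) + cfg$eps)
  }
  list(params = params, state = state)
}

# add d(lambda2 * |W|_1 + lambda3 * |W|_2^2)/dW to the weight-matrix grads
.add_reg_grads <- function(grads, params, weights) {
  if (weights$lambda2 == 0 && weights$lambda3 == 0) {
    return(grads)
  }
  for (k in names(params)) {
    if (is.matrix(params[[k]])) {
      grads[[k]] <- grads[[k]] + weights$lambda2 * sign(params[[k]]) +
        2 * weights$lambda3 * params[[k]]
    }
  }
  grads
}

# ---------------------------------------------------------------------------
# prediction

#' Predict step-level class probabilities
#'
#' Runs the compiled batched forward pass (dropout disabled) over a
#' standardized step dataset.
#'
#' @param object a `fusion_fit` (uses its best checkpoint and stored
#'   z-score statistics) or a raw parameter list.
#' @param ds a `step_dataset`; if `object` is a fit, the dataset is
#'   standardized with the fit's stored statistics unless
#'   `standardized = TRUE`.
#' @param config [model_config()] (taken from the fit when available).
#' @param standardized set `TRUE` if `ds` is already z-scored.
#' @param chunk samples per forward chunk.
#' @return Tibble `sample_id, subject_id, label, p_hc, p_pd, pred`.
#' @export
fusion_predict <- function(object, ds, config = NULL, standardized = FALSE,
                         chunk = 512) {
  if (inherits(object, "fusion_fit")) {
    params <- object$params
    config <- object$config
    if (!standardized) ds <- zscore_apply(ds, object$stats)
  } else {
    params <- object
    if (is.null(config)) stop("supply `config` with a raw parameter list", call. = FALSE)
  }
  n <- dim(ds$frontal)[3]
  probs <- matrix(0, n, 2)
  for (start in seq(1, n, by = chunk)) {
    idx <- start:min(start + chunk - 1, n)
    out <- .fusion_forward_cpp(
      params, config,
      ds$frontal[, , idx, drop = FALSE], ds$lateral[, , idx, drop = FALSE]
    )
    probs[idx, ] <- out$probs
  }
  tibble::tibble(
    sample_id = ds$info$sample_id, subject_id = ds$info$subject_id,
    label = ds$info$label, p_hc = probs[, 1], p_pd = probs[, 2],
    pred = as.integer(probs[, 2] >= probs[, 1])
  )
}

.eval_metrics <- function(pred_tbl) {
  m <- compute_metrics(confusion_counts(pred_tbl$pred, pred_tbl$label))
  # a validation fold can contain a single class on tiny cohorts
  m$auc <- tryCatch(roc_auc(pred_tbl$p_pd, pred_tbl$label),
    error = function(e) NA_real_
  )
  m
}

# ---------------------------------------------------------------------------
# single-split training

#' Train the fusion network on one train/validation split
#'
#' Minibatch AdamW under the piecewise learning-rate schedule, loss =
#' class-weighted cross-entropy + lambda1 * per-layer MMD + L1/L2
#' penalties. After every epoch the validation fold is scored and the
#' parameters achieving the highest validation F1 are checkpointed
#' (ties keep the earlier epoch). Both datasets must already be
#' standardized with statistics fitted on the training portion
#' ([zscore_fit()] / [zscore_apply()]).
#'
#' @param train_ds,val_ds standardized `step_dataset`s.
#' @param model_cfg [model_config()].
#' @param train_cfg [train_config()].
#' @param weights [loss_weights()].
#' @param seed integer seed for initialization, shuffling and dropout.
#' @param stats the `zscore_stats` used (stored in the checkpoint).
#' @param verbose print per-epoch progress.
#' @return Object of class `fusion_fit`: best `params`, `config`, `stats`,
#'   training `log` tibble, `best_epoch`, `val_metrics` at the best
#'   epoch, `val_predictions`.
#' @export
train_fusion <- function(train_ds, val_ds, model_cfg = model_config(),
                       train_cfg = reduced_train_config(),
                       weights = loss_weights(), seed = 1, stats = NULL,
                       verbose = FALSE) {
  n <- dim(train_ds$frontal)[3]
  labels <- train_ds$info$label
  params <- init_fusion_params(model_cfg, seed = seed)
  opt <- .adamw_init(params)
  best <- list(f1 = -Inf, params = params, epoch = NA_integer_, metrics = NULL)
  log <- vector("list", train_cfg$epochs)
  .with_seed(seed + 1L, {
    for (epoch in seq_len(train_cfg$epochs) - 1L) {
      lr <- learning_rate(epoch, train_cfg)
      ord <- sample.int(n)
      comp <- c(loss_w = 0, ld = 0, l1 = 0, l2 = 0, total = 0)
      nb <- 0L
      for (start in seq(1, n, by = train_cfg$batch_size)) {
        idx <- ord[start:min(start + train_cfg$batch_size - 1, n)]
        if (length(idx) < 2) next
        m_idx <- sample(seq_along(idx), min(train_cfg$mmd_subsample, length(idx)))
        step <- .fusion_train_step_cpp(
          params, model_cfg,
          train_ds$frontal[, , idx, drop = FALSE],
          train_ds$lateral[, , idx, drop = FALSE],
          as.integer(labels[idx]), weights$w1, weights$w2, weights$lambda1,
          as.integer(m_idx - 1L), model_cfg$dropout,
          sample.int(.Machine$integer.max, 1)
        )
        grads <- .add_reg_grads(step$grads, params, weights)
        upd <- .adamw_update(params, grads, opt, lr, train_cfg)
        params <- upd$params
        opt <- upd$state
        l1 <- l1_norm(params)
        l2 <- l2_norm_sq(params)
        tot <- step$loss_w + weights$lambda1 * step$ld +
          weights$lambda2 * l1 + weights$lambda3 * l2
        if (!is.finite(tot)) {
          warning("non-finite loss at epoch ", epoch, "; stopping early")
          break
        }
        comp <- comp + c(step$loss_w, step$ld, l1, l2, tot)
        nb <- nb + 1L
      }
      val_pred <- fusion_predict(params, val_ds, model_cfg, standardized = TRUE)
      vm <- .eval_metrics(val_pred)
      val_f1 <- if (is.na(vm$f1)) 0 else vm$f1
      if (val_f1 > best$f1) {
        best <- list(f1 = val_f1, params = params, epoch = epoch, metrics = vm)
      }
      log[[epoch + 1L]] <- tibble::tibble(
        epoch = epoch, lr = lr,
        loss = comp[["total"]] / max(nb, 1), loss_w = comp[["loss_w"]] / max(nb, 1),
        loss_mmd = comp[["ld"]] / max(nb, 1), l1 = comp[["l1"]] / max(nb, 1),
        l2 = comp[["l2"]] / max(nb, 1),
        val_acc = vm$acc, val_f1 = vm$f1, val_auc = vm$auc
      )
      if (verbose) {
        message(sprintf(
          "epoch %3d lr %.2e loss %.4f val F1 %.1f val acc %.1f",
          epoch, lr, comp[["total"]] / max(nb, 1), vm$f1, vm$acc
        ))
      }
    }
  })
  val_pred <- fusion_predict(best$params, val_ds, model_cfg, standardized = TRUE)
  structure(
    list(
      params = best$params, config = model_cfg, train_config = train_cfg,
      weights = weights, stats = stats, log = dplyr::bind_rows(log),
      best_epoch = best$epoch, val_metrics = best$metrics,
      val_predictions = val_pred, seed = seed
    ),
    class = "fusion_fit"
  )
}

#' @export
print.fusion_fit <- function(x, ...) {
  cat(
    "<fusion_fit> best epoch", x$best_epoch, "| val F1",
    sprintf("%.1f%%", x$val_metrics$f1), "| val acc",
    sprintf("%.1f%%", x$val_metrics$acc), "\n"
  )
  invisible(x)
}

# ---------------------------------------------------------------------------
# grouped cross-validation

#' Subject-grouped k-fold training and evaluation
#'
#' The full evaluation protocol: subjects are partitioned with
#' [grouped_kfold()]; for each fold, z-score statistics are fitted on the
#' training folds only, the network is trained with best-F1
#' checkpointing, and the held-out fold is scored. Per-fold and mean
#' metrics follow the step sample as the evaluation unit; a subject-level
#' majority-vote summary is attached for reference.
#'
#' @param ds a raw (unstandardized) `step_dataset`.
#' @param k number of folds.
#' @param model_cfg,train_cfg,weights see [train_fusion()].
#' @param seed integer seed; fold assignment and every fold's training
#'   derive from it.
#' @param verbose print progress.
#' @return Object of class `fusion_cv`: `folds` (metrics tibble),
#'   `mean` (aggregated row), `fits` (per-fold `fusion_fit`),
#'   `predictions` (pooled out-of-fold), `fold_assignment`,
#'   `subject_metrics`.
#' @export
run_training <- function(ds, k = 5, model_cfg = model_config(),
                         train_cfg = reduced_train_config(),
                         weights = loss_weights(), seed = 1, verbose = FALSE) {
  assignment <- grouped_kfold(ds$info, k = k, seed = seed)
  fold_of <- assignment$fold[match(ds$info$subject_id, assignment$subject_id)]
  fits <- vector("list", k)
  fold_rows <- vector("list", k)
  preds <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- subset_steps(ds, fold_of != f)
    va <- subset_steps(ds, fold_of == f)
    st <- zscore_fit(tr)
    fit <- train_fusion(
      zscore_apply(tr, st), zscore_apply(va, st),
      model_cfg, train_cfg, weights,
      seed = seed + f, stats = st, verbose = verbose
    )
    fits[[f]] <- fit
    m <- fit$val_metrics
    m$fold <- f
    fold_rows[[f]] <- dplyr::relocate(m, "fold")
    pr <- fit$val_predictions
    pr$fold <- f
    preds[[f]] <- pr
    if (verbose) {
      message(sprintf(
        "fold %d: acc %.1f prec %.1f rec %.1f f1 %.1f auc %.3f",
        f, m$acc, m$prec, m$rec, m$f1, m$auc
      ))
    }
  }
  folds <- dplyr::bind_rows(fold_rows)
  predictions <- dplyr::bind_rows(preds)
  subj <- dplyr::summarise(
    dplyr::group_by(predictions, .data$subject_id, .data$label),
    vote = as.integer(mean(.data$pred) >= 0.5), .groups = "drop"
  )
  subject_acc <- 100 * mean(subj$vote == subj$label)
  structure(
    list(
      folds = folds, mean = aggregate_folds(folds), fits = fits,
      predictions = predictions, fold_assignment = assignment,
      subject_metrics = list(majority_vote_acc = subject_acc),
      seed = seed, k = k
    ),
    class = "fusion_cv"
  )
}

#' @export
print.fusion_cv <- function(x, ...) {
  cat("<fusion_cv>", x$k, "subject-grouped folds\n")
  print(as.data.frame(x$folds), row.names = FALSE, digits = 3)
  cat("mean:\n")
  print(as.data.frame(x$mean), row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
tidy.fusion_cv <- function(x, ...) x$folds

#' @export
glance.fusion_cv <- function(x, ...) {
  out <- x$mean
  out$subject_vote_acc <- x$subject_metrics$majority_vote_acc
  out$k <- x$k
  out
}

#' @export
tidy.fusion_fit <- function(x, ...) x$log

#' @export
glance.fusion_fit <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(best_epoch = x$best_epoch),
    x$val_metrics
  )
}

# ---------------------------------------------------------------------------
# checkpointing

#' Save a fitted model checkpoint
#'
#' Single-file archive of the best parameters, architecture
#' configuration and preprocessing statistics (schema version 1).
#'
#' @param fit a `fusion_fit`.
#' @param path destination file.
#' @export
save_checkpoint <- function(fit, path) {
  stopifnot(inherits(fit, "fusion_fit"))
  saveRDS(
    list(
      schema = 1L, params = fit$params, config = fit$config,
      stats = fit$stats, weights = fit$weights, best_epoch = fit$best_epoch,
      val_metrics = fit$val_metrics, seed = fit$seed
    ),
    path
  )
  invisible(path)
}

#' Load a model checkpoint saved with [save_checkpoint()]
#' @param path checkpoint file.
#' @return A `fusion_fit`-like object usable with [fusion_predict()].
#' @export
load_checkpoint <- function(path) {
  x <- readRDS(path)
  if (is.null(x$schema) || x$schema != 1L) {
    stop("unrecognized checkpoint schema", call. = FALSE)
  }
  structure(x, class = "fusion_fit")
}
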