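#' Prior fields and their fixed order
#'
#' The seven physiological priors consumed by the adjustment head, in the
#' frozen order used for the weight matrix rows: sex (+1 male / -1
#' female), age (years), height (cm), weight (kg), BMI (kg/m^2), shoe
#' size (EU), single-step duration (s).
#' @export
prior_fields <- c("sex", "age", "height", "weight", "bmi", "shoe_size", "step_duration")

#' Z-score standardize a priors table
#'
#' Field-wise z-scores using statistics fitted on the training subjects;
#' sex, although already coded +1/-1, is standardized like every other
#' field. Constant fields are flagged and passed through centred.
#'
#' @param priors tibble with the columns of [prior_fields] (plus
#'   `subject_id`, carried through).
#' @param stats optional stats from a previous call (training set);
#'   fitted on `priors` when `NULL`.
#' @return List: `z` (matrix subjects x 7, rownames = subject ids),
#'   `stats` (list `mu`, `sigma`, `constant`).
#' @export
standardize_priors <- function(priors, stats = NULL) {
  missing_cols <- setdiff(prior_fields, names(priors))
  if (length(missing_cols) > 0) {
    stop("priors lack field(s): ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  if (anyNA(priors[prior_fields])) {
    stop("priors contain missing values; the adjustment head requires complete vectors",
      call. = FALSE
    )
  }
  X <- as.matrix(priors[prior_fields])
  if (is.null(stats)) {
    mu <- colMeans(X)
    sigma <- apply(X, 2, sd)
    constant <- sigma == 0
    if (any(constant)) {
      warning(
        "constant prior field(s) passed through centred: ",
        paste(prior_fields[constant], collapse = ", ")
      )
    }
    stats <- list(mu = mu, sigma = ifelse(constant, 1, sigma), constant = constant)
  }
  z <- sweep(sweep(X, 2, stats$mu, "-"), 2, stats$sigma, "/")
  if (!is.null(priors$subject_id)) rownames(z) <- priors$subject_id
  list(z = z, stats = stats)
}

.softmax_rows <- function(A) {
  e <- exp(A - apply(A, 1, max))
  e / rowSums(e)
}

#' Adjust frozen-model outputs with standardized priors
#'
#' The prior adjustment `z %*% W` (bias-free by design, so the weights
#' stay interpretable on the z-scored inputs) is added to the frozen
#' model's softmax output and passed through a final softmax
#' (`mode = "softmax"`, the default, literal double-softmax form). The
#' `"logit"` variant adds the adjustment to log-probabilities instead.
#'
#' @param base_probs matrix `n x 2` of frozen-model class probabilities
#'   (columns HC, PD), or a length-2 vector.
#' @param z standardized priors, matrix `n x 7` (or length-7 vector).
#' @param head a `prior_head` object (or a bare 7 x 2 matrix).
#' @param mode `"softmax"` or `"logit"`.
#' @return Matrix `n x 2` of adjusted probabilities.
#' @export
adjust_with_priors <- function(base_probs, z, head, mode = NULL) {
  if (is.vector(base_probs)) base_probs <- matrix(base_probs, nrow = 1)
  if (is.vector(z)) z <- matrix(z, nrow = 1)
  W <- if (inherits(head, "prior_head")) head$W else head
  if (is.null(mode)) mode <- if (inherits(head, "prior_head")) head$mode else "softmax"
  adj <- z %*% W
  base <- if (mode == "logit") log(pmin(pmax(base_probs, 1e-12), 1)) else base_probs
  .softmax_rows(base + adj)
}

#' Fit the prior-information adjustment head
#'
#' Fine-tunes only the bias-free 7 x 2 linear map on top of a frozen
#' model: the base model's probabilities are computed once and never
#' touched, and the head is optimized with full-batch AdamW on the same
#' loss family as the main network minus the MMD term (no stream
#' features are involved): class-weighted cross-entropy plus L1/L2 on
#' the weight matrix.
#'
#' @param object a `fusion_fit` (with `ds` a `step_dataset`), or a
#'   numeric matrix `n x 2` of precomputed base probabilities.
#' @param ds `step_dataset` scored by the frozen model (when `object` is
#'   a fit).
#' @param priors priors tibble ([read_priors()] layout); matched to
#'   samples by `subject_id` when `ds` is given, otherwise row-aligned
#'   with `object`.
#' @param labels 0/1 labels (taken from `ds` when given).
#' @param prior_stats optional standardization statistics from the
#'   training subjects; fitted on `priors` when `NULL`.
#' @param epochs fine-tuning epochs (default 500).
#' @param lr AdamW learning rate.
#' @param weights [loss_weights()]; `lambda1` is ignored.
#' @param mode adjustment mode stored in the head (see
#'   [adjust_with_priors()]).
#' @return Object of class `prior_head`: `W` (7 x 2, rows in
#'   [prior_fields] order), `stats`, `mode`, `log`.
#' @export
fit_prior_head <- function(object, ds = NULL, priors, labels = NULL,
                           prior_stats = NULL, epochs = 500, lr = 0.01,
                           weights = loss_weights(), mode = "softmax") {
  if (inherits(object, "fusion_fit")) {
    if (is.null(ds)) stop("supply `ds` together with a fitted model", call. = FALSE)
    pred <- fusion_predict(object, ds)
    base <- as.matrix(pred[, c("p_hc", "p_pd")])
    labels <- pred$label
    pri <- priors[match(pred$subject_id, priors$subject_id), , drop = FALSE]
    if (anyNA(pri$subject_id)) {
      stop("priors missing for some training subjects", call. = FALSE)
    }
  } else {
    base <- as.matrix(object)
    pri <- priors
    if (is.null(labels)) stop("supply `labels` with precomputed probabilities", call. = FALSE)
  }
  stopifnot(ncol(base) == 2, nrow(base) == length(labels))
  sp <- standardize_priors(pri, prior_stats)
  Z <- sp$z
  n <- nrow(Z)
  W <- matrix(0, length(prior_fields), 2,
    dimnames = list(prior_fields, c("HC", "PD"))
  )
  cfg <- train_config(
    epochs = epochs, batch_size = n, lr_start = lr, lr_peak = lr,
    lr_end = lr, warmup_end = 0, constant_end = epochs
  )
  state <- .adamw_init(list(W = W))
  base_in <- if (mode == "logit") log(pmin(pmax(base, 1e-12), 1)) else base
  wvec <- ifelse(labels == 1, weights$w1, weights$w2)
  onehot <- cbind(1 - labels, labels)
  log_rows <- vector("list", epochs)
  for (e in seq_len(epochs)) {
    P <- .softmax_rows(base_in + Z %*% W)
    dA <- (P - onehot) * wvec / n
    dW <- crossprod(Z, dA) + weights$lambda2 * sign(W) + 2 * weights$lambda3 * W
    upd <- .adamw_update(list(W = W), list(W = dW), state, lr, cfg)
    W <- upd$params$W
    state <- upd$state
    log_rows[[e]] <- tibble::tibble(
      epoch = e,
      loss = weighted_cross_entropy(P, labels, weights$w1, weights$w2)
    )
  }
  structure(
    list(W = W, stats = sp$stats, mode = mode, log = dplyr::bind_rows(log_rows)),
    class = "prior_head"
  )
}

#' @export
print.prior_head <- function(x, ...) {
  cat("<prior_head> bias-free 7 x 2 adjustment (", x$mode, " mode)\n", sep = "")
  print(round(x$W, 4))
  invisible(x)
}

#' @export
tidy.prior_head <- function(x, ...) {
  tibble::tibble(
    prior = rownames(x$W),
    weight_hc = x$W[, 1],
    weight_pd = x$W[, 2],
    # signed influence toward the PD class, the quantity plotted/reported
    pd_influence = x$W[, 2] - x$W[, 1]
  )
}
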