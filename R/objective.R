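#' Loss weights of the composite training objective
#'
#' Defaults are the tuned operating point: class weights slightly
#' compensating the ~0.72:0.28 HC:PD imbalance (w1 = 0.9 on the PD term,
#' w2 = 1.1 on the HC term), MMD regularization weight 0.01, L1 weight
#' 1e-4 and L2 weight 1e-3.
#'
#' @param w1 weight of the positive-class (PD) log-likelihood term.
#' @param w2 weight of the negative-class (HC) term.
#' @param lambda1 weight of the MMD distribution-alignment term.
#' @param lambda2 weight of the L1 penalty on weight matrices.
#' @param lambda3 weight of the squared-L2 penalty on weight matrices.
#' @export
loss_weights <- function(w1 = 0.9, w2 = 1.1, lambda1 = 0.01,
                         lambda2 = 1e-4, lambda3 = 1e-3) {
  vals <- c(w1, w2, lambda1, lambda2, lambda3)
  if (any(vals < 0)) stop("loss weights must be non-negative", call. = FALSE)
  structure(
    list(w1 = w1, w2 = w2, lambda1 = lambda1, lambda2 = lambda2, lambda3 = lambda3),
    class = "loss_weights"
  )
}

.as_feature_matrix <- function(x) {
  if (is.matrix(x)) {
    return(x)
  }
  if (is.array(x) && length(dim(x)) == 3) {
    # (T, d, B) array -> B x (T*d), one flattened sample per row
    return(t(apply(x, 3, as.vector)))
  }
  stop("features must be a matrix (samples x features) or a T x d x B array",
    call. = FALSE
  )
}

#' Median-heuristic Gaussian kernel bandwidth
#'
#' \eqn{\gamma = 1 / \mathrm{median}\{\lVert z_i - z_j\rVert_2\}^2} over
#' all pairs (i < j) of the pooled sample set \eqn{Z = [X; Y]}. When all
#' points coincide (median distance 0) the bandwidth falls back to 1 with
#' a warning.
#'
#' @param X,Y numeric matrices, one sample per row, equal column count.
#' @return Scalar bandwidth `gamma`.
#' @export
kernel_bandwidth <- function(X, Y) {
  X <- .as_feature_matrix(X)
  Y <- .as_feature_matrix(Y)
  Z <- rbind(X, Y)
  if (nrow(Z) < 2) stop("need at least two pooled samples", call. = FALSE)
  d <- as.numeric(stats::dist(Z))
  med <- median(d)
  if (med == 0) {
    warning("all pooled points identical; falling back to gamma = 1")
    return(1)
  }
  1 / med^2
}

#' Unbiased squared maximum mean discrepancy
#'
#' Gaussian-kernel MMD\eqn{^2} between two sample sets with the unbiased
#' estimator: within-set sums over ordered pairs i != j, full cross term,
#' \deqn{D^2 = \frac{1}{n(n-1)}\sum_{i\neq j}K(x_i,x_j)
#'   + \frac{1}{m(m-1)}\sum_{k\neq l}K(y_k,y_l)
#'   - \frac{2}{nm}\sum_{i,k}K(x_i,y_k),}
#' with \eqn{K(x,y)=\exp(-\gamma\lVert x-y\rVert^2)}. The unbiased value
#' can be slightly negative and is reported raw.
#'
#' @param X,Y numeric matrices, one sample per row; both need >= 2 rows.
#' @param gamma kernel bandwidth; defaults to [kernel_bandwidth()] of the
#'   pooled set.
#' @return Scalar (possibly slightly negative) squared MMD.
#' @export
mmd_squared <- function(X, Y, gamma = kernel_bandwidth(X, Y)) {
  X <- .as_feature_matrix(X)
  Y <- .as_feature_matrix(Y)
  n <- nrow(X)
  m <- nrow(Y)
  if (n < 2 || m < 2) {
    stop("unbiased MMD needs at least 2 samples per set", call. = FALSE)
  }
  sq_dist <- function(A, B) {
    an <- rowSums(A^2)
    bn <- rowSums(B^2)
    pmax(outer(an, bn, "+") - 2 * tcrossprod(A, B), 0)
  }
  Kxx <- exp(-gamma * sq_dist(X, X))
  Kyy <- exp(-gamma * sq_dist(Y, Y))
  Kxy <- exp(-gamma * sq_dist(X, Y))
  (sum(Kxx) - n) / (n * (n - 1)) + (sum(Kyy) - m) / (m * (m - 1)) -
    2 * mean(Kxy)
}

#' Per-layer MMD alignment loss
#'
#' For each layer, the squared MMD between the frontal and lateral
#' streams' features is computed with a layer-specific median-heuristic
#' bandwidth and clamped at zero (the unbiased estimator may dip below);
#' the loss is the mean over layers.
#'
#' @param feats_frontal,feats_lateral lists (one element per layer) of
#'   feature matrices (samples x features) or `T x d x B` arrays.
#' @return List with `ld` (mean over layers) and `per_layer_D`.
#' @export
mmd_layer_loss <- function(feats_frontal, feats_lateral) {
  stopifnot(length(feats_frontal) == length(feats_lateral))
  per_layer <- purrr::map2_dbl(feats_frontal, feats_lateral, function(fx, fy) {
    max(mmd_squared(fx, fy), 0)
  })
  list(ld = mean(per_layer), per_layer_D = per_layer)
}

#' Class-weighted cross-entropy
#'
#' Mean-reduced negative weighted log-likelihood for the binary PD/HC
#' problem: the PD term (y = 1) is weighted by `w1`, the HC term (y = 0)
#' by `w2`. Probabilities are clamped to `[1e-7, 1 - 1e-7]`.
#'
#' @param probs matrix `n x 2` (columns HC, PD) or vector of PD-class
#'   probabilities.
#' @param labels 0/1 vector, 1 = PD.
#' @param w1,w2 class weights.
#' @return Scalar loss.
#' @export
weighted_cross_entropy <- function(probs, labels, w1 = 0.9, w2 = 1.1) {
  p_pd <- if (is.matrix(probs)) probs[, 2] else probs
  stopifnot(length(p_pd) == length(labels))
  eps <- 1e-7
  p_pd <- pmin(pmax(p_pd, eps), 1 - eps)
  -mean(w1 * labels * log(p_pd) + w2 * (1 - labels) * log(1 - p_pd))
}

# weight matrices only: biases, norm gains, per-channel scales and scalars
# are stored as plain vectors in the parameter list and are excluded from
# the penalties
.weight_matrices <- function(params) {
  params[vapply(params, is.matrix, logical(1))]
}

#' L1 norm of the model's weight matrices
#' @param params named parameter list (see [init_fusion_params()]).
#' @export
l1_norm <- function(params) sum(vapply(.weight_matrices(params), function(w) sum(abs(w)), numeric(1)))

#' Squared L2 norm of the model's weight matrices
#' @param params named parameter list.
#' @export
l2_norm_sq <- function(params) sum(vapply(.weight_matrices(params), function(w) sum(w^2), numeric(1)))

#' Assemble the composite loss
#'
#' \deqn{L = L_w + \lambda_1 L_d + \lambda_2 \lVert W\rVert_1
#'   + \lambda_3 \lVert W\rVert_2^2}
#' with \eqn{L_w} the class-weighted cross-entropy, \eqn{L_d} the mean
#' per-layer clamped squared MMD, and the penalties taken over all weight
#' matrices.
#'
#' @param probs,labels as in [weighted_cross_entropy()].
#' @param feats_frontal,feats_lateral as in [mmd_layer_loss()]; may be
#'   `NULL` when `lambda1 = 0`.
#' @param params named parameter list.
#' @param weights a [loss_weights()] object.
#' @return An object of class `loss_breakdown`: `L_w`, `L_d`, `l1`, `l2`,
#'   `per_layer_D`, `total`.
#' @export
total_loss <- function(probs, labels, feats_frontal = NULL, feats_lateral = NULL,
                       params, weights = loss_weights()) {
  L_w <- weighted_cross_entropy(probs, labels, weights$w1, weights$w2)
  if (!is.null(feats_frontal)) {
    md <- mmd_layer_loss(feats_frontal, feats_lateral)
  } else {
    md <- list(ld = 0, per_layer_D = numeric(0))
  }
  l1 <- l1_norm(params)
  l2 <- l2_norm_sq(params)
  total <- L_w + weights$lambda1 * md$ld + weights$lambda2 * l1 + weights$lambda3 * l2
  comps <- c(L_w = L_w, L_d = md$ld, l1 = l1, l2 = l2, total = total)
  bad <- names(comps)[!is.finite(comps)]
  if (length(bad) > 0) {
    stop("non-finite loss component: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(
    list(
      L_w = L_w, L_d = md$ld, l1 = l1, l2 = l2,
      per_layer_D = md$per_layer_D, total = total
    ),
    class = "loss_breakdown"
  )
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat(sprintf(
    "<loss_breakdown> total %.5f = L_w %.5f + MMD %.5f + L1 %.5f + L2 %.5f\n",
    x$total, x$L_w, x$L_d, x$l1, x$l2
  ))
  invisible(x)
}
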