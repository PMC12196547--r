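#' Model configuration
#'
#' Architecture hyperparameters of the dual-stream fusion network. The
#' defaults are the tuned operating point: 50-frame steps embedded at
#' dimension 39 (13 joints x 3 channels), 3 attention heads, feed-forward
#' width 64, four layers alternating self-attention (layers 1, 3) and
#' state-space blocks (layers 2, 4), state dimension 32, pointwise
#' depthwise convolution, expansion factor 1, and chunk size 10 for the
#' chunked state-space evaluation.
#'
#' @param seq_len frames per step sample.
#' @param embed_dim feature dimension `d`; must be divisible by `heads`.
#' @param heads attention heads.
#' @param ffn_dim feed-forward hidden width.
#' @param dropout dropout probability used during training.
#' @param depth number of layers; must be even (self-attention and
#'   state-space blocks alternate).
#' @param state_dim state dimension `N` of the state-space blocks.
#' @param conv_kernel depthwise convolution kernel size (1 = pointwise).
#' @param expansion inner expansion factor of the state-space block.
#' @param chunk_size chunk length of the chunked state-space evaluation.
#' @export
model_config <- function(seq_len = 50, embed_dim = 39, heads = 3, ffn_dim = 64,
                         dropout = 0.2, depth = 4, state_dim = 32,
                         conv_kernel = 1, expansion = 1, chunk_size = 10) {
  if (embed_dim %% heads != 0) {
    stop("`embed_dim` must be divisible by `heads`", call. = FALSE)
  }
  if (depth %% 2 != 0) stop("`depth` must be even", call. = FALSE)
  if (conv_kernel != 1 || expansion != 1) {
    stop("only conv_kernel = 1 and expansion = 1 are supported", call. = FALSE)
  }
  structure(
    list(
      seq_len = as.integer(seq_len), embed_dim = as.integer(embed_dim),
      heads = as.integer(heads), ffn_dim = as.integer(ffn_dim),
      dropout = dropout, depth = as.integer(depth),
      state_dim = as.integer(state_dim), conv_kernel = 1L, expansion = 1L,
      chunk_size = as.integer(chunk_size)
    ),
    class = "model_config"
  )
}

.xavier <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(runif(nin * nout, -lim, lim), nin, nout)
}

.attn_param_names <- c(
  "Wq", "bq", "Wk", "bk", "Wv", "bv", "Wo", "bo",
  "ln1g", "ln1b", "Wf1", "bf1", "Wf2", "bf2", "ln2g", "ln2b"
)

.init_attn_block <- function(d, ffn) {
  list(
    Wq = .xavier(d, d), bq = numeric(d),
    Wk = .xavier(d, d), bk = numeric(d),
    Wv = .xavier(d, d), bv = numeric(d),
    Wo = .xavier(d, d), bo = numeric(d),
    ln1g = rep(1, d), ln1b = numeric(d),
    Wf1 = .xavier(d, ffn), bf1 = numeric(ffn),
    Wf2 = .xavier(ffn, d), bf2 = numeric(d),
    ln2g = rep(1, d), ln2b = numeric(d)
  )
}

.init_mamba_block <- function(d, N) {
  list(
    Win = .xavier(d, 2 * d), bin = numeric(2 * d),
    wcv = rep(1, d), bcv = numeric(d),
    Wd = .xavier(d, 1), bd = 0,
    abase = 0.5413249, # softplus(abase) ~= 1
    WB = .xavier(d, N), bB = numeric(N),
    WC = .xavier(d, N), bC = numeric(N),
    Wout = .xavier(d, d), bout = numeric(d)
  )
}

#' Initialize network parameters
#'
#' Xavier-uniform weight matrices, zero biases, unit layer-norm gains.
#' Parameters are stored in a flat named list keyed
#' `<stream>.<layer>.<block>.<tensor>` (streams `f`/`l`; blocks `attn`
#' at odd layers, `mamba` at even layers, `cross` at every layer) plus
#' the classifier `cls.W` / `cls.b`.
#'
#' @param config a [model_config()].
#' @param seed integer RNG seed.
#' @return Named list of numeric matrices/vectors.
#' @export
init_fusion_params <- function(config, seed = 1) {
  d <- config$embed_dim
  .with_seed(seed, {
    params <- list()
    for (s in c("f", "l")) {
      for (layer in seq_len(config$depth)) {
        blocks <- list()
        if (layer %% 2 == 1) {
          blocks$attn <- .init_attn_block(d, config$ffn_dim)
        } else {
          blocks$mamba <- .init_mamba_block(d, config$state_dim)
        }
        blocks$cross <- .init_attn_block(d, config$ffn_dim)
        for (bn in names(blocks)) {
          for (tn in names(blocks[[bn]])) {
            params[[paste(s, layer, bn, tn, sep = ".")]] <- blocks[[bn]][[tn]]
          }
        }
      }
    }
    params[["cls.W"]] <- .xavier(2 * d, 2)
    params[["cls.b"]] <- numeric(2)
    params
  })
}

.block_params <- function(params, stream, layer, block) {
  prefix <- paste(stream, layer, block, "", sep = ".")
  keys <- names(params)[startsWith(names(params), prefix)]
  out <- params[keys]
  names(out) <- sub(prefix, "", names(out), fixed = TRUE)
  out
}

.silu <- function(x) x / (1 + exp(-x))

.layernorm <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc^2)
  xhat <- xc / sqrt(v + eps)
  sweep(xhat, 2, g, "*") + matrix(b, nrow(X), length(b), byrow = TRUE)
}

.addb <- function(X, b) X + matrix(b, nrow(X), length(b), byrow = TRUE)

#' Multi-head scaled dot-product attention
#'
#' The attention core: `softmax(Q K' / sqrt(d_k)) V` per head, heads
#' concatenated and passed through the output projection. Self-attention
#' uses `x_kv = x_q`; cross-attention takes queries from one stream and
#' keys/values from the other.
#'
#' @param x_q query sequence, `T x d` matrix.
#' @param x_kv key/value sequence, `T x d` matrix (defaults to `x_q`).
#' @param weights list with `Wq, bq, Wk, bk, Wv, bv, Wo, bo`.
#' @param heads number of heads; `d` must be divisible by it.
#' @return `T x d` attended sequence.
#' @export
multihead_attention <- function(x_q, x_kv = x_q, weights, heads = 1) {
  d <- ncol(x_q)
  if (d %% heads != 0) stop("embed dim not divisible by heads", call. = FALSE)
  if (ncol(x_kv) != d) stop("query/key embed dims differ", call. = FALSE)
  dh <- d %/% heads
  Q <- .addb(x_q %*% weights$Wq, weights$bq)
  K <- .addb(x_kv %*% weights$Wk, weights$bk)
  V <- .addb(x_kv %*% weights$Wv, weights$bv)
  O <- matrix(0, nrow(x_q), d)
  for (h in seq_len(heads)) {
    cols <- ((h - 1) * dh + 1):(h * dh)
    S <- tcrossprod(Q[, cols, drop = FALSE], K[, cols, drop = FALSE]) / sqrt(dh)
    S <- S - apply(S, 1, max)
    P <- exp(S) / rowSums(exp(S))
    O[, cols] <- P %*% V[, cols, drop = FALSE]
  }
  .addb(O %*% weights$Wo, weights$bo)
}

#' Attention block (attention + feed-forward + layer norm)
#'
#' The full transformer-style block: multi-head attention with a residual
#' connection and layer normalization, followed by a SiLU feed-forward
#' network with a second residual and layer normalization (post-norm).
#'
#' @inheritParams multihead_attention
#' @param weights full block parameter list (attention projections,
#'   layer-norm gains/offsets, feed-forward weights).
#' @return `T x d` matrix.
#' @export
attention_block <- function(x_q, x_kv = x_q, weights, heads = 1) {
  A <- multihead_attention(x_q, x_kv, weights, heads)
  U <- .layernorm(x_q + A, weights$ln1g, weights$ln1b)
  F_ <- .addb(.silu(.addb(U %*% weights$Wf1, weights$bf1)) %*% weights$Wf2, weights$bf2)
  .layernorm(U + F_, weights$ln2g, weights$ln2b)
}

#' State-space (Mamba-2 style) block
#'
#' Input projection to a value and a gate path, pointwise depthwise
#' convolution, SiLU nonlinearity, data-dependent generation of the
#' per-timestep state-space quantities (scalar decay
#' `a_t = exp(-softplus-rate * Delta_t)` with `Delta_t = softplus` of a
#' linear map, and linear maps for `B_t`, `C_t`), chunked state-space
#' mixing ([ssd_forward()]), SiLU-gated output projection and a residual
#' connection.
#'
#' @param x `T x d` input sequence.
#' @param weights block parameter list (see [init_fusion_params()]).
#' @param chunk_size chunk length for [ssd_forward()].
#' @return `T x d` matrix.
#' @export
mamba2_block <- function(x, weights, chunk_size = 10) {
  d <- ncol(x)
  P0 <- .addb(x %*% weights$Win, weights$bin)
  u <- P0[, seq_len(d), drop = FALSE]
  z <- P0[, d + seq_len(d), drop = FALSE]
  uc <- sweep(u, 2, weights$wcv, "*")
  uc <- .addb(uc, weights$bcv)
  u <- .silu(uc)
  delta <- log1p(exp(as.numeric(u %*% weights$Wd) + weights$bd))
  abar <- log1p(exp(weights$abase))
  a <- exp(-delta * abar)
  Bm <- .addb(u %*% weights$WB, weights$bB)
  Cm <- .addb(u %*% weights$WC, weights$bC)
  yss <- ssd_forward(u, a, Bm, Cm, chunk = chunk_size)
  o <- yss * .silu(z)
  x + .addb(o %*% weights$Wout, weights$bout)
}

#' Forward pass of the dual-stream fusion network (reference path)
#'
#' Processes the frontal and lateral step matrices through two
#' weight-independent streams of alternating self-attention and
#' state-space blocks. After each layer's temporal block the streams
#' exchange information through bidirectional cross-attention: both
#' directions are computed from the pre-exchange features and added
#' residually, so the exchange is symmetric. The final features are
#' mean-pooled over time, concatenated, and classified by a linear +
#' softmax head. Per-layer post-exchange features of both streams are
#' returned for the distribution-alignment (MMD) regularizer.
#'
#' This is the plain-R reference implementation (no dropout); training
#' uses a compiled batched path ([fusion_predict()]) that is tested to
#' agree with it.
#'
#' @param frontal,lateral `seq_len x embed_dim` matrices of one
#'   normalized step.
#' @param params named parameter list from [init_fusion_params()].
#' @param config the matching [model_config()].
#' @return List with `probs` (length-2: HC, PD), `feats_frontal` and
#'   `feats_lateral` (lists of `depth` per-layer feature matrices).
#' @export
fusion_forward <- function(frontal, lateral, params, config = model_config()) {
  d <- config$embed_dim
  if (!all(dim(frontal) == c(config$seq_len, d)) ||
    !all(dim(lateral) == c(config$seq_len, d))) {
    stop("inputs must be seq_len x embed_dim matrices", call. = FALSE)
  }
  hf <- frontal
  hl <- lateral
  feats_f <- feats_l <- vector("list", config$depth)
  for (layer in seq_len(config$depth)) {
    if (layer %% 2 == 1) {
      tf <- attention_block(hf, hf, .block_params(params, "f", layer, "attn"), config$heads)
      tl <- attention_block(hl, hl, .block_params(params, "l", layer, "attn"), config$heads)
    } else {
      tf <- mamba2_block(hf, .block_params(params, "f", layer, "mamba"), config$chunk_size)
      tl <- mamba2_block(hl, .block_params(params, "l", layer, "mamba"), config$chunk_size)
    }
    cf <- attention_block(tf, tl, .block_params(params, "f", layer, "cross"), config$heads)
    cl <- attention_block(tl, tf, .block_params(params, "l", layer, "cross"), config$heads)
    hf <- tf + cf
    hl <- tl + cl
    feats_f[[layer]] <- hf
    feats_l[[layer]] <- hl
  }
  pooled <- c(colMeans(hf), colMeans(hl))
  logits <- as.numeric(pooled %*% params[["cls.W"]]) + params[["cls.b"]]
  e <- exp(logits - max(logits))
  list(probs = e / sum(e), feats_frontal = feats_f, feats_lateral = feats_l)
}
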