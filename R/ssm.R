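#' State-space model recursion (sequential scan)
#'
#' The selective state-space recurrence with scalar per-timestep
#' transition: \eqn{h_t = a_t h_{t-1} + B_t x_t^\top} (with \eqn{h_{-1}=0})
#' and \eqn{y_t = C_t^\top h_t}. The scalar-times-identity transition is
#' what makes the semiseparable-matrix formulation ([ssm_materialize()])
#' and its chunked evaluation ([ssd_forward()]) exact; all input channels
#' share the same sequence mixing.
#'
#' @param x input sequence, `T x d` matrix (or vector, treated as `T x 1`).
#' @param A numeric vector of length `T`, per-timestep scalar transitions.
#' @param B,C `T x N` matrices of per-timestep input/output maps.
#' @return `T x d` output sequence.
#' @export
ssm_scan <- function(x, A, B, C) {
  if (is.vector(x)) x <- matrix(x, ncol = 1)
  T_ <- nrow(x)
  stopifnot(length(A) == T_, nrow(B) == T_, nrow(C) == T_, ncol(B) == ncol(C))
  N <- ncol(B)
  h <- matrix(0, N, ncol(x))
  y <- matrix(0, T_, ncol(x))
  for (t in seq_len(T_)) {
    h <- A[t] * h + tcrossprod(B[t, ], x[t, ])
    y[t, ] <- as.numeric(crossprod(h, C[t, ]))
  }
  y
}

#' Materialize the semiseparable sequence-mixing matrix
#'
#' Dense `T x T` lower-triangular matrix \eqn{M} with
#' \eqn{M_{ji} = C_j^\top \big(\prod_{k=i+1}^{j} a_k\big) B_i} (empty
#' product = 1), so that the scan output equals \eqn{M x}. This is the
#' quadratic-cost oracle used to validate the scan and the chunked SSD
#' path; it refuses long sequences.
#'
#' @param A,B,C as in [ssm_scan()].
#' @param len sequence length; must match `A` and be at most 256.
#' @return `len x len` lower-triangular matrix.
#' @export
ssm_materialize <- function(A, B, C, len = length(A)) {
  stopifnot(len == length(A), nrow(B) == len, nrow(C) == len)
  if (len > 256) {
    stop("ssm_materialize is a quadratic-cost oracle; refusing length > 256",
      call. = FALSE
    )
  }
  G <- tcrossprod(C, B) # G[j, i] = C_j . B_i
  M <- matrix(0, len, len)
  for (j in seq_len(len)) {
    acc <- 1
    M[j, j] <- G[j, j]
    if (j > 1) {
      for (i in seq(j - 1, 1)) {
        acc <- acc * A[i + 1]
        M[j, i] <- G[j, i] * acc
      }
    }
  }
  M
}

#' Chunked (SSD) evaluation of the state-space map
#'
#' Computes the same map as [ssm_scan()] by partitioning the sequence into
#' chunks of size `chunk`: within each chunk the dense semiseparable block
#' is applied directly, while information crossing chunk boundaries is
#' passed through the low-rank state (size `N`), never materializing the
#' full `T x T` matrix. `chunk = 1` degenerates to the recursion;
#' `chunk >= T` degenerates to the dense matrix path.
#'
#' @param x input sequence, `T x d` matrix (or vector).
#' @param A,B,C as in [ssm_scan()].
#' @param chunk chunk length, a positive integer.
#' @return `T x d` output sequence, equal to the scan up to float error.
#' @export
ssd_forward <- function(x, A, B, C, chunk = 10) {
  if (is.vector(x)) x <- matrix(x, ncol = 1)
  T_ <- nrow(x)
  stopifnot(chunk >= 1, length(A) == T_)
  N <- ncol(B)
  d <- ncol(x)
  y <- matrix(0, T_, d)
  h <- matrix(0, N, d) # carried state = h_{chunk end}
  cs <- 1L
  while (cs <= T_) {
    ce <- min(cs + chunk - 1L, T_)
    idx <- cs:ce
    q <- length(idx)
    a_loc <- A[idx]
    B_loc <- B[idx, , drop = FALSE]
    C_loc <- C[idx, , drop = FALSE]
    x_loc <- x[idx, , drop = FALSE]
    # within-chunk dense block
    y_loc <- ssm_materialize(a_loc, B_loc, C_loc, q) %*% x_loc
    # cross-chunk: prior state enters timestep t with weight prod(a[cs..t])
    pc <- cumprod(a_loc)
    y_loc <- y_loc + (pc * C_loc) %*% h
    # update carried state: h_ce = prod(a_loc) * h + sum_t prod(a[t+1..ce]) B_t x_t
    rc <- rev(cumprod(c(1, rev(a_loc))[seq_len(q)])) # rc[t] = prod a[(t+1)..ce]
    h <- pc[q] * h + crossprod(rc * B_loc, x_loc)
    y[idx, ] <- y_loc
    cs <- ce + 1L
  }
  y
}
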