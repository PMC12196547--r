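test_that("the median-heuristic bandwidth matches an explicit pair enumeration", {
  # two points at distance 2: the single pairwise distance is the median
  X <- matrix(c(0, 0), 1)
  Y <- matrix(c(2, 0), 1)
  expect_equal(kernel_bandwidth(X, Y), 1 / 4)
  # homogeneity: scaling all points by c scales gamma by 1/c^2
  set.seed(2)
  Z1 <- matrix(rnorm(12), 4)
  Z2 <- matrix(rnorm(12), 4)
  expect_equal(kernel_bandwidth(3 * Z1, 3 * Z2), kernel_bandwidth(Z1, Z2) / 9,
    tolerance = 1e-12
  )
  # brute-force median over all pooled pairs
  set.seed(3)
  X <- matrix(rnorm(5 * 3), 5)
  Y <- matrix(rnorm(5 * 3), 5)
  Z <- rbind(X, Y)
  dists <- c()
  for (i in 1:9) {
    for (j in (i + 1):10) dists <- c(dists, sqrt(sum((Z[i, ] - Z[j, ])^2)))
  }
  expect_equal(kernel_bandwidth(X, Y), 1 / median(dists)^2, tolerance = 1e-12)
  # identical points fall back with a warning
  P <- matrix(1, 3, 2)
  expect_warning(g <- kernel_bandwidth(P, P), "identical")
  expect_equal(g, 1)
})

test_that("unbiased MMD matches the double-loop oracle and its limits", {
  # all four points identical: within 1 + within 1 - cross 2 = 0
  P <- matrix(c(1, 2), 1)
  expect_equal(mmd_squared(rbind(P, P), rbind(P, P), gamma = 1), 0, tolerance = 1e-12)
  # two far-separated tight clusters: within-kernels -> 1, cross -> 0, D2 -> 2
  set.seed(4)
  X <- matrix(rnorm(10 * 2, sd = 1e-4), 10)
  Y <- matrix(rnorm(10 * 2, sd = 1e-4) + 100, 10)
  expect_equal(mmd_squared(X, Y, gamma = 1), 2, tolerance = 1e-4)
  # O(n^2) double-loop oracle on random sets
  for (seed in 1:4) {
    set.seed(seed)
    n <- sample(3:8, 1)
    m <- sample(3:8, 1)
    X <- matrix(rnorm(n * 4), n)
    Y <- matrix(rnorm(m * 4), m)
    gam <- kernel_bandwidth(X, Y)
    K <- function(a, b) exp(-gam * sum((a - b)^2))
    sxx <- 0
    for (i in 1:n) for (j in 1:n) if (i != j) sxx <- sxx + K(X[i, ], X[j, ])
    syy <- 0
    for (k in 1:m) for (l in 1:m) if (k != l) syy <- syy + K(Y[k, ], Y[l, ])
    sxy <- 0
    for (i in 1:n) for (k in 1:m) sxy <- sxy + K(X[i, ], Y[k, ])
    oracle <- sxx / (n * (n - 1)) + syy / (m * (m - 1)) - 2 * sxy / (n * m)
    expect_equal(mmd_squared(X, Y, gam), oracle, tolerance = 1e-10)
  }
  expect_error(mmd_squared(matrix(1, 1, 2), matrix(1, 3, 2)), "at least 2")
})

test_that("MMD is symmetric and permutation-invariant", {
  set.seed(6)
  X <- matrix(rnorm(8 * 3), 8)
  Y <- matrix(rnorm(8 * 3), 8)
  expect_equal(mmd_squared(X, Y), mmd_squared(Y, X), tolerance = 1e-12)
  expect_equal(mmd_squared(X[sample(8), ], Y), mmd_squared(X, Y), tolerance = 1e-12)
})

test_that("the layer loss averages clamped per-layer discrepancies", {
  set.seed(7)
  F1 <- matrix(rnorm(12 * 5), 12)
  # identical streams at every layer: zero
  res <- mmd_layer_loss(list(F1, F1), list(F1, F1))
  expect_equal(res$ld, 0, tolerance = 1e-9)
  expect_true(all(res$per_layer_D >= 0))
  # a single layer is its own mean
  F2 <- matrix(rnorm(12 * 5), 12)
  one <- mmd_layer_loss(list(F1), list(F2))
  expect_equal(one$ld, one$per_layer_D[1])
  # four layers: the loss is the arithmetic mean of the per-layer values
  Fs <- replicate(4, matrix(rnorm(12 * 5), 12), simplify = FALSE)
  Gs <- replicate(4, matrix(rnorm(12 * 5, mean = 0.5), 12), simplify = FALSE)
  four <- mmd_layer_loss(Fs, Gs)
  expect_length(four$per_layer_D, 4)
  expect_equal(four$ld, mean(four$per_layer_D), tolerance = 1e-12)
})

test_that("weighted cross-entropy reduces to the stated hand values", {
  # perfect confident predictions: loss ~ 0
  expect_lt(weighted_cross_entropy(c(1e-9, 1 - 1e-9), c(0, 1)), 1e-6)
  # w1 = w2 = 1 is the plain cross-entropy
  set.seed(8)
  p <- runif(20, 0.05, 0.95)
  y <- rbinom(20, 1, 0.5)
  expect_equal(
    weighted_cross_entropy(p, y, 1, 1),
    -mean(y * log(p) + (1 - y) * log(1 - p)),
    tolerance = 1e-12
  )
  # single sample, y = 1, p = 0.5, w1 = 0.9 -> 0.9 * (-log 0.5)
  expect_equal(weighted_cross_entropy(0.5, 1, w1 = 0.9), 0.9 * (-log(0.5)),
    tolerance = 1e-12
  )
  # clamping keeps the loss finite at p in {0, 1}
  expect_true(is.finite(weighted_cross_entropy(c(0, 1), c(1, 0))))
})

test_that("the composite loss assembles its terms as declared", {
  cfg <- tiny_config()
  p <- init_fusion_params(cfg, seed = 9)
  set.seed(10)
  probs <- cbind(runif(6, 0.2, 0.8))
  probs <- cbind(1 - probs, probs)
  y <- rbinom(6, 1, 0.4)
  F1 <- matrix(rnorm(6 * 4), 6)
  F2 <- matrix(rnorm(6 * 4), 6)
  lw0 <- total_loss(probs, y,
    params = p,
    weights = loss_weights(lambda1 = 0, lambda2 = 0, lambda3 = 0)
  )
  expect_equal(lw0$total, lw0$L_w)
  full <- total_loss(probs, y, list(F1), list(F2),
    params = p,
    weights = loss_weights()
  )
  expect_equal(
    full$total,
    full$L_w + 0.01 * full$L_d + 1e-4 * full$l1 + 1e-3 * full$l2,
    tolerance = 1e-12
  )
  # all-zero weight matrices zero the penalties
  p0 <- lapply(p, function(x) x * 0)
  z <- total_loss(probs, y, params = p0, weights = loss_weights())
  expect_equal(z$l1, 0)
  expect_equal(z$l2, 0)
  # the loss is monotone non-decreasing in each lambda
  for (lam in c("lambda1", "lambda2", "lambda3")) {
    args_lo <- loss_weights()
    args_hi <- loss_weights()
    args_hi[[lam]] <- args_hi[[lam]] * 10
    lo <- total_loss(probs, y, list(F1), list(F2), params = p, weights = args_lo)
    hi <- total_loss(probs, y, list(F1), list(F2), params = p, weights = args_hi)
    expect_gte(hi$total, lo$total)
  }
})

test_that("the MMD term pulls on features when distributions differ", {
  # finite-difference gradient of lambda1 * L_d w.r.t. one feature entry
  set.seed(11)
  F1 <- matrix(rnorm(8 * 4), 8)
  F2 <- matrix(rnorm(8 * 4, mean = 2), 8)
  gam <- kernel_bandwidth(F1, F2)
  f <- function(z) {
    F1b <- F1
    F1b[1, 1] <- z
    0.01 * max(mmd_squared(F1b, F2, gam), 0)
  }
  eps <- 1e-5
  grad <- (f(F1[1, 1] + eps) - f(F1[1, 1] - eps)) / (2 * eps)
  expect_gt(abs(grad), 0)
})
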