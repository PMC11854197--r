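test_that("information gain has its closed-form anchor values", {
  # feature identical to the label on balanced classes: exactly 1 bit
  y <- rep(c(0, 1), each = 10)
  expect_equal(information_gain(y, y), 1.0)
  # constant feature carries nothing
  expect_equal(information_gain(rep(3.3, 20), y), 0)
  # two bins with label counts (3,1) and (1,3):
  # H(0.5) - 0.5 H(0.75) - 0.5 H(0.25) = 0.1887 bits
  vals <- c(rep(0, 4), rep(1, 4))
  labs <- c(1, 1, 1, 0, 1, 0, 0, 0)
  expect_equal(information_gain(vals, labs), 0.18872, tolerance = 1e-4)
  expect_warning(ig <- information_gain(c(1, 2, 3), c(1, 1, 1)),
                 "constant")
  expect_equal(ig, 0)
})

test_that("quantile binning never produces negative information gain", {
  set.seed(10)
  for (i in 1:40) {
    n <- sample(10:200, 1)
    v <- switch(sample(3, 1), rnorm(n), rpois(n, 2), rep(1, n))
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    expect_gte(information_gain(v, y), 0)
  }
})

test_that("fusion weights are normalized information-gain shares", {
  y <- rep(c(0, 1), 20)
  h_seq <- list(matrix(rnorm(40), 40, 1))
  # every dimension identical to the label -> uniform weights
  x_eq <- cbind(y, y, y)
  w <- compute_fusion_weights(x_eq, h_seq, y, min_samples = 10)
  expect_equal(w$w_x, rep(1 / 3, 3))
  expect_equal(sum(w$w_h), 1)
  # one informative dimension among constants takes all the mass
  x_one <- cbind(y, rep(1, 40), rep(2, 40))
  w1 <- suppressWarnings(compute_fusion_weights(x_one, h_seq, y,
                                                min_samples = 10))
  expect_equal(w1$w_x, c(1, 0, 0))
  # weights equal raw IG normalized (oracle: brute-force MI per column)
  set.seed(21)
  x_rnd <- matrix(rbinom(120, 1, 0.5), 40, 3)
  w2 <- compute_fusion_weights(x_rnd, h_seq, y, min_samples = 10)
  igs <- apply(x_rnd, 2, function(v) {
    brute_mi(table(factor(v, levels = 0:1), factor(y, levels = 0:1)))
  })
  expect_equal(w2$w_x, igs / sum(igs), tolerance = 1e-10)
  expect_error(compute_fusion_weights(x_eq[1:5, ], h_seq, y[1:5]),
               class = "igfuse_error_estimation")
})

test_that("all-zero information gain falls back to uniform weights", {
  y <- rep(c(0, 1), 25)
  x <- matrix(1, 50, 4)
  h <- list(matrix(1, 50, 2), matrix(2, 50, 2))
  w <- suppressWarnings(compute_fusion_weights(x, h, y, min_samples = 10))
  expect_equal(w$w_x, rep(0.25, 4))
  expect_equal(w$w_h, rep(0.5, 2))
})

test_that("channel fusion equals a naive loop with stated broadcasting", {
  set.seed(5)
  d_x <- 4; p <- 6; d_f <- 3; T_len <- 5
  x <- rnorm(d_x)
  h_mat <- matrix(rnorm(T_len * p), T_len, p)
  w <- list(w_x = runif(d_x), w_h = runif(T_len))
  w$w_x <- w$w_x / sum(w$w_x); w$w_h <- w$w_h / sum(w$w_h)
  proj <- list(P_x = matrix(rnorm(d_x * d_f), d_x, d_f),
               P_h = matrix(rnorm(p * d_f), p, d_f),
               b_f = rnorm(d_f))
  got <- fuse_channels(x, h_mat, w, proj)
  want <- matrix(0, T_len, d_f)
  for (t in seq_len(T_len)) {
    for (j in seq_len(d_f)) {
      acc <- proj$b_f[j]
      for (i in seq_len(d_x)) acc <- acc + w$w_x[i] * x[i] * proj$P_x[i, j]
      for (i in seq_len(p)) {
        acc <- acc + w$w_h[t] * h_mat[t, i] * proj$P_h[i, j]
      }
      want[t, j] <- acc
    }
  }
  expect_equal(got, want, tolerance = 1e-12)
  # w_x all zero reduces to the weighted context term alone
  w0 <- list(w_x = rep(0, d_x), w_h = w$w_h)
  got0 <- fuse_channels(x, h_mat, w0, proj)
  expect_equal(got0[2, ],
               drop(crossprod(proj$P_h, w$w_h[2] * h_mat[2, ])) + proj$b_f)
  # T = 1 keeps a single fused row
  expect_equal(dim(fuse_channels(x, h_mat[1, , drop = FALSE],
                                 list(w_x = w$w_x, w_h = w$w_h[1]), proj)),
               c(1, d_f))
})

test_that("attention weights are a proper softmax over unmasked steps", {
  # equal scores -> uniform attention
  a <- attend(matrix(1, 4, 2), q = c(0, 0), W = matrix(0, 2, 2), b = c(0, 0))
  expect_equal(a$alpha, rep(0.25, 4))
  # scores (ln 2, 0) -> weights (2/3, 1/3)
  Fm <- matrix(c(atanh(log(2)), 0), 2, 1)
  a2 <- attend(Fm, q = 1, W = matrix(1, 1, 1), b = 0)
  expect_equal(a2$alpha, c(2 / 3, 1 / 3), tolerance = 1e-9)
  # T = 1: weight 1 and c = F1
  a3 <- attend(matrix(c(3, 4), 1, 2), q = c(1, 1), W = diag(2), b = c(0, 0))
  expect_equal(a3$alpha, 1)
  expect_equal(a3$c, c(3, 4))
  expect_error(attend(matrix(1, 2, 2), q = c(1, 1), W = diag(2), b = c(0, 0),
                      mask = c(FALSE, FALSE)),
               class = "igfuse_error_degenerate")
})

test_that("attention is invariant to additive score shifts and sums to 1", {
  set.seed(8)
  for (i in 1:20) {
    T_len <- sample(1:7, 1)
    Fm <- matrix(rnorm(T_len * 3), T_len, 3)
    W <- matrix(rnorm(6), 3, 2)
    q <- rnorm(2)
    b <- rnorm(2)
    mask <- runif(T_len) < 0.8
    if (!any(mask)) mask[1] <- TRUE
    a <- attend(Fm, q, W, b, mask)
    expect_equal(sum(a$alpha), 1, tolerance = 1e-9)
    expect_true(all(a$alpha[!mask] == 0))
  }
  # explicit shift invariance of the softmax under huge scores
  big <- attend(matrix(c(1000, 1000.5), 2, 1), q = 1,
                W = matrix(1e-3, 1, 1), b = 1000)
  expect_true(all(is.finite(big$alpha)))
  expect_equal(sum(big$alpha), 1)
})

test_that("frozen fusion weights make the fused vector reproducible", {
  set.seed(14)
  x <- rnorm(4)
  h <- matrix(rnorm(12), 4, 3)
  w <- list(w_x = rep(0.25, 4), w_h = rep(0.25, 4))
  proj <- list(P_x = matrix(rnorm(8), 4, 2), P_h = matrix(rnorm(6), 3, 2),
               b_f = rnorm(2))
  f1 <- fuse_channels(x, h, w, proj)
  f2 <- fuse_channels(x, h, w, proj)
  expect_identical(f1, f2)
})
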