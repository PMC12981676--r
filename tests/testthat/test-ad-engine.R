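# Finite-difference verification of the reverse-mode engine. Each check
# compares the tape gradient of a scalar functional against central
# differences computed from an independent plain-R forward evaluation.

numgrad <- function(f, x, eps = 1e-6) {
  g <- array(0, dim = dim(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

rel_err <- function(a, b) max(abs(a - b)) / max(1, max(abs(a)))

test_that("core op gradients match finite differences", {
  set.seed(42)
  B <- matrix(rnorm(20), 4, 5)
  A <- matrix(rnorm(12), 3, 4)
  f <- function(a) sum(1 / (1 + exp(-(a %*% B))))
  tape <- dtakan:::ad_tape()
  an <- dtakan:::ad_leaf(tape, A)
  out <- dtakan:::ad_sum(tape, dtakan:::ad_sigmoid(tape,
    dtakan:::ad_matmul(tape, an, B)))
  dtakan:::ad_backward(tape, out)
  expect_lt(rel_err(numgrad(f, A), an$grad), 1e-6)
})

test_that("layernorm and batchnorm gradients match finite differences", {
  set.seed(1)
  X <- matrix(rnorm(20), 4, 5)
  gm <- matrix(runif(5, 0.5, 1.5), 1)
  f_ln <- function(x) {
    mu <- rowMeans(x); xc <- x - mu; v <- rowMeans(xc^2)
    sum(tanh(sweep(xc / sqrt(v + 1e-5), 2, as.vector(gm), "*")))
  }
  tape <- dtakan:::ad_tape()
  xn <- dtakan:::ad_leaf(tape, X)
  out <- dtakan:::ad_sum(tape, dtakan:::ad_tanh(tape,
    dtakan:::ad_layernorm(tape, xn, gm, matrix(0, 1, 5))))
  dtakan:::ad_backward(tape, out)
  expect_lt(rel_err(numgrad(f_ln, X), xn$grad), 1e-6)

  st <- dtakan:::bn_state(5)
  f_bn <- function(x) {
    mu <- colMeans(x); xc <- sweep(x, 2, mu); v <- colMeans(xc^2)
    sum(tanh(sweep(xc, 2, sqrt(v + 1e-5), "/")))
  }
  tape <- dtakan:::ad_tape()
  xn <- dtakan:::ad_leaf(tape, X)
  out <- dtakan:::ad_sum(tape, dtakan:::ad_tanh(tape,
    dtakan:::ad_batchnorm(tape, xn, matrix(1, 1, 5), matrix(0, 1, 5),
                          st, TRUE)))
  dtakan:::ad_backward(tape, out)
  expect_lt(rel_err(numgrad(f_bn, X), xn$grad), 1e-6)
})

test_that("group softmax matches a per-group reference and its gradient", {
  set.seed(2)
  S <- matrix(rnorm(14), 7, 2)
  grp <- c(1L, 1L, 2L, 2L, 2L, 3L, 3L)
  ref <- S
  for (g in 1:3) for (j in 1:2) {
    r <- grp == g
    ref[r, j] <- exp(S[r, j]) / sum(exp(S[r, j]))
  }
  tape <- dtakan:::ad_tape()
  sn <- dtakan:::ad_leaf(tape, S)
  a <- dtakan:::ad_group_softmax(tape, sn, grp, 3L)
  expect_equal(dtakan:::ad_val(a), ref, tolerance = 1e-12)
  W <- matrix(seq_len(14), 7, 2)
  out <- dtakan:::ad_sum(tape, dtakan:::ad_mul(tape, a, W))
  dtakan:::ad_backward(tape, out)
  f <- function(s) {
    aa <- s
    for (g in 1:3) for (j in 1:2) {
      r <- grp == g
      aa[r, j] <- exp(s[r, j]) / sum(exp(s[r, j]))
    }
    sum(aa * W)
  }
  expect_lt(rel_err(numgrad(f, S), sn$grad), 1e-6)
})

test_that("fused attention ops agree with their unfused composition", {
  set.seed(3)
  n <- 6L; d <- 8L; H <- 2L
  Q <- matrix(rnorm(n * d), n, d)
  K <- matrix(rnorm(n * d), n, d)
  V <- matrix(rnorm(n * d), n, d)
  src <- c(1L, 1L, 2L, 3L, 4L, 5L, 6L, 6L)
  dst <- c(2L, 3L, 1L, 4L, 3L, 5L, 1L, 2L)
  sc <- 1 / sqrt(d / H)
  # reference scores via explicit per-head dot products
  ref <- matrix(0, length(src), H)
  for (k in seq_along(src)) for (h in 1:H) {
    cols <- ((h - 1) * (d / H) + 1):(h * d / H)
    ref[k, h] <- sum(Q[src[k], cols] * K[dst[k], cols]) * sc
  }
  tape <- dtakan:::ad_tape()
  qn <- dtakan:::ad_leaf(tape, Q)
  s <- dtakan:::ad_edge_scores(tape, qn, K, src, dst, H, sc)
  expect_equal(dtakan:::ad_val(s), ref, tolerance = 1e-12)
  W <- matrix(rnorm(length(src) * H), length(src), H)
  out <- dtakan:::ad_sum(tape, dtakan:::ad_mul(tape, s, W))
  dtakan:::ad_backward(tape, out)
  f <- function(q) {
    r <- matrix(0, length(src), H)
    for (k in seq_along(src)) for (h in 1:H) {
      cols <- ((h - 1) * (d / H) + 1):(h * d / H)
      r[k, h] <- sum(q[src[k], cols] * K[dst[k], cols]) * sc
    }
    sum(r * W)
  }
  expect_lt(rel_err(numgrad(f, Q), qn$grad), 1e-6)

  # aggregation: out[src, col] += alpha[edge, head(col)] * V[dst, col]
  alpha <- matrix(runif(length(src) * H), length(src), H)
  tape <- dtakan:::ad_tape()
  vn <- dtakan:::ad_leaf(tape, V)
  an <- dtakan:::ad_leaf(tape, alpha)
  o <- dtakan:::ad_attn_out(tape, an, vn, dst, src, n)
  refo <- matrix(0, n, d)
  for (k in seq_along(src)) for (cc in 1:d) {
    h <- ceiling(cc / (d / H))
    refo[src[k], cc] <- refo[src[k], cc] + alpha[k, h] * V[dst[k], cc]
  }
  expect_equal(dtakan:::ad_val(o), refo, tolerance = 1e-12)
  Wo <- matrix(rnorm(n * d), n, d)
  out <- dtakan:::ad_sum(tape, dtakan:::ad_mul(tape, o, Wo))
  dtakan:::ad_backward(tape, out)
  fv <- function(v) {
    r <- matrix(0, n, d)
    for (k in seq_along(src)) for (cc in 1:d) {
      h <- ceiling(cc / (d / H))
      r[src[k], cc] <- r[src[k], cc] + alpha[k, h] * v[dst[k], cc]
    }
    sum(r * Wo)
  }
  expect_lt(rel_err(numgrad(fv, V), vn$grad), 1e-6)
})

test_that("gather, scatter and sparse products backpropagate correctly", {
  set.seed(4)
  X <- matrix(rnorm(15), 5, 3)
  idx <- c(2L, 2L, 5L, 1L)
  tape <- dtakan:::ad_tape()
  xn <- dtakan:::ad_leaf(tape, X)
  r <- dtakan:::ad_rows(tape, xn, idx)
  out <- dtakan:::ad_sum(tape, dtakan:::ad_mul(tape, r, r))
  dtakan:::ad_backward(tape, out)
  f <- function(x) sum(x[idx, ]^2)
  expect_lt(rel_err(numgrad(f, X), xn$grad), 1e-6)

  S <- Matrix::sparseMatrix(i = c(1, 2, 3, 1), j = c(2, 3, 1, 1),
                            x = c(0.5, 0.2, 0.9, 1), dims = c(3, 3))
  X2 <- matrix(rnorm(6), 3, 2)
  tape <- dtakan:::ad_tape()
  xn <- dtakan:::ad_leaf(tape, X2)
  r <- dtakan:::ad_spmm(tape, S, xn)
  out <- dtakan:::ad_sum(tape, dtakan:::ad_mul(tape, r, r))
  dtakan:::ad_backward(tape, out)
  f2 <- function(x) sum(as.matrix(S %*% x)^2)
  expect_lt(rel_err(numgrad(f2, X2), xn$grad), 1e-6)
})

test_that("the spline design matrix backpropagates through its inputs", {
  set.seed(5)
  X <- matrix(runif(8, -0.9, 0.9), 4, 2)
  grid <- seq(-1, 1, length.out = 6)
  C <- matrix(rnorm(16 * 3), 16, 3)
  tape <- dtakan:::ad_tape()
  xn <- dtakan:::ad_leaf(tape, X)
  out <- dtakan:::ad_sum(tape, dtakan:::ad_matmul(tape,
    dtakan:::ad_bspline_design(tape, xn, grid, 3L), C))
  dtakan:::ad_backward(tape, out)
  f <- function(x) {
    B <- bspline_basis(as.vector(x), grid, 3)
    sum(cbind(B[1:4, ], B[5:8, ]) %*% C)
  }
  expect_lt(rel_err(numgrad(f, X), xn$grad), 1e-4)
})
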