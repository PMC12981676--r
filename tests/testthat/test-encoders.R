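make_graph <- function(n, seed, feat_dim = 6L, p_edge = 0.4) {
  set.seed(seed)
  nf <- matrix(rnorm(n * feat_dim), n, feat_dim)
  edges <- NULL; w <- c()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (runif(1) < p_edge) {
      edges <- rbind(edges, c(i - 1L, j - 1L), c(j - 1L, i - 1L))
      wt <- runif(1, 0.5, 1)
      w <- c(w, wt, wt)
    }
  }
  if (is.null(edges)) edges <- matrix(integer(0), 0, 2)
  weighted_graph(nf, edges, w)
}

test_that("gcn_layer equals the dense normalized-adjacency oracle", {
  g <- make_graph(5, seed = 11)
  params <- gcn_layer_params(6, 4, seed = 3)
  out <- gcn_layer(g, params, training = FALSE)
  # dense oracle: D^-1/2 (A + I) D^-1/2 H W + b, eval-mode BN, ReLU
  n <- nrow(g$node_features)
  A <- matrix(0, n, n)
  A[g$edges + 1L] <- g$edge_weights
  Ah <- A + diag(n)
  dis <- 1 / sqrt(rowSums(Ah))
  prop <- diag(dis) %*% Ah %*% diag(dis) %*% g$node_features %*%
    params$gcn$W
  prop <- sweep(prop, 2, as.vector(params$gcn$b), "+")
  st <- params$state
  bn <- sweep(sweep(prop, 2, st$mean), 2, sqrt(st$var + 1e-5), "/")
  oracle <- pmax(bn, 0)
  expect_equal(out, oracle, tolerance = 1e-10)
})

test_that("an isolated node passes through its self-loop only", {
  g1 <- weighted_graph(matrix(rnorm(6), 1, 6), matrix(integer(0), 0, 2),
                       numeric(0))
  params <- gcn_layer_params(6, 4, seed = 5)
  out <- gcn_layer(g1, params)
  ref <- pmax(matrix(g1$node_features %*% params$gcn$W +
                       rep(params$gcn$b, each = 1), 1), 0) /
    sqrt(1 + 1e-5)  # eval BN with unit running variance
  expect_equal(dim(out), c(1L, 4L))
  expect_equal(out, pmax(sweep(g1$node_features %*% params$gcn$W, 2,
                               as.vector(params$gcn$b), "+") /
                           sqrt(1 + 1e-5), 0), tolerance = 1e-10)
})

test_that("gat attention weights are a simplex over each neighborhood", {
  g <- make_graph(6, seed = 21)
  params <- gat_layer_params(6, seed = 7)
  res <- gat_layer(g$node_features, g$edges, params,
                   return_attention = TRUE)
  sums <- tapply(res$alpha, res$edges[, 1], sum)
  expect_equal(as.vector(sums), rep(1, 6), tolerance = 1e-12)
  expect_true(all(res$alpha > 0))
})

test_that("gat_layer matches a step-by-step hand computation", {
  # 4-node path graph 0-1-2-3
  edges <- rbind(c(0L, 1L), c(1L, 0L), c(1L, 2L), c(2L, 1L),
                 c(2L, 3L), c(3L, 2L))
  set.seed(9)
  h <- matrix(rnorm(4 * 3), 4, 3)
  params <- gat_layer_params(3, seed = 13)
  out <- gat_layer(h, edges, params, training = FALSE)

  W <- params$W
  Wh <- h %*% W
  s1 <- Wh %*% params$a_src
  s2 <- Wh %*% params$a_dst
  src <- c(edges[, 1] + 1L, 1:4)
  dst <- c(edges[, 2] + 1L, 1:4)
  e <- s1[src] + s2[dst]
  e <- ifelse(e > 0, e, 0.2 * e)
  agg <- matrix(0, 4, 3)
  for (i in 1:4) {
    rows <- src == i
    a <- exp(e[rows] - max(e[rows]))
    a <- a / sum(a)
    agg[i, ] <- colSums(a * Wh[dst[rows], , drop = FALSE])
  }
  bn <- sweep(sweep(agg, 2, params$state$mean), 2,
              sqrt(params$state$var + 1e-5), "/")
  oracle <- pmax(sweep(bn, 2, as.vector(params$bn$gamma), "*") +
                   rep(params$bn$beta, each = 4), 0)
  expect_equal(out, oracle, tolerance = 1e-10)
})

test_that("graph encoding is permutation invariant in eval mode", {
  g <- make_graph(8, seed = 31)
  params <- graph_encoder_params(6, hidden_dim = 8, output_dim = 12,
                                 seed = 17)
  base <- graph_encode(g, params)
  set.seed(99)
  for (k in 1:10) {
    perm <- sample(8)
    inv <- order(perm)
    pg <- weighted_graph(g$node_features[perm, ],
                         cbind(inv[g$edges[, 1] + 1L] - 1L,
                               inv[g$edges[, 2] + 1L] - 1L),
                         g$edge_weights)
    expect_equal(graph_encode(pg, params), base, tolerance = 1e-8)
  }
})

test_that("graph encoder output width follows the configured output dim", {
  params <- graph_encoder_params(6, hidden_dim = 16, output_dim = 128,
                                 seed = 1)
  for (n in c(1, 4, 9)) {
    g <- make_graph(n, seed = n, p_edge = 0.5)
    expect_length(graph_encode(g, params), 128L)
  }
  expect_error(graph_encode(weighted_graph(matrix(0, 0, 6) + 0,
                                           matrix(integer(0), 0, 2),
                                           numeric(0)), params), "empty")
})

test_that("global add pooling is additive over identical disconnected nodes", {
  nf <- matrix(rnorm(6), 1, 6)
  g1 <- weighted_graph(nf, matrix(integer(0), 0, 2), numeric(0))
  g2 <- weighted_graph(rbind(nf, nf), matrix(integer(0), 0, 2), numeric(0))
  params <- graph_encoder_params(6, hidden_dim = 8, output_dim = 4, seed = 3)
  gb1 <- dtakan:::build_graph_batch(list(g1))
  gb2 <- dtakan:::build_graph_batch(list(g2))
  pool_of <- function(gb) {
    tape <- dtakan:::ad_tape()
    h <- dtakan:::ad_gcn_layer(tape, gb$X, gb, params,
                               params$states$bn0, FALSE)
    for (i in seq_along(params$gat)) {
      h <- dtakan:::ad_gat_layer(tape, h, gb, params$gat[[i]],
                                 params$states$gat[[i]], FALSE)
    }
    dtakan:::ad_val(dtakan:::ad_scatter_rows(tape, h, gb$gid, gb$n_graphs))
  }
  expect_equal(pool_of(gb2), 2 * pool_of(gb1), tolerance = 1e-10)
})

test_that("transformer encoding preserves token counts and batches consistently", {
  params <- transformer_params(10, model_dim = 8, n_layers = 2, n_heads = 2,
                               ff_dim = 8, max_len = 50, seed = 5)
  a <- matrix(rnorm(7 * 10), 7, 10)
  b <- matrix(rnorm(4 * 10), 4, 10)
  single <- transformer_encode(a, params = params)
  expect_equal(nrow(single$tokens[[1]]), 7L)
  expect_equal(ncol(single$tokens[[1]]), 8L)
  batch <- transformer_encode(list(a, b), params = params)
  expect_equal(batch$tokens[[1]], single$tokens[[1]], tolerance = 1e-10)
  expect_equal(dim(batch$pooled), c(2L, 8L))
  # eval-mode determinism
  again <- transformer_encode(list(a, b), params = params)
  expect_identical(batch$tokens, again$tokens)
})

test_that("padding tokens cannot influence real-token outputs", {
  params <- transformer_params(6, model_dim = 8, n_layers = 2, n_heads = 2,
                               ff_dim = 8, max_len = 30, seed = 5)
  arr <- array(rnorm(2 * 9 * 6), c(2, 9, 6))
  mask <- rbind(c(rep(TRUE, 5), rep(FALSE, 4)), rep(TRUE, 9))
  out1 <- transformer_encode(arr, mask, params)
  arr2 <- arr
  arr2[1, 6:9, ] <- 999  # perturb padding only
  out2 <- transformer_encode(arr2, mask, params)
  expect_equal(out1$tokens[[1]], out2$tokens[[1]], tolerance = 1e-12)
  expect_equal(out1$pooled, out2$pooled, tolerance = 1e-12)

  all_pad <- rbind(rep(FALSE, 9), rep(TRUE, 9))
  expect_error(transformer_encode(arr, all_pad, params), "padding")
})

test_that("encoder outputs stay finite across random seeds", {
  params <- transformer_params(5, model_dim = 8, n_layers = 1, n_heads = 2,
                               ff_dim = 8, max_len = 20, seed = 2)
  gp <- graph_encoder_params(5, hidden_dim = 8, output_dim = 8, seed = 2)
  for (seed in 1:100) {
    set.seed(seed)
    x <- matrix(rnorm(6 * 5, sd = 3), 6, 5)
    out <- transformer_encode(x, params = params)
    expect_no_na(out$pooled)
    g <- make_graph(5, seed = seed, feat_dim = 5L)
    expect_no_na(graph_encode(g, gp))
  }
})
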