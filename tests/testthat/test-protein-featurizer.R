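test_that("special-token trimming keeps the residue window", {
  m <- matrix(1:10, 5, 2)
  expect_equal(trim_special_tokens(m, TRUE), m[2:4, ])
  expect_identical(trim_special_tokens(m, FALSE), m)
  m3 <- matrix(1:6, 3, 2)
  expect_equal(dim(trim_special_tokens(m3, TRUE)), c(1L, 2L))
  expect_error(trim_special_tokens(matrix(1:4, 2, 2), TRUE), ">= 3")
})

test_that("threshold rule creates exactly the strict-exceedance edges", {
  emb <- matrix(rnorm(5 * 8), 5, 8)
  M <- diag(3)
  rec <- protein_record("p", "MKV", embeddings = matrix(rnorm(3 * 8), 3, 8),
                        contact = M, embed_dim = 8)
  g0 <- build_protein_graph(rec)
  expect_equal(nrow(g0$edges), 0L)   # zero off-diagonal -> no edges

  M2 <- diag(3); M2[1, 2] <- M2[2, 1] <- 0.9
  rec2 <- protein_record("p", "MKV", embeddings = matrix(rnorm(24), 3, 8),
                         contact = M2, embed_dim = 8)
  g2 <- build_protein_graph(rec2)
  expect_equal(g2$edges[order(g2$edges[, 1]), ],
               rbind(c(0L, 1L), c(1L, 0L)))
  expect_equal(g2$edge_weights, c(0.9, 0.9))

  # exactly-at-threshold contacts are excluded (strict >)
  M3 <- diag(3); M3[1, 3] <- M3[3, 1] <- 0.5
  rec3 <- protein_record("p", "MKV", embeddings = matrix(rnorm(24), 3, 8),
                         contact = M3, embed_dim = 8)
  expect_equal(nrow(build_protein_graph(rec3)$edges), 0L)
})

test_that("edge sets match the brute-force double loop on random maps", {
  spec <- contact_graph_spec()
  for (seed in 1:8) {
    set.seed(seed)
    n <- sample(3:12, 1)
    M <- matrix(runif(n * n), n, n)
    M <- (M + t(M)) / 2
    diag(M) <- 1
    seqs <- paste(rep("A", n), collapse = "")
    rec <- protein_record(paste0("p", seed), seqs,
                          embeddings = matrix(rnorm(n * 4), n, 4),
                          contact = M, embed_dim = 4)
    g <- build_protein_graph(rec, spec)
    naive <- NULL
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i != j && M[i, j] > 0.5) naive <- rbind(naive, c(i - 1L, j - 1L))
    }
    got <- g$edges[order(g$edges[, 1], g$edges[, 2]), , drop = FALSE]
    want <- naive[order(naive[, 1], naive[, 2]), , drop = FALSE]
    expect_equal(got, want)
    expect_equal(g$edge_weights[order(g$edges[, 1], g$edges[, 2])],
                 M[want + 1L])
  }
})

test_that("edges are symmetric and monotone in the threshold", {
  rec <- random_protein(25, seed = 5)
  g <- build_protein_graph(rec)
  key <- paste(g$edges[, 1], g$edges[, 2])
  rev_key <- paste(g$edges[, 2], g$edges[, 1])
  expect_setequal(key, rev_key)
  w <- setNames(g$edge_weights, key)
  expect_equal(unname(w[key]), unname(w[rev_key]))

  counts <- vapply(c(0.3, 0.5, 0.7, 0.9), function(th) {
    nrow(build_protein_graph(rec, contact_graph_spec(threshold = th))$edges)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("token-indexed contact matrices are trimmed on both axes", {
  n <- 6L
  emb <- matrix(rnorm((n + 2) * 8), n + 2, 8)
  Mtok <- matrix(runif((n + 2)^2), n + 2, n + 2)
  Mtok <- (Mtok + t(Mtok)) / 2
  diag(Mtok) <- 1
  rec <- protein_record("p", paste(rep("A", n), collapse = ""),
                        embeddings = emb, contact = Mtok,
                        has_special_tokens = TRUE, embed_dim = 8)
  g <- build_protein_graph(rec)
  expect_equal(nrow(g$node_features), n)
  # node features equal the trimmed embeddings
  expect_equal(g$node_features, emb[2:(n + 1), ])
  # compare against residue-indexed construction of the interior window
  Mres <- Mtok[2:(n + 1), 2:(n + 1)]
  rec2 <- protein_record("p", paste(rep("A", n), collapse = ""),
                         embeddings = emb, contact = Mres,
                         has_special_tokens = TRUE, embed_dim = 8)
  g2 <- build_protein_graph(rec2)
  expect_equal(g$edges, g2$edges)
  expect_equal(g$edge_weights, g2$edge_weights)
})

test_that("self-loop flag keeps the diagonal out by default", {
  rec <- random_protein(12, seed = 9)
  g_off <- build_protein_graph(rec)
  expect_false(any(g_off$edges[, 1] == g_off$edges[, 2]))
  g_on <- build_protein_graph(rec, contact_graph_spec(include_self_loops = TRUE))
  expect_equal(sum(g_on$edges[, 1] == g_on$edges[, 2]), 12L)
})

test_that("protein batches pad to the batch maximum under the cap", {
  a <- matrix(rnorm(5 * 4), 5, 4)
  b <- matrix(rnorm(9 * 4), 9, 4)
  batch <- pad_protein_batch(list(a, b), cap = 1200)
  expect_equal(dim(batch$embeddings), c(2L, 9L, 4L))
  expect_equal(rowSums(batch$mask), c(5, 9))
  expect_equal(batch$embeddings[1, 1:5, ], a)
  expect_equal(batch$embeddings[1, 6:9, ], matrix(0, 4, 4))

  single <- pad_protein_batch(list(a))
  expect_equal(dim(single$embeddings), c(1L, 5L, 4L))

  long <- matrix(rnorm(1500 * 2), 1500, 2)
  capped <- pad_protein_batch(list(long), cap = 1200)
  expect_equal(dim(capped$embeddings)[2], 1200L)
  expect_equal(capped$lengths, 1200L)
  expect_error(pad_protein_batch(list()), "empty")
})
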