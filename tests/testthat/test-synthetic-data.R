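test_that("gen_protein is deterministic and structurally valid", {
  p1 <- gen_protein(30, seed = 7, embed_dim = 48)
  p2 <- gen_protein(30, seed = 7, embed_dim = 48)
  expect_identical(p1, p2)
  expect_equal(nchar(p1$sequence), 30L)
  expect_equal(dim(p1$embeddings), c(32L, 48L))   # start/end tokens included
  expect_true(p1$has_special_tokens)
  M <- p1$contact
  expect_equal(M, t(M))
  expect_equal(unname(diag(M)), rep(1, 30))
  expect_true(all(M >= 0 & M <= 1))
  expect_error(gen_protein(2, seed = 1), ">= 3")
})

test_that("contact band exceeds threshold and long-range rate matches", {
  w <- 3L; p_lr <- 0.05
  pr <- gen_protein(200, seed = 21, band_width = w, long_range_prob = p_lr,
                    embed_dim = 8)
  M <- pr$contact
  iu <- which(upper.tri(M), arr.ind = TRUE)
  d <- abs(iu[, 1] - iu[, 2])
  expect_true(all(M[iu][d <= w] > 0.5))
  off <- M[iu][d > w]
  phat <- mean(off > 0.5)
  se <- sqrt(p_lr * (1 - p_lr) / length(off))
  expect_lt(abs(phat - p_lr), 3 * se)
})

test_that("thresholded synthetic contact maps keep the chain connected", {
  for (seed in 1:5) {
    pr <- gen_protein(40, seed = seed, embed_dim = 8)
    M <- pr$contact
    adj <- abs(row(M) - col(M)) == 1
    expect_true(all(M[adj] > 0.5))
  }
})

test_that("gen_drug covers the size bucket and falls back to alkanes", {
  d1 <- gen_drug(1, seed = 3, embed_dim = 12)
  expect_equal(d1$smiles, "C")
  g <- smiles_to_graph(d1$smiles)
  expect_equal(nrow(g$node_features), 1L)
  expect_equal(nrow(g$edges), 0L)

  d2a <- gen_drug(10, seed = 5, embed_dim = 12)
  d2b <- gen_drug(10, seed = 5, embed_dim = 12)
  expect_identical(d2a, d2b)
  expect_equal(dim(d2a$embeddings), c(nchar(d2a$smiles), 12L))

  # no library molecule near 60 heavy atoms: linear alkane fallback
  d3 <- gen_drug(60, seed = 1, embed_dim = 12)
  expect_equal(d3$smiles, strrep("C", 60))
})

test_that("every packaged SMILES parses with 88-wide features", {
  lib <- dtakan:::SMILES_LIBRARY
  for (i in seq_len(nrow(lib))) {
    g <- smiles_to_graph(lib$smiles[i])
    expect_equal(ncol(g$node_features), 88L)
    expect_equal(nrow(g$node_features), lib$n_atoms[i])
  }
})

test_that("gen_dataset plants the latent-factor affinity structure", {
  cfg <- tiny_synthetic_config(latent_dim = 1L, noise_sd = 0,
                               n_pairs = 36L)
  ds <- gen_dataset(cfg)
  # noiseless rank-1: affinity - intercept factorizes as u_p * v_d
  u <- ds$latent$u[ds$interactions$protein_id, 1]
  v <- ds$latent$v[ds$interactions$drug_id, 1]
  expect_equal(ds$interactions$affinity, unname(u * v) + cfg$intercept,
               tolerance = 1e-12)
  expect_false(anyDuplicated(names(ds$proteins)) > 0)
  expect_false(anyDuplicated(names(ds$drugs)) > 0)
})

test_that("affinity variance follows the law of total variance", {
  # pools large enough that the realized grid variance of u.v sits close
  # to its expectation latent_dim; pairs sharing an entity are correlated,
  # so small pools fluctuate well beyond the estimator's iid error
  cfg <- synthetic_config(n_proteins = 400L, n_drugs = 400L,
                          n_pairs = 2000L,
                          protein_len_range = c(5L, 8L),
                          drug_atoms_range = c(3L, 6L),
                          embed_dim_protein = 4L, embed_dim_drug = 4L,
                          latent_dim = 8L, noise_sd = 0.5, seed = 2L)
  ds <- gen_dataset(cfg)
  expected <- cfg$latent_dim + cfg$noise_sd^2   # Var(u.v) = latent_dim
  expect_lt(abs(var(ds$interactions$affinity) - expected) / expected, 0.1)
})

test_that("per-entity hashing isolates entities from grid growth", {
  small <- gen_dataset(tiny_synthetic_config(n_proteins = 4L, n_pairs = 10L))
  large <- gen_dataset(tiny_synthetic_config(n_proteins = 6L, n_pairs = 10L))
  for (id in names(small$proteins)) {
    expect_identical(small$proteins[[id]], large$proteins[[id]])
  }
  expect_identical(small$drugs, large$drugs)
})

test_that("seed changes reshuffle pairings but keep marginal shapes", {
  a <- gen_dataset(tiny_synthetic_config(seed = 1L))
  b <- gen_dataset(tiny_synthetic_config(seed = 2L))
  expect_false(identical(a$interactions$affinity, b$interactions$affinity))
  expect_equal(dim(a$interactions), dim(b$interactions))
  expect_error(gen_dataset(tiny_synthetic_config(n_pairs = 37L)),
               "exceeds")
})

test_that("dataset directories round-trip through write/read", {
  ds <- tiny_dataset()
  d <- withr::local_tempdir()
  dir_out <- file.path(d, "ds")
  write_dataset(ds, dir_out, format = "npy")
  expect_error(write_dataset(ds, dir_out), "not empty")
  back <- read_dataset(dir_out)
  expect_equal(names(back$proteins), names(ds$proteins))
  expect_equal(back$interactions, ds$interactions)
  p0 <- ds$proteins[[1]]; p1 <- back$proteins[[1]]
  expect_equal(p1$embeddings, p0$embeddings)
  expect_equal(p1$contact, p0$contact)
  expect_equal(back$drugs[[3]]$smiles, ds$drugs[[3]]$smiles)
})
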