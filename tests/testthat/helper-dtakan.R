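# Shared fixtures: a tiny model configuration and a small synthetic
# dataset, built once per test run.

tiny_model_config <- function(...) {
  args <- list(epochs = 2L, lr = 1e-3, batch_size = 8L,
               transformer_layers = 2L, transformer_heads = 2L,
               transformer_dim = 16L, transformer_ff_dim = 16L,
               protein_embed_dim = 24L, drug_embed_dim = 12L,
               protein_graph_hidden_dim = 16L, drug_graph_hidden_dim = 16L,
               graph_output_dim = 16L, attention_dim = 8L,
               kan_hidden = c(16L, 8L), seed = 42L)
  do.call(model_config, utils::modifyList(args, list(...)))
}

tiny_synthetic_config <- function(...) {
  args <- list(n_proteins = 6L, n_drugs = 6L, n_pairs = 30L,
               protein_len_range = c(12L, 20L),
               drug_atoms_range = c(3L, 12L),
               embed_dim_protein = 24L, embed_dim_drug = 12L,
               seed = 101L)
  do.call(synthetic_config, utils::modifyList(args, list(...)))
}

the_fixture_env <- new.env(parent = emptyenv())

tiny_dataset <- function() {
  if (is.null(the_fixture_env$ds)) {
    the_fixture_env$ds <- gen_dataset(tiny_synthetic_config())
  }
  the_fixture_env$ds
}

# A small random protein record with residue-indexed contact matrix.
random_protein <- function(len = 10L, seed = 1L, embed_dim = 24L) {
  gen_protein(len, seed = seed, embed_dim = embed_dim)
}

expect_no_na <- function(x) expect_true(all(is.finite(x)))
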