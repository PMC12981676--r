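forward_batch <- function(model, pairs, cache) {
  b <- dtakan:::prepare_batch(pairs, cache, model$config)
  tape <- dtakan:::ad_tape()
  yhat <- dtakan:::dta_forward(tape, model$params, model$states,
                               model$config, b, training = FALSE)
  dtakan:::ad_val(yhat)
}

test_that("forward shapes hold for the full model and every ablation", {
  ds <- tiny_dataset()
  pairs <- ds$interactions[1:6, ]
  flag_sets <- list(
    list(),
    list(use_graph = FALSE),
    list(use_sequence = FALSE),
    list(use_linear_attention = FALSE),
    list(use_gated_fusion = FALSE),
    list(use_esmc_node_features = FALSE),
    list(use_kan = FALSE)
  )
  for (flags in flag_sets) {
    mc <- do.call(tiny_model_config, flags)
    model <- dta_model(mc)
    cache <- dtakan:::featurize_entities(ds$proteins, ds$drugs, mc)
    out <- forward_batch(model, pairs, cache)
    expect_equal(dim(out), c(6L, 1L))
    expect_no_na(out)
  }
})

test_that("ablation flags change the head input width as specified", {
  expect_equal(dta_model(tiny_model_config())$params$head$widths[1], 64L)
  expect_equal(dta_model(tiny_model_config(
    use_sequence = FALSE))$params$head$widths[1], 16L)
  expect_equal(dta_model(tiny_model_config(
    use_graph = FALSE))$params$head$widths[1], 48L)
  m <- dta_model(tiny_model_config(use_kan = FALSE))
  expect_true(m$params$head$mlp)
})

test_that("every parameter tensor receives a nonzero gradient", {
  ds <- tiny_dataset()
  mc <- tiny_model_config(dropout = 0)
  model <- dta_model(mc)
  cache <- dtakan:::featurize_entities(ds$proteins, ds$drugs, mc)
  b <- dtakan:::prepare_batch(ds$interactions[1:10, ], cache, mc)
  tape <- dtakan:::ad_tape()
  P <- dtakan:::wrap_params(tape, model$params)
  yhat <- dtakan:::dta_forward(tape, P, model$states, mc, b,
                               training = TRUE)
  diff <- dtakan:::ad_sub(tape, yhat, b$y)
  loss <- dtakan:::ad_mean(tape, dtakan:::ad_mul(tape, diff, diff))
  dtakan:::ad_backward(tape, loss)
  grads <- dtakan:::flatten_params(dtakan:::collect_grads(P))
  expect_gt(length(grads), 80)
  for (nm in names(grads)) {
    expect_gt(max(abs(grads[[nm]])), 0, label = paste("gradient of", nm))
  }
})

test_that("checkpoints round-trip to identical predictions", {
  ds <- tiny_dataset()
  mc <- tiny_model_config()
  model <- dta_model(mc)
  cache <- dtakan:::featurize_entities(ds$proteins, ds$drugs, mc)
  pairs <- ds$interactions[1:8, ]
  before <- forward_batch(model, pairs, cache)
  f <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(model, f)
  back <- load_checkpoint(f)
  expect_equal(forward_batch(back, pairs, cache), before,
               tolerance = 1e-12)
  expect_identical(back$config$use_kan, TRUE)
  expect_error(load_checkpoint(system.file("DESCRIPTION",
                                           package = "dtakan")))
})

test_that("predict_affinity carries labels through and names unknown ids", {
  ds <- tiny_dataset()
  mc <- tiny_model_config()
  model <- dta_model(mc)
  cache <- dtakan:::featurize_entities(ds$proteins, ds$drugs, mc)
  preds <- predict_affinity(model, ds$interactions[1:5, ], cache = cache)
  expect_named(preds, c("drug_id", "protein_id", "y_true", "y_pred"))
  expect_equal(preds$y_true, ds$interactions$affinity[1:5])
  bad <- tibble::tibble(drug_id = "nope", protein_id = "prot001")
  expect_error(predict_affinity(model, bad, cache = cache), "nope")
})

test_that("eval-mode forward passes are deterministic", {
  ds <- tiny_dataset()
  mc <- tiny_model_config()
  model <- dta_model(mc)
  cache <- dtakan:::featurize_entities(ds$proteins, ds$drugs, mc)
  pairs <- ds$interactions[1:10, ]
  expect_identical(forward_batch(model, pairs, cache),
                   forward_batch(model, pairs, cache))
})
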