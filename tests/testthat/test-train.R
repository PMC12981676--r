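test_that("early stopping fires exactly patience+1 epochs after the best", {
  es <- early_stopping(patience = 20L)
  # constant validation trace: epoch 1 is the best, then 21 flat epochs
  decisions <- vapply(1:30, function(i) es$update(1.0), logical(1))
  expect_equal(which(!decisions)[1], 22L)
  expect_equal(es$best_epoch, 1L)

  es2 <- early_stopping(patience = 2L)
  trace <- c(5, 4, 4.5, 3, 3.5, 3.6, 3.7)
  going <- vapply(trace, es2$update, logical(1))
  # best at epoch 4; stops when the 3rd consecutive non-improvement lands
  expect_equal(going, c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_equal(es2$best_epoch, 4L)
  expect_equal(es2$best, 3)
})

test_that("a tiny model overfits a small noiseless planted set", {
  cfg <- tiny_synthetic_config(n_proteins = 8L, n_drugs = 8L,
                               n_pairs = 64L, noise_sd = 0,
                               latent_dim = 2L)
  ds <- gen_dataset(cfg)
  mc <- tiny_model_config(epochs = 300L, lr = 5e-3, batch_size = 64L,
                          dropout = 0, encoder_lr_scale = 0.05,
                          transformer_layers = 1L,
                          transformer_dim = 24L, transformer_ff_dim = 24L,
                          protein_graph_hidden_dim = 24L,
                          drug_graph_hidden_dim = 24L,
                          graph_output_dim = 24L, attention_dim = 12L,
                          kan_hidden = c(24L, 12L))
  model <- dta_model(mc)
  cache <- dtakan:::featurize_entities(ds$proteins, ds$drugs, mc)
  # train == val: pure capacity check on 64 noiseless pairs
  fit <- dta_train(model, ds$interactions, ds$interactions, cache = cache)
  expect_lt(min(fit$history$train_mse), 0.01)
  ev <- dta_evaluate(fit, ds$interactions, cache = cache)
  expect_lt(ev$metrics$mse, 0.05)
  expect_gt(ev$metrics$ci, 0.95)
})

test_that("training histories are reproducible under a fixed seed", {
  ds <- tiny_dataset()
  mc <- tiny_model_config(epochs = 2L)
  sp <- split_dataset(ds$interactions, split_spec("warm", seed = 4))
  cache <- dtakan:::featurize_entities(ds$proteins, ds$drugs, mc)
  f1 <- dta_train(dta_model(mc), sp$train, sp$val, cache = cache)
  f2 <- dta_train(dta_model(mc), sp$train, sp$val, cache = cache)
  expect_identical(f1$history, f2$history)
  p1 <- predict_affinity(f1$model, sp$test, cache = cache)
  p2 <- predict_affinity(f2$model, sp$test, cache = cache)
  expect_identical(p1$y_pred, p2$y_pred)
})

test_that("training restores the best-validation parameters and states", {
  ds <- tiny_dataset()
  mc <- tiny_model_config(epochs = 4L)
  sp <- split_dataset(ds$interactions, split_spec("warm", seed = 4))
  cache <- dtakan:::featurize_entities(ds$proteins, ds$drugs, mc)
  fit <- dta_train(dta_model(mc), sp$train, sp$val, cache = cache)
  # re-evaluating the returned model on the validation set reproduces the
  # best recorded validation MSE exactly (parameters AND running state)
  val_pred <- predict_affinity(fit$model, sp$val, cache = cache)
  expect_equal(mean((val_pred$y_pred - sp$val$affinity)^2), fit$best_val,
               tolerance = 1e-10)
})

test_that("fit accessors expose history and parameter summaries", {
  ds <- tiny_dataset()
  mc <- tiny_model_config(epochs = 2L)
  sp <- split_dataset(ds$interactions, split_spec("warm", seed = 4))
  cache <- dtakan:::featurize_entities(ds$proteins, ds$drugs, mc)
  fit <- dta_train(dta_model(mc), sp$train, sp$val, cache = cache)
  td <- tidy(fit)
  expect_true(all(c("parameter", "l2", "n") %in% names(td)))
  expect_gt(nrow(td), 50)
  gl <- glance(fit)
  expect_equal(gl$epochs_run, 2L)
  expect_equal(gl$head, "kan")
  expect_s3_class(ggplot2::autoplot(fit), "ggplot")
  ev <- dta_evaluate(fit, sp$test, cache = cache)
  expect_s3_class(ggplot2::autoplot(ev$predictions), "ggplot")
})
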