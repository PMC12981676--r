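# Training loop: Adam on mean-squared-error loss, mini-batches, early
# stopping on validation MSE with best-weight restoration.

#' Early-stopping tracker
#'
#' Tracks the best validation loss seen so far; training stops once the
#' loss has failed to (strictly) decrease for more than `patience`
#' consecutive epochs. With a constant loss trace the stop fires on the
#' 21st epoch after the best one (for the default patience of 20).
#'
#' @param patience Number of non-improving epochs tolerated (default 20).
#' @return An environment with `update(val)` returning `TRUE` while
#'   training should continue, plus fields `best`, `best_epoch`, `epoch`
#'   and `wait`.
#' @export
early_stopping <- function(patience = 20L) {
  es <- new.env(parent = emptyenv())
  es$patience <- as.integer(patience)
  es$best <- Inf
  es$best_epoch <- 0L
  es$epoch <- 0L
  es$wait <- 0L
  es$update <- function(val) {
    es$epoch <- es$epoch + 1L
    if (val < es$best) {
      es$best <- val
      es$best_epoch <- es$epoch
      es$wait <- 0L
    } else {
      es$wait <- es$wait + 1L
    }
    es$wait <= es$patience
  }
  es
}

#' Train a drug-target affinity model
#'
#' Minimizes mean squared error with Adam (learning rate, batch size,
#' epoch budget and dropout from the model's [model_config()]), evaluates
#' validation MSE each epoch, stops early when validation MSE has not
#' decreased for more than `patience` epochs, and restores the
#' best-validation parameters.
#'
#' @param model A [dta_model()].
#' @param train,val Interaction tibbles (`drug_id`, `protein_id`,
#'   `affinity`).
#' @param proteins,drugs Named lists of entity records covering all ids.
#' @param cache Optional precomputed `featurize_entities()` cache.
#' @param verbose Print per-epoch progress.
#' @return A `dta_fit` list: the trained `model`, a `history` tibble
#'   (`epoch`, `train_mse`, `val_mse`), `best_epoch` and `best_val`.
#' @export
dta_train <- function(model, train, val, proteins = NULL, drugs = NULL,
                      cache = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "dta_model"))
  cfg <- model$config
  if (nrow(train) == 0L || nrow(val) == 0L) {
    abort("train and validation sets must be non-empty.")
  }
  if (is.null(cache)) {
    cache <- featurize_entities(proteins, drugs, cfg)
  }
  set.seed(cfg$seed)
  flat <- flatten_params(model$params)
  opt <- adam_state(flat)
  is_encoder <- grepl("^\\.(prot_tf|drug_tf)\\.|\\.(gcn|bn0|gat)\\.",
                      names(flat))
  lr_vec <- ifelse(is_encoder, cfg$lr * (cfg$encoder_lr_scale %||% 1),
                   cfg$lr)
  es <- early_stopping(cfg$patience)
  best_flat <- flat
  best_states <- snapshot_states(model)
  history <- vector("list", cfg$epochs)
  n_tr <- nrow(train)
  # fixed mini-batch membership (seeded), shuffled order per epoch: batch
  # structures (merged graphs, attention edge lists) are built once
  ord0 <- sample.int(n_tr)
  batch_ids <- split(ord0, ceiling(seq_along(ord0) / cfg$batch_size))
  batch_structs <- lapply(batch_ids, function(bi) {
    prepare_batch(train[bi, , drop = FALSE], cache, cfg)
  })
  val_struct <- prepare_batch(val, cache, cfg)
  for (epoch in seq_len(cfg$epochs)) {
    tr_loss_sum <- 0
    for (k in sample.int(length(batch_structs))) {
      bi <- batch_ids[[k]]
      b <- batch_structs[[k]]
      tape <- ad_tape()
      P <- wrap_params(tape, model$params)
      yhat <- dta_forward(tape, P, model$states, cfg, b, training = TRUE)
      diff <- ad_sub(tape, yhat, b$y)
      loss <- ad_mean(tape, ad_mul(tape, diff, diff))
      lv <- ad_val(loss)[1L]
      if (!is.finite(lv)) {
        abort(sprintf(
          "non-finite training loss at epoch %d (batch of %d pairs); consider a lower learning rate.",
          epoch, length(bi)))
      }
      tr_loss_sum <- tr_loss_sum + lv * length(bi)
      ad_backward(tape, loss)
      grads <- flatten_params(collect_grads(P))
      flat <- adam_step(flat, grads, opt, lr = lr_vec)
      model$params <- unflatten_params(flat, model$params)
    }
    vtape <- ad_tape()
    val_pred <- as.vector(ad_val(dta_forward(vtape, model$params,
                                             model$states, cfg, val_struct,
                                             training = FALSE)))
    val_mse <- mean((val_pred - val$affinity)^2)
    history[[epoch]] <- tibble::tibble(epoch = epoch,
                                       train_mse = tr_loss_sum / n_tr,
                                       val_mse = val_mse)
    improved <- val_mse < es$best
    keep_going <- es$update(val_mse)
    if (improved) {
      best_flat <- flat
      best_states <- snapshot_states(model)
    }
    if (verbose) {
      message(sprintf("epoch %3d  train %.4f  val %.4f%s", epoch,
                      tr_loss_sum / n_tr, val_mse,
                      if (improved) " *" else ""))
    }
    if (!keep_going) break
  }
  model$params <- unflatten_params(best_flat, model$params)
  restore_states(model, best_states)
  structure(list(model = model,
                 history = dplyr::bind_rows(history),
                 best_epoch = es$best_epoch,
                 best_val = es$best),
            class = "dta_fit")
}

#' @export
print.dta_fit <- function(x, ...) {
  cat(sprintf("<dta_fit> %d epochs (best %d, val MSE %.4f)\n",
              nrow(x$history), x$best_epoch, x$best_val))
  invisible(x)
}

#' Evaluate a fitted model on a pair table
#'
#' @param fit A `dta_fit` (or `dta_model`).
#' @param pairs Interaction tibble with affinities.
#' @param cache Feature cache (or pass `proteins` / `drugs`).
#' @param proteins,drugs Entity records if no cache is given.
#' @return A list with the `predictions` tibble and one-row `metrics`
#'   tibble.
#' @export
dta_evaluate <- function(fit, pairs, cache = NULL, proteins = NULL,
                         drugs = NULL) {
  model <- if (inherits(fit, "dta_fit")) fit$model else fit
  preds <- predict_affinity(model, pairs, proteins, drugs, cache)
  list(predictions = structure(preds, class = c("dta_predictions",
                                                class(preds))),
       metrics = metric_report(preds$y_true, preds$y_pred))
}
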