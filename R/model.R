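# The full drug-target affinity model: two transformer sequence branches,
# two graph encoder branches sharing one architecture, gated fusion +
# attention-based distillation, and the KAN (or MLP) regression head.

#' Initialize a drug-target affinity model
#'
#' @param config A [model_config()].
#' @return A `dta_model` with parameter and state trees.
#' @export
dta_model <- function(config = model_config()) {
  stopifnot(inherits(config, "model_config"))
  s <- config$seed
  params <- list()
  states <- list()
  if (config$use_sequence) {
    params$prot_tf <- with_seed(hash_seed("prot-tf", s), init_transformer(
      config$protein_embed_dim, config$transformer_dim,
      config$transformer_layers, config$transformer_heads,
      config$transformer_ff_dim, config$protein_max_len))
    params$drug_tf <- with_seed(hash_seed("drug-tf", s), init_transformer(
      config$drug_embed_dim, config$transformer_dim,
      config$transformer_layers, config$transformer_heads,
      config$transformer_ff_dim, config$drug_max_len))
    if (config$use_linear_attention) {
      params$att_d <- with_seed(hash_seed("att-d", s), init_attention_pool(
        config$transformer_dim, config$attention_dim))
      params$att_t <- with_seed(hash_seed("att-t", s), init_attention_pool(
        config$transformer_dim, config$attention_dim))
      params$att_x <- with_seed(hash_seed("att-x", s), init_attention_pool(
        config$transformer_dim, config$attention_dim))
    } else {
      params$lin_x <- with_seed(hash_seed("lin-x", s), init_linear(
        2L * config$transformer_dim, config$transformer_dim))
    }
  }
  if (config$use_graph) {
    prot_in <- if (config$use_esmc_node_features) config$protein_embed_dim
               else length(AA_ALPHABET)
    params$prot_graph <- with_seed(hash_seed("prot-graph", s),
      init_graph_encoder(prot_in, config$protein_graph_hidden_dim,
                         config$graph_output_dim))
    params$drug_graph <- with_seed(hash_seed("drug-graph", s),
      init_graph_encoder(config$atom_feature_dim,
                         config$drug_graph_hidden_dim,
                         config$graph_output_dim))
    states$prot_graph <- graph_encoder_states(params$prot_graph)
    states$drug_graph <- graph_encoder_states(params$drug_graph)
    if (config$use_gated_fusion) {
      params$gate <- with_seed(hash_seed("gate", s),
                               init_gated_fusion(config$graph_output_dim))
    } else {
      params$lin_g <- with_seed(hash_seed("lin-g", s), init_linear(
        2L * config$graph_output_dim, config$graph_output_dim))
    }
  }
  params$head <- kan_block_params(
    c(joint_width(config), config$kan_hidden, 1L),
    grid_size = config$kan_grid_size, order = config$kan_order,
    seed = hash_seed("head", s), mlp = !config$use_kan)
  structure(list(config = config, params = params, states = states),
            class = "dta_model")
}

#' @export
print.dta_model <- function(x, ...) {
  np <- sum(vapply(flatten_params(x$params), length, integer(1)))
  cat(sprintf("<dta_model> %s head, %d trainable values\n",
              if (x$config$use_kan) "KAN" else "MLP", np))
  print(x$config)
  invisible(x)
}

# One-hot residue features (ablation for provider node features).
residue_onehot <- function(sequence) {
  chars <- strsplit(sequence, "")[[1]]
  m <- matrix(0, length(chars), length(AA_ALPHABET))
  m[cbind(seq_along(chars), match(chars, AA_ALPHABET))] <- 1
  m
}

# Precompute per-entity features: truncated records, graphs, token
# embedding matrices. Returns an environment reused across batches.
featurize_entities <- function(proteins, drugs, config,
                               graph_spec = contact_graph_spec()) {
  cache <- new.env(parent = emptyenv())
  res_cap <- config$protein_max_len -
    2L * any(vapply(proteins, function(p) p$has_special_tokens, logical(1)))
  cache$proteins <- lapply(proteins, function(p) {
    p <- truncate_protein(p, res_cap)
    nf <- if (config$use_esmc_node_features) NULL else residue_onehot(p$sequence)
    graph <- if (config$use_graph) {
      build_protein_graph(p, graph_spec, node_features = nf)
    } else NULL
    emb <- p$embeddings
    if (nrow(emb) > config$protein_max_len) {
      emb <- emb[seq_len(config$protein_max_len), , drop = FALSE]
    }
    list(graph = graph, emb = emb)
  })
  cache$drugs <- lapply(drugs, function(d) {
    graph <- if (config$use_graph) smiles_to_graph(d$smiles) else NULL
    emb <- d$embeddings
    if (nrow(emb) > config$drug_max_len) {
      emb <- emb[seq_len(config$drug_max_len), , drop = FALSE]
    }
    list(graph = graph, emb = emb)
  })
  cache
}

# Assemble constant batch structures for a set of pairs.
prepare_batch <- function(pairs, cache, config) {
  upid <- unique(pairs$protein_id)
  udid <- unique(pairs$drug_id)
  missing_p <- setdiff(upid, names(cache$proteins))
  missing_d <- setdiff(udid, names(cache$drugs))
  if (length(missing_p) || length(missing_d)) {
    abort(sprintf("unknown entity id(s): %s.",
                  paste(c(missing_p, missing_d), collapse = ", ")))
  }
  b <- list(
    pi = match(pairs$protein_id, upid),
    di = match(pairs$drug_id, udid),
    y = if ("affinity" %in% names(pairs)) matrix(pairs$affinity, ncol = 1L)
        else NULL,
    n = nrow(pairs)
  )
  if (config$use_sequence) {
    b$prot_rag <- build_ragged_batch(
      lapply(cache$proteins[upid], `[[`, "emb"), config$protein_max_len)
    b$drug_rag <- build_ragged_batch(
      lapply(cache$drugs[udid], `[[`, "emb"), config$drug_max_len)
  }
  if (config$use_graph) {
    b$prot_gb <- build_graph_batch(lapply(cache$proteins[upid], `[[`,
                                          "graph"))
    b$drug_gb <- build_graph_batch(lapply(cache$drugs[udid], `[[`, "graph"))
  }
  b
}

# Tape-level forward pass; P is the wrapped (or plain) parameter tree.
dta_forward <- function(tape, P, states, config, batch, training) {
  blocks <- list()
  if (config$use_graph) {
    Hp_ent <- ad_graph_encoder(tape, batch$prot_gb, P$prot_graph,
                               states$prot_graph, training, config$dropout)
    Hd_ent <- ad_graph_encoder(tape, batch$drug_gb, P$drug_graph,
                               states$drug_graph, training, config$dropout)
    Hp <- ad_rows(tape, Hp_ent, batch$pi)
    Hd <- ad_rows(tape, Hd_ent, batch$di)
    blocks$a_g <- if (config$use_gated_fusion) {
      ad_gated_fusion(tape, Hd, Hp, P$gate)
    } else {
      ad_linear(tape, ad_cbind_list(tape, list(Hd, Hp)), P$lin_g)
    }
  }
  if (config$use_sequence) {
    Ft <- ad_transformer(tape, batch$prot_rag, P$prot_tf, training,
                         config$dropout)
    Fs <- ad_transformer(tape, batch$drug_rag, P$drug_tf, training,
                         config$dropout)
    if (config$use_linear_attention) {
      At_ent <- ad_attention_pool(tape, Ft, batch$prot_rag$seq,
                                  batch$prot_rag$n_seq, P$att_t)
      Ad_ent <- ad_attention_pool(tape, Fs, batch$drug_rag$seq,
                                  batch$drug_rag$n_seq, P$att_d)
    } else {
      At_ent <- ad_masked_mean(tape, Ft, batch$prot_rag)
      Ad_ent <- ad_masked_mean(tape, Fs, batch$drug_rag)
    }
    At <- ad_rows(tape, At_ent, batch$pi)
    Ad <- ad_rows(tape, Ad_ent, batch$di)
    blocks$a_d <- Ad
    blocks$a_t <- At
    blocks$a_dt <- if (config$use_linear_attention) {
      ad_cross_attention(tape, Ad, At, P$att_x)
    } else {
      ad_linear(tape, ad_cbind_list(tape, list(Ad, At)), P$lin_x)
    }
  }
  Z <- ad_cbind_list(tape, unname(blocks))
  ad_kan_block(tape, Z, P$head, training)
}

# Evaluation-mode predictions for arbitrary pairs.
predict_pairs <- function(model, pairs, cache, batch_size = 256L) {
  preds <- numeric(nrow(pairs))
  idx <- seq_len(nrow(pairs))
  for (chunk in split(idx, ceiling(idx / batch_size))) {
    b <- prepare_batch(pairs[chunk, , drop = FALSE], cache, model$config)
    tape <- ad_tape()
    yhat <- dta_forward(tape, model$params, model$states, model$config, b,
                        training = FALSE)
    preds[chunk] <- as.vector(ad_val(yhat))
  }
  preds
}

#' Predict affinities for drug-protein pairs
#'
#' @param model A `dta_model` (typically the `$model` of a [dta_train()]
#'   fit).
#' @param pairs Tibble with `drug_id` and `protein_id` (an `affinity`
#'   column, if present, is carried through as `y_true`).
#' @param proteins,drugs Named lists of [protein_record()] /
#'   [drug_record()] covering all ids in `pairs`.
#' @param cache Optional precomputed feature cache (overrides
#'   `proteins` / `drugs`).
#' @return `pairs` with columns `y_true` (or `NA`) and `y_pred`.
#' @export
predict_affinity <- function(model, pairs, proteins = NULL, drugs = NULL,
                             cache = NULL) {
  stopifnot(inherits(model, "dta_model"))
  if (is.null(cache)) {
    cache <- featurize_entities(proteins, drugs, model$config)
  }
  y_pred <- predict_pairs(model, pairs, cache)
  tibble::tibble(
    drug_id = pairs$drug_id, protein_id = pairs$protein_id,
    y_true = if ("affinity" %in% names(pairs)) pairs$affinity else NA_real_,
    y_pred = y_pred)
}

# Deep-copy all mutable normalization state (batch-norm running moments,
# KAN input ranges) so an early-stopping snapshot can be restored later.
snapshot_states <- function(model) {
  list(states = states_to_list(model$states),
       kan = lapply(model$params$head$states, as.list))
}

restore_states <- function(model, snap) {
  write_env <- function(e, l) {
    for (nm in names(l)) assign(nm, l[[nm]], envir = e)
  }
  walk <- function(tree, vals) {
    if (is.environment(tree)) return(write_env(tree, vals))
    if (is.list(tree)) for (nm in seq_along(tree)) walk(tree[[nm]],
                                                        vals[[nm]])
    invisible(NULL)
  }
  walk(model$states, snap$states)
  for (i in seq_along(model$params$head$states)) {
    write_env(model$params$head$states[[i]], snap$kan[[i]])
  }
  invisible(model)
}

# --- checkpoint serialization ----------------------------------------------

states_to_list <- function(x) {
  if (is.environment(x)) return(as.list(x))
  if (is.list(x)) return(lapply(x, states_to_list))
  x
}

states_from_list <- function(x) {
  if (is.list(x) && !is.null(names(x)) &&
      all(c("mean", "var") %in% names(x) | c("mn", "mx") %in% names(x))) {
    e <- new.env(parent = emptyenv())
    for (nm in names(x)) assign(nm, x[[nm]], envir = e)
    return(e)
  }
  if (is.list(x)) return(lapply(x, states_from_list))
  x
}

#' Save a model checkpoint
#'
#' Serializes configuration, parameters and running statistics (batch
#' norm, KAN input ranges) to an RDS file.
#'
#' @param model A `dta_model`.
#' @param path Output file path.
#' @export
save_checkpoint <- function(model, path) {
  head <- model$params$head
  head$states <- lapply(head$states, as.list)
  obj <- list(format = "dtakan-checkpoint-1",
              config = unclass(model$config),
              params = model$params[setdiff(names(model$params), "head")],
              head = unclass(head),
              states = states_to_list(model$states))
  saveRDS(obj, path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path Checkpoint file from [save_checkpoint()].
#' @return A `dta_model`.
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "dtakan-checkpoint-1")) {
    abort(sprintf("%s is not a dtakan checkpoint.", path))
  }
  head <- obj$head
  head$states <- lapply(head$states, function(s) {
    e <- new.env(parent = emptyenv())
    for (nm in names(s)) assign(nm, s[[nm]], envir = e)
    e
  })
  class(head) <- "kan_block_params"
  params <- obj$params
  params$head <- head
  structure(list(config = structure(obj$config, class = "model_config"),
                 params = params,
                 states = states_from_list(obj$states)),
            class = "dta_model")
}
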