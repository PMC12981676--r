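# User-facing encoder operations. These wrap the tape-level builders in
# evaluation mode on plain matrices; the training pipeline drives the same
# builders directly with gradients.

#' Parameters for a single graph-convolution layer
#'
#' @param input_dim,output_dim Layer widths.
#' @param seed Integer seed.
#' @return Parameter list (weight, bias, batch-norm gain/shift and
#'   running statistics).
#' @export
gcn_layer_params <- function(input_dim, output_dim, seed = 1L) {
  with_seed(seed, {
    list(gcn = init_linear(input_dim, output_dim),
         bn0 = init_norm(output_dim), state = bn_state(output_dim))
  })
}

#' Weighted graph convolution layer
#'
#' Symmetric-normalized weighted propagation
#' `h'_i = sum_j (w_ij / sqrt(d_i d_j)) W h_j` with a unit self-loop added
#' to every node, followed by batch normalization and ReLU.
#'
#' @param graph A [weighted_graph()].
#' @param params From [gcn_layer_params()].
#' @param training Use batch statistics (and update the running ones)
#'   instead of the stored running statistics.
#' @return The transformed node-feature matrix.
#' @export
gcn_layer <- function(graph, params, training = FALSE) {
  stopifnot(inherits(graph, "weighted_graph"))
  n <- nrow(graph$node_features)
  A <- gcn_norm_matrix(n, graph$edges[, 1L] + 1L, graph$edges[, 2L] + 1L,
                       graph$edge_weights)
  tape <- ad_tape()
  gb <- list(X = graph$node_features, Anorm = A)
  ad_val(ad_gcn_layer(tape, gb$X, gb, params, params$state, training))
}

#' Parameters for a single graph-attention layer
#'
#' @param dim Node feature width (input and output).
#' @param seed Integer seed.
#' @return Parameter list (weight, the two attention vectors, batch norm).
#' @export
gat_layer_params <- function(dim, seed = 1L) {
  with_seed(seed, {
    list(W = glorot(dim, dim), a_src = glorot(dim, 1L),
         a_dst = glorot(dim, 1L), bn = init_norm(dim),
         state = bn_state(dim))
  })
}

#' Graph attention layer
#'
#' Single-head additive attention over each node's neighborhood plus the
#' node itself: `e_ij = LeakyReLU(a^T [W h_i || W h_j])`, softmax over
#' `j`, weighted sum of `W h_j`, then batch normalization and ReLU. Edge
#' weights are not used.
#'
#' @param h Node-feature matrix.
#' @param edges Integer edge matrix (two columns, 0-based, directed).
#' @param params From [gat_layer_params()].
#' @param training Batch-statistics mode as in [gcn_layer()].
#' @param return_attention Also return the per-edge attention
#'   coefficients (including self-loops).
#' @return Transformed node matrix, or a list with `output`, `edges` and
#'   `alpha` when `return_attention = TRUE`.
#' @export
gat_layer <- function(h, edges, params, training = FALSE,
                      return_attention = FALSE) {
  h <- as_matrix2d(h, "h")
  if (is.null(dim(edges))) edges <- matrix(as.integer(edges), ncol = 2L)
  n <- nrow(h)
  gb <- list(att_src = c(edges[, 1L] + 1L, seq_len(n)),
             att_dst = c(edges[, 2L] + 1L, seq_len(n)),
             n_nodes = n)
  tape <- ad_tape()
  if (!return_attention) {
    return(ad_val(ad_gat_layer(tape, h, gb, params, params$state, training)))
  }
  Wh <- ad_val(ad_matmul(tape, h, params$W))
  s1 <- Wh %*% ad_val(params$a_src)
  s2 <- Wh %*% ad_val(params$a_dst)
  se <- s1[gb$att_src] + s2[gb$att_dst]
  e <- ifelse(se > 0, se, 0.2 * se)
  alpha <- ad_val(ad_group_softmax(tape, matrix(e, ncol = 1L), gb$att_src,
                                   n))
  out <- ad_val(ad_gat_layer(tape, h, gb, params, params$state, training))
  list(output = out, edges = cbind(gb$att_src - 1L, gb$att_dst - 1L),
       alpha = as.vector(alpha))
}

#' Parameters for the shared graph encoder
#'
#' One weighted GCN layer, `n_gat_layers` GAT layers with batch
#' normalization, global add pooling, dropout and a 2-layer MLP; the same
#' architecture serves protein and drug graphs.
#'
#' @param input_dim Node feature width (1152 for residue embeddings, 88
#'   for atom features).
#' @param hidden_dim,output_dim Hidden and output widths.
#' @param n_gat_layers Number of attention layers (default 5).
#' @param seed Integer seed.
#' @return A parameter list with attached batch-norm states.
#' @export
graph_encoder_params <- function(input_dim, hidden_dim = 256L,
                                 output_dim = 128L, n_gat_layers = 5L,
                                 seed = 1L) {
  P <- with_seed(seed, init_graph_encoder(input_dim, hidden_dim, output_dim,
                                          n_gat_layers))
  P$states <- graph_encoder_states(P)
  P
}

#' Encode a graph into a fixed-width vector
#'
#' @param graph A [weighted_graph()] (or list of graphs, encoded as one
#'   batch).
#' @param params From [graph_encoder_params()].
#' @param training Batch-statistics/dropout mode.
#' @param dropout Dropout probability before the MLP when training.
#' @return A vector of length `output_dim` (or a matrix with one row per
#'   graph).
#' @export
graph_encode <- function(graph, params, training = FALSE, dropout = 0) {
  single <- inherits(graph, "weighted_graph")
  graphs <- if (single) list(graph) else graph
  for (g in graphs) {
    if (nrow(g$node_features) < 1L) abort("cannot encode an empty graph.")
  }
  gb <- build_graph_batch(graphs)
  tape <- ad_tape()
  out <- ad_val(ad_graph_encoder(tape, gb, params, params$states, training,
                                 dropout))
  if (single) as.vector(out) else out
}

#' Parameters for the transformer sequence encoder
#'
#' @param provider_dim Width of the provider token embeddings.
#' @param model_dim,n_layers,n_heads,ff_dim Transformer settings.
#' @param max_len Positional-embedding table length (token cap).
#' @param seed Integer seed.
#' @return A parameter list.
#' @export
transformer_params <- function(provider_dim, model_dim = 128L, n_layers = 3L,
                               n_heads = 8L, ff_dim = 128L, max_len = 1200L,
                               seed = 1L) {
  with_seed(seed, init_transformer(provider_dim, model_dim, n_layers,
                                   n_heads, ff_dim, max_len))
}

#' Transformer encoding of provider token embeddings
#'
#' Projects tokens to the model width, adds learned positional
#' embeddings, and applies pre-norm encoder layers (multi-head
#' self-attention plus feed-forward). Accepts a single embedding matrix
#' or a padded batch from [pad_protein_batch()] / [pad_drug_batch()];
#' padded positions take no part in attention and are returned as zero
#' rows.
#'
#' @param embeddings Token matrix, list of token matrices, or a padded
#'   batch list with `embeddings` and `mask`.
#' @param mask Optional logical matrix marking real tokens (for 3-D array
#'   input).
#' @param params From [transformer_params()].
#' @param training Dropout mode.
#' @param dropout Dropout probability.
#' @return A list with `tokens` (list of per-sequence token matrices,
#'   real tokens only) and `pooled` (masked-mean summary, one row per
#'   sequence).
#' @export
transformer_encode <- function(embeddings, mask = NULL, params,
                               training = FALSE, dropout = 0) {
  emb_list <- NULL
  if (is.list(embeddings) && !is.null(embeddings$embeddings)) {
    mask <- embeddings$mask
    embeddings <- embeddings$embeddings
  }
  if (is.array(embeddings) && length(dim(embeddings)) == 3L) {
    if (is.null(mask)) abort("3-D embedding input requires a `mask`.")
    emb_list <- lapply(seq_len(dim(embeddings)[1L]), function(i) {
      keep <- which(mask[i, ])
      if (length(keep) == 0L) {
        abort(sprintf("sequence %d is entirely padding.", i))
      }
      matrix(embeddings[i, keep, ], nrow = length(keep))
    })
  } else if (is.list(embeddings)) {
    emb_list <- lapply(embeddings, as_matrix2d, what = "embeddings")
  } else {
    emb_list <- list(as_matrix2d(embeddings, "embeddings"))
  }
  widths <- vapply(emb_list, ncol, integer(1))
  if (any(widths != params$meta$provider_dim)) {
    abort(sprintf("embedding width %d does not match provider_dim %d.",
                  widths[1L], params$meta$provider_dim))
  }
  rs <- build_ragged_batch(emb_list, params$meta$max_len)
  tape <- ad_tape()
  toks <- ad_transformer(tape, rs, params, training, dropout)
  pooled <- ad_val(ad_masked_mean(tape, toks, rs))
  tv <- ad_val(toks)
  ends <- cumsum(rs$lens)
  starts <- ends - rs$lens + 1L
  tokens <- lapply(seq_along(rs$lens), function(i) {
    tv[starts[i]:ends[i], , drop = FALSE]
  })
  list(tokens = tokens, pooled = pooled)
}
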