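# Parameter containers, initializers, the Adam optimizer, and tape-level
# forward builders for the encoder stacks. Parameters live in nested named
# lists whose trainable leaves are double matrices (biases are 1 x k);
# metadata (grids, dims) are kept as plain vectors/scalars so the
# flatten/wrap walkers skip them.

glorot <- function(fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
}

init_linear <- function(in_dim, out_dim) {
  list(W = glorot(in_dim, out_dim), b = matrix(0, 1L, out_dim))
}

init_norm <- function(d) {
  list(gamma = matrix(1, 1L, d), beta = matrix(0, 1L, d))
}

bn_state <- function(d) {
  st <- new.env(parent = emptyenv())
  st$mean <- rep(0, d)
  st$var <- rep(1, d)
  st
}

is_param_leaf <- function(x) is.matrix(x) && is.double(x)

flatten_params <- function(x, prefix = "") {
  if (is_param_leaf(x) || is_ad(x)) {
    out <- list(x)
    names(out) <- prefix
    return(out)
  }
  if (is.list(x)) {
    nm <- names(x) %||% as.character(seq_along(x))
    nm[nm == ""] <- as.character(which(nm == ""))
    out <- list()
    for (i in seq_along(x)) {
      child <- flatten_params(x[[i]], paste0(prefix, ".", nm[i]))
      out <- c(out, child)
    }
    return(out)
  }
  list()
}

# Replace trainable leaves (in flatten order) by the values in `flat`.
unflatten_params <- function(flat, skeleton) {
  i <- 0L
  walk <- function(x) {
    if (is_param_leaf(x)) {
      i <<- i + 1L
      return(flat[[i]])
    }
    if (is.list(x)) {
      for (k in seq_along(x)) x[[k]] <- walk(x[[k]])
      return(x)
    }
    x
  }
  walk(skeleton)
}

# Same structure with trainable leaves replaced by tape leaf nodes.
wrap_params <- function(tape, x) {
  if (is_param_leaf(x)) return(ad_leaf(tape, x))
  if (is.list(x)) {
    for (k in seq_along(x)) x[[k]] <- wrap_params(tape, x[[k]])
    return(x)
  }
  x
}

# Gradients in the same nested structure (zeros where unused).
collect_grads <- function(x) {
  if (is_ad(x)) {
    g <- x$grad
    if (is.null(g)) g <- array(0, dim = dim(x$value))
    return(g)
  }
  if (is.list(x)) {
    for (k in seq_along(x)) x[[k]] <- collect_grads(x[[k]])
    return(x)
  }
  x
}

adam_state <- function(flat) {
  st <- new.env(parent = emptyenv())
  st$m <- lapply(flat, function(p) array(0, dim = dim(p)))
  st$v <- lapply(flat, function(p) array(0, dim = dim(p)))
  st$t <- 0L
  st
}

# `lr` may be a scalar or a per-tensor vector (differential learning
# rates for encoder vs readout parameters).
adam_step <- function(flat, gflat, st, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (i in seq_along(flat)) {
    g <- gflat[[i]]
    st$m[[i]] <- beta1 * st$m[[i]] + (1 - beta1) * g
    st$v[[i]] <- beta2 * st$v[[i]] + (1 - beta2) * g * g
    mh <- st$m[[i]] / bc1
    vh <- st$v[[i]] / bc2
    lri <- if (length(lr) > 1L) lr[i] else lr
    flat[[i]] <- flat[[i]] - lri * mh / (sqrt(vh) + eps)
  }
  flat
}

ad_linear <- function(tape, x, p) {
  ad_add_bias(tape, ad_matmul(tape, x, p$W), p$b)
}

# --- transformer sequence encoder -------------------------------------------

init_transformer <- function(provider_dim, d_model, n_layers, n_heads,
                             ff_dim, max_len) {
  stopifnot(d_model %% n_heads == 0L)
  layers <- lapply(seq_len(n_layers), function(i) {
    list(
      ln1 = init_norm(d_model),
      q = init_linear(d_model, d_model),
      k = init_linear(d_model, d_model),
      v = init_linear(d_model, d_model),
      o = init_linear(d_model, d_model),
      ln2 = init_norm(d_model),
      ff1 = init_linear(d_model, ff_dim),
      ff2 = init_linear(ff_dim, d_model)
    )
  })
  list(
    W_x = glorot(provider_dim, d_model),
    pos = matrix(rnorm(max_len * d_model, sd = 0.02), max_len, d_model),
    layers = layers,
    ln_f = init_norm(d_model),
    meta = list(d_model = d_model, n_heads = n_heads, max_len = max_len,
                provider_dim = provider_dim)
  )
}

# Ragged token batch: sequences stacked row-wise with bookkeeping vectors.
# All-pairs attention edges are built within each sequence only, so padding
# tokens simply never exist inside the encoder.
build_ragged_batch <- function(emb_list, cap) {
  emb_list <- lapply(emb_list, function(e) {
    if (nrow(e) > cap) e[seq_len(cap), , drop = FALSE] else e
  })
  lens <- vapply(emb_list, nrow, integer(1))
  offs <- cumsum(c(0L, lens[-length(lens)]))
  src <- integer(0); dst <- integer(0)
  for (i in seq_along(lens)) {
    idx <- offs[i] + seq_len(lens[i])
    src <- c(src, rep(idx, each = lens[i]))
    dst <- c(dst, rep(idx, times = lens[i]))
  }
  list(
    tok = do.call(rbind, emb_list),
    seq = rep(seq_along(lens), lens),
    pos = unlist(lapply(lens, seq_len), use.names = FALSE),
    src = src,
    dst = dst,
    lens = lens,
    n_seq = length(lens)
  )
}

# Pre-norm transformer encoder over a ragged batch; returns the token node.
ad_transformer <- function(tape, rs, P, training, dropout = 0) {
  meta <- P$meta
  d <- meta$d_model
  H <- meta$n_heads
  hd <- d %/% H
  ntok <- nrow(rs$tok)

  x <- ad_matmul(tape, rs$tok, P$W_x)
  x <- ad_add(tape, x, ad_rows(tape, P$pos, rs$pos))
  for (ly in P$layers) {
    xn <- ad_layernorm(tape, x, ly$ln1$gamma, ly$ln1$beta)
    Q <- ad_linear(tape, xn, ly$q)
    K <- ad_linear(tape, xn, ly$k)
    V <- ad_linear(tape, xn, ly$v)
    scores <- ad_edge_scores(tape, Q, K, rs$src, rs$dst, H, 1 / sqrt(hd))
    alpha <- ad_group_softmax(tape, scores, rs$src, ntok)
    O <- ad_attn_out(tape, alpha, V, rs$dst, rs$src, ntok)
    att <- ad_dropout(tape, ad_linear(tape, O, ly$o), dropout, training)
    x <- ad_add(tape, x, att)
    xn2 <- ad_layernorm(tape, x, ly$ln2$gamma, ly$ln2$beta)
    h <- ad_relu(tape, ad_linear(tape, xn2, ly$ff1))
    h <- ad_dropout(tape, ad_linear(tape, h, ly$ff2), dropout, training)
    x <- ad_add(tape, x, h)
  }
  ad_layernorm(tape, x, P$ln_f$gamma, P$ln_f$beta)
}

# Masked mean over each sequence of a ragged token node.
ad_masked_mean <- function(tape, toks, rs) {
  pooled <- ad_scatter_rows(tape, toks, rs$seq, rs$n_seq)
  w <- matrix(1 / rs$lens, rs$n_seq, ncol(ad_val(toks)))
  ad_mul(tape, pooled, w)
}

# --- graph encoder (1 GCN + 5 GAT + add-pool + MLP) -------------------------

init_graph_encoder <- function(input_dim, hidden_dim, output_dim,
                               n_gat_layers = 5L) {
  # global add pooling sums tens of nonnegative post-BN/ReLU node vectors,
  # so the pooled input to the MLP carries a large common offset; the MLP
  # weights start small so downstream sigmoid gates open in their linear
  # range instead of saturating at initialization
  mlp1 <- init_linear(hidden_dim, hidden_dim)
  mlp1$W <- 0.2 * mlp1$W
  mlp2 <- init_linear(hidden_dim, output_dim)
  mlp2$W <- 0.2 * mlp2$W
  list(
    gcn = init_linear(input_dim, hidden_dim),
    bn0 = init_norm(hidden_dim),
    gat = lapply(seq_len(n_gat_layers), function(i) {
      list(W = glorot(hidden_dim, hidden_dim),
           a_src = glorot(hidden_dim, 1L),
           a_dst = glorot(hidden_dim, 1L),
           bn = init_norm(hidden_dim))
    }),
    mlp1 = mlp1,
    mlp2 = mlp2,
    meta = list(input_dim = input_dim, hidden_dim = hidden_dim,
                output_dim = output_dim, n_gat_layers = n_gat_layers)
  )
}

# Symmetric-normalized weighted adjacency with unit self-loops, as a sparse
# constant: A_hat = D^{-1/2} (W + I) D^{-1/2}, d_i = sum_j w_hat_ij.
gcn_norm_matrix <- function(n_nodes, src, dst, weights) {
  i <- c(src, seq_len(n_nodes))
  j <- c(dst, seq_len(n_nodes))
  w <- c(weights, rep(1, n_nodes))
  A <- Matrix::sparseMatrix(i = i, j = j, x = w, dims = c(n_nodes, n_nodes))
  d <- Matrix::rowSums(A)
  dis <- 1 / sqrt(pmax(d, 1e-12))
  Matrix::Diagonal(x = dis) %*% A %*% Matrix::Diagonal(x = dis)
}

# Batch of graphs merged into one block-diagonal graph. GAT edges include a
# self-loop per node so every node attends at least to itself.
build_graph_batch <- function(graphs) {
  ns <- vapply(graphs, function(g) nrow(g$node_features), integer(1))
  offs <- cumsum(c(0L, ns[-length(ns)]))
  src <- integer(0); dst <- integer(0); w <- numeric(0)
  for (i in seq_along(graphs)) {
    e <- graphs[[i]]$edges
    if (nrow(e) > 0L) {
      src <- c(src, e[, 1L] + 1L + offs[i])
      dst <- c(dst, e[, 2L] + 1L + offs[i])
      w <- c(w, graphs[[i]]$edge_weights)
    }
  }
  n <- sum(ns)
  loops <- seq_len(n)
  list(
    X = do.call(rbind, lapply(graphs, function(g) g$node_features)),
    Anorm = gcn_norm_matrix(n, src, dst, w),
    att_src = c(src, loops),
    att_dst = c(dst, loops),
    gid = rep(seq_along(ns), ns),
    n_nodes = n,
    n_graphs = length(graphs)
  )
}

ad_gat_layer <- function(tape, h, gb, ly, state, training, slope = 0.2) {
  Wh <- ad_matmul(tape, h, ly$W)
  s1 <- ad_matmul(tape, Wh, ly$a_src)
  s2 <- ad_matmul(tape, Wh, ly$a_dst)
  se <- ad_add(tape, ad_rows(tape, s1, gb$att_src),
               ad_rows(tape, s2, gb$att_dst))
  e <- ad_leakyrelu(tape, se, slope)
  alpha <- ad_group_softmax(tape, e, gb$att_src, gb$n_nodes)
  agg <- ad_attn_out(tape, alpha, Wh, gb$att_dst, gb$att_src, gb$n_nodes)
  out <- ad_batchnorm(tape, agg, ly$bn$gamma, ly$bn$beta, state, training)
  ad_relu(tape, out)
}

ad_gcn_layer <- function(tape, X, gb, p, state, training) {
  # A (X W) rather than (A X) W: identical result, and the sparse product
  # then runs at the hidden width instead of the provider width
  h <- ad_spmm(tape, gb$Anorm, ad_matmul(tape, X, p$gcn$W))
  h <- ad_add_bias(tape, h, p$gcn$b)
  h <- ad_batchnorm(tape, h, p$bn0$gamma, p$bn0$beta, state, training)
  ad_relu(tape, h)
}

# Full graph encoder over a batched graph: returns n_graphs x output_dim.
ad_graph_encoder <- function(tape, gb, P, states, training, dropout = 0) {
  h <- ad_gcn_layer(tape, gb$X, gb, P, states$bn0, training)
  for (i in seq_along(P$gat)) {
    h <- ad_gat_layer(tape, h, gb, P$gat[[i]], states$gat[[i]], training)
  }
  pooled <- ad_scatter_rows(tape, h, gb$gid, gb$n_graphs)
  pooled <- ad_dropout(tape, pooled, dropout, training)
  h <- ad_relu(tape, ad_linear(tape, pooled, P$mlp1))
  ad_linear(tape, h, P$mlp2)
}

graph_encoder_states <- function(P) {
  list(
    bn0 = bn_state(P$meta$hidden_dim),
    gat = lapply(P$gat, function(x) bn_state(P$meta$hidden_dim))
  )
}

# --- fusion blocks ----------------------------------------------------------

init_attention_pool <- function(dim, att_dim = 64L) {
  list(W = glorot(dim, att_dim), v = glorot(att_dim, 1L))
}

# Additive (tanh-scorer) attention pooling over a ragged token node.
ad_attention_pool <- function(tape, toks, group, ngroups, p) {
  s <- ad_matmul(tape, ad_tanh(tape, ad_matmul(tape, toks, p$W)), p$v)
  alpha <- ad_group_softmax(tape, s, group, ngroups)
  ad_attn_out(tape, alpha, toks, seq_len(nrow(ad_val(toks))), group,
              ngroups)
}

init_gated_fusion <- function(dim) {
  list(W_g = glorot(2L * dim, dim))
}

# Elementwise convex combination with a learned sigmoid gate (no bias, the
# gate weight is the only learnable piece).
ad_gated_fusion <- function(tape, H_d, H_p, p) {
  g <- ad_sigmoid(tape, ad_matmul(tape, ad_cbind_list(tape, list(H_d, H_p)),
                                  p$W_g))
  one_minus <- ad_sub(tape, array(1, dim = dim(ad_val(g))), g)
  ad_add(tape, ad_mul(tape, g, H_d), ad_mul(tape, one_minus, H_p))
}

# Cross-modal attention: stack the two pooled vectors as a 2-token sequence
# per pair and reuse the additive attention pooling operator.
ad_cross_attention <- function(tape, A_d, A_t, p) {
  B <- nrow(ad_val(A_d))
  stacked <- ad_rbind_list(tape, list(A_d, A_t))
  group <- rep(seq_len(B), 2L)
  ad_attention_pool(tape, stacked, group, B, p)
}
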