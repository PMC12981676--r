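# Adaptive feature learning: gated fusion of the two graph-level vectors,
# additive ("linear") attention pooling of sequence features, cross-modal
# attention over the two pooled vectors, and assembly of the joint vector.

#' Parameters for gated fusion
#'
#' @param dim Width of each input vector.
#' @param seed Integer seed.
#' @return List with the gate weight `W_g` of shape `(2 * dim) x dim`.
#' @export
gated_fusion_params <- function(dim, seed = 1L) {
  with_seed(seed, init_gated_fusion(dim))
}

#' Gated fusion of drug and protein graph embeddings
#'
#' `A_g = g * H_d + (1 - g) * H_p` with gate
#' `g = sigmoid(W_g [H_d; H_p])`: an elementwise convex combination, so
#' every output coordinate lies between the corresponding inputs.
#'
#' @param h_d,h_p Vectors (or matrices of row vectors) of equal width.
#' @param params From [gated_fusion_params()].
#' @return The fused vector (or matrix).
#' @export
gated_fusion <- function(h_d, h_p, params) {
  vec_in <- is.null(dim(h_d))
  if (vec_in) { h_d <- matrix(h_d, 1L); h_p <- matrix(h_p, 1L) }
  if (!all(dim(h_d) == dim(h_p))) {
    abort(sprintf("width mismatch: %d vs %d.", ncol(h_d), ncol(h_p)))
  }
  if (nrow(params$W_g) != 2L * ncol(h_d)) {
    abort(sprintf("gate expects inputs of width %d, got %d.",
                  nrow(params$W_g) / 2L, ncol(h_d)))
  }
  tape <- ad_tape()
  out <- ad_val(ad_gated_fusion(tape, h_d, h_p, params))
  if (vec_in) as.vector(out) else out
}

#' Parameters for additive attention pooling
#'
#' @param dim Token feature width.
#' @param att_dim Scorer width (default 64).
#' @param seed Integer seed.
#' @return List with scorer weight `W` and scorer vector `v`.
#' @export
attention_pool_params <- function(dim, att_dim = 64L, seed = 1L) {
  with_seed(seed, init_attention_pool(dim, att_dim))
}

#' Additive attention pooling of a token sequence
#'
#' Scores each unmasked token as `s_i = v^T tanh(W f_i)`, softmaxes over
#' the sequence and returns the attention-weighted sum: a fixed-width
#' distillation of a variable-length sequence.
#'
#' @param f Token matrix (`L x dim`).
#' @param mask Optional logical vector of real-token flags (default all
#'   true).
#' @param params From [attention_pool_params()].
#' @param return_weights Also return the attention weights.
#' @return Pooled vector of width `dim` (or a list with `pooled` and
#'   `weights`).
#' @export
linear_attention_pool <- function(f, mask = NULL, params,
                                  return_weights = FALSE) {
  f <- as_matrix2d(f, "f")
  if (is.null(mask)) mask <- rep(TRUE, nrow(f))
  if (!any(mask)) abort("all tokens are masked.")
  fm <- f[mask, , drop = FALSE]
  tape <- ad_tape()
  pooled <- ad_val(ad_attention_pool(tape, fm, rep(1L, nrow(fm)), 1L,
                                     params))
  if (!return_weights) return(as.vector(pooled))
  s <- as.vector(tanh(fm %*% ad_val(params$W)) %*% ad_val(params$v))
  a <- exp(s - max(s)); a <- a / sum(a)
  w <- numeric(nrow(f)); w[mask] <- a
  list(pooled = as.vector(pooled), weights = w)
}

#' Cross-modal attention over two pooled vectors
#'
#' Stacks the drug and protein sequence summaries as a 2-token sequence
#' and applies the same additive attention pooling operator (with its own
#' parameters), yielding a convex combination of the two vectors.
#'
#' @param a_d,a_t Vectors (or row-vector matrices) of equal width.
#' @param params From [attention_pool_params()].
#' @return The cross-attended vector (or matrix).
#' @export
cross_attention <- function(a_d, a_t, params) {
  vec_in <- is.null(dim(a_d))
  if (vec_in) { a_d <- matrix(a_d, 1L); a_t <- matrix(a_t, 1L) }
  if (!all(dim(a_d) == dim(a_t))) {
    abort(sprintf("width mismatch: %d vs %d.", ncol(a_d), ncol(a_t)))
  }
  tape <- ad_tape()
  out <- ad_val(ad_cross_attention(tape, a_d, a_t, params))
  if (vec_in) as.vector(out) else out
}

#' Assemble the joint representation
#'
#' Concatenates the available blocks in the fixed order
#' `(A_g, A_d, A_t, A_dt)`; ablations pass `NULL` for removed blocks
#' (`use_graph = FALSE` drops `A_g`; `use_sequence = FALSE` drops the
#' three sequence blocks). At least one block must remain.
#'
#' @param a_g Fused graph vector or `NULL`.
#' @param a_d,a_t,a_dt Sequence attention vectors or `NULL`.
#' @return The concatenated joint vector (or matrix for row-vector
#'   input).
#' @export
assemble_joint <- function(a_g, a_d = NULL, a_t = NULL, a_dt = NULL) {
  blocks <- list(a_g = a_g, a_d = a_d, a_t = a_t, a_dt = a_dt)
  blocks <- blocks[!vapply(blocks, is.null, logical(1))]
  if (length(blocks) == 0L) {
    abort("all blocks are absent: the joint vector would be empty.")
  }
  vec_in <- is.null(dim(blocks[[1L]]))
  mats <- lapply(blocks, function(b) if (is.null(dim(b))) matrix(b, 1L) else b)
  ns <- unique(vapply(mats, nrow, integer(1)))
  if (length(ns) != 1L) abort("blocks disagree on the number of rows.")
  out <- do.call(cbind, mats)
  if (vec_in) as.vector(out) else out
}
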