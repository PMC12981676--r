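# Residue-level protein graph construction from contact-probability maps.

#' Contact-graph construction settings
#'
#' @param threshold Contact probability above which (strictly) an edge is
#'   created; default 0.5.
#' @param symmetrize Average the matrix with its transpose before
#'   thresholding (resolves asymmetric predictions).
#' @param include_self_loops Keep diagonal entries as self-loop edges
#'   (default `FALSE`; graph-convolution normalization adds its own
#'   self-loops).
#' @return A `contact_graph_spec` list.
#' @export
contact_graph_spec <- function(threshold = 0.5, symmetrize = TRUE,
                               include_self_loops = FALSE) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 1) {
    abort("`threshold` must be a single number in (0, 1).")
  }
  structure(list(threshold = threshold, symmetrize = isTRUE(symmetrize),
                 include_self_loops = isTRUE(include_self_loops)),
            class = "contact_graph_spec")
}

#' Drop special start/end token rows from an embedding matrix
#'
#' Providers that emit start and end special tokens produce `n` rows for
#' `n - 2` residues; the graph nodes are residues, so rows `2..(n-1)`
#' (1-based) are kept. Unflagged matrices pass through unchanged.
#'
#' @param embeddings Token-embedding matrix.
#' @param has_special_tokens Whether the first and last rows are special
#'   tokens.
#' @return The residue-level embedding matrix.
#' @export
trim_special_tokens <- function(embeddings, has_special_tokens) {
  embeddings <- as_matrix2d(embeddings, "embeddings")
  if (!has_special_tokens) return(embeddings)
  if (nrow(embeddings) < 3L) {
    abort(sprintf(
      "embeddings flagged with special tokens need >= 3 rows, got %d.",
      nrow(embeddings)))
  }
  embeddings[2L:(nrow(embeddings) - 1L), , drop = FALSE]
}

#' Build the weighted residue graph of a protein
#'
#' Node features are the (special-token-trimmed) residue embeddings; an
#' edge `(i, j)` (both directions) is created for every residue pair whose
#' symmetrized contact probability strictly exceeds the threshold, with
#' that probability as edge weight. A token-indexed contact matrix (side
#' equal to the token count) has the same trimming window applied to both
#' axes.
#'
#' @param record A [protein_record()] carrying embeddings and a contact
#'   matrix.
#' @param spec A [contact_graph_spec()].
#' @param node_features Optional replacement node-feature matrix (one row
#'   per residue), used by the no-residue-embedding ablation.
#' @return A [weighted_graph()].
#' @export
build_protein_graph <- function(record, spec = contact_graph_spec(),
                                node_features = NULL) {
  stopifnot(inherits(record, "protein_record"),
            inherits(spec, "contact_graph_spec"))
  if (is.null(record$contact)) {
    abort(sprintf("protein '%s' has no contact matrix.", record$protein_id))
  }
  M <- record$contact
  if (nrow(M) != ncol(M)) {
    abort(sprintf("protein '%s': contact matrix is not square.",
                  record$protein_id))
  }
  n_res <- nchar(record$sequence)
  if (nrow(M) == n_res + 2L && record$has_special_tokens) {
    keep <- 2L:(nrow(M) - 1L)
    M <- M[keep, keep, drop = FALSE]
  } else if (nrow(M) != n_res) {
    abort(sprintf(
      "protein '%s': contact side %d matches neither residues (%d) nor tokens.",
      record$protein_id, nrow(M), n_res))
  }
  feats <- node_features
  if (is.null(feats)) {
    if (is.null(record$embeddings)) {
      abort(sprintf("protein '%s' has no embeddings.", record$protein_id))
    }
    feats <- trim_special_tokens(record$embeddings,
                                 record$has_special_tokens)
  }
  if (nrow(feats) != n_res) {
    abort(sprintf("protein '%s': %d feature rows for %d residues.",
                  record$protein_id, nrow(feats), n_res))
  }
  if (spec$symmetrize) M <- (M + t(M)) / 2
  keep_mask <- M > spec$threshold
  if (!spec$include_self_loops) diag(keep_mask) <- FALSE
  idx <- which(keep_mask, arr.ind = TRUE)
  weighted_graph(feats, cbind(idx[, 1L] - 1L, idx[, 2L] - 1L), M[idx])
}

# Truncate a protein record to at most `cap` residues; the contact matrix
# and embeddings are cut to the same window.
truncate_protein <- function(record, cap) {
  n_res <- nchar(record$sequence)
  if (n_res <= cap) return(record)
  seq_tr <- substr(record$sequence, 1L, cap)
  emb <- record$embeddings
  if (!is.null(emb)) {
    emb <- if (record$has_special_tokens) {
      # keep start token, first `cap` residues, and the end token row
      emb[c(1L, 1L + seq_len(cap), nrow(emb)), , drop = FALSE]
    } else {
      emb[seq_len(cap), , drop = FALSE]
    }
  }
  M <- record$contact
  if (!is.null(M)) {
    win <- if (nrow(M) == n_res + 2L) c(1L, 1L + seq_len(cap), nrow(M))
           else seq_len(cap)
    M <- M[win, win, drop = FALSE]
  }
  protein_record(record$protein_id, seq_tr, embeddings = emb, contact = M,
                 has_special_tokens = record$has_special_tokens,
                 embed_dim = if (is.null(emb)) NULL else ncol(emb))
}

#' Pad a batch of protein token embeddings
#'
#' Sequences are padded to the batch maximum, capped at `cap` (longer
#' sequences are truncated at the cap); the logical mask marks real
#' tokens.
#'
#' @param items List of embedding matrices or `protein_record`s.
#' @param cap Maximum token length (default 1200).
#' @return List with a `B x L x d` array `embeddings`, a `B x L` logical
#'   `mask` and the true (possibly truncated) `lengths`.
#' @export
pad_protein_batch <- function(items, cap = 1200L) {
  pad_token_batch(items, cap, "protein")
}
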