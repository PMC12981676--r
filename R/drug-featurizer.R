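# SMILES -> weighted molecular graph with 88-dimensional atom features.
#
# Chemistry (parsing, aromaticity perception, stereo assignment, Morgan
# fingerprints) is delegated to RDKit through a small batched subprocess
# bridge; the one-hot feature blocks and the graph assembly are done here.
# Results are cached per session keyed by (SMILES, options).

the_mol_cache <- new.env(parent = emptyenv())

find_python <- function() {
  p <- Sys.which("python")
  if (!nzchar(p)) p <- Sys.which("python3")
  if (!nzchar(p)) abort("no `python` interpreter found on PATH (required for SMILES parsing).")
  p
}

bridge_script <- function() {
  path <- system.file("python", "mol_bridge.py", package = "dtakan")
  if (!nzchar(path)) abort("bundled mol_bridge.py not found.")
  path
}

# Run the bridge for all uncached SMILES, then return results for all.
mol_bridge <- function(smiles, fingerprint = FALSE, kekulize = FALSE) {
  key <- function(s) paste0(s, "\r", fingerprint, "\r", kekulize)
  todo <- unique(smiles[!vapply(smiles, function(s)
    exists(key(s), envir = the_mol_cache), logical(1))])
  if (length(todo) > 0L) {
    req <- jsonlite::toJSON(list(smiles = I(todo), fingerprint = fingerprint,
                                 kekulize = kekulize), auto_unbox = TRUE)
    infile <- tempfile(fileext = ".json")
    writeLines(req, infile)
    out <- suppressWarnings(system2(find_python(), shQuote(bridge_script()),
                                    stdin = infile, stdout = TRUE,
                                    stderr = FALSE))
    status <- attr(out, "status") %||% 0L
    if (status != 0L || length(out) == 0L) {
      abort("SMILES bridge subprocess failed.")
    }
    res <- jsonlite::fromJSON(paste(out, collapse = ""),
                              simplifyDataFrame = FALSE,
                              simplifyVector = FALSE)
    for (i in seq_along(todo)) {
      assign(key(todo[i]), res[[i]], envir = the_mol_cache)
    }
  }
  lapply(smiles, function(s) get(key(s), envir = the_mol_cache))
}

#' Atom featurization scheme
#'
#' Defines the one-hot block layout of the 88-dimensional atom feature
#' vector: element (43 symbols + OTHER, 44), degree 0-10 (11), formal
#' charge -5..+5 (11), hybridization (8), total hydrogens 0-8 (9),
#' aromaticity (1), ring membership (1) and CIP chirality none/R/S (3).
#' Out-of-vocabulary elements and hybridizations fall into their OTHER
#' bucket. The layout is versioned so an alternative scheme can be swapped
#' without touching the encoders.
#'
#' @param aromatic_bond_order Weight assigned to aromatic bonds
#'   (default 1.5). Set `kekulize = TRUE` to use alternating single/double
#'   orders instead.
#' @param kekulize Use kekulized bond orders.
#' @return An `atom_feature_scheme` list; its `width` is always 88.
#' @export
atom_feature_scheme <- function(aromatic_bond_order = 1.5, kekulize = FALSE) {
  element_vocab <- c(
    "C", "N", "O", "F", "P", "S", "Cl", "Br", "I", "B", "Si", "Se", "Te",
    "As", "Al", "Zn", "Ca", "Mg", "Na", "K", "Li", "Fe", "Co", "Cu", "Ni",
    "Mn", "Cr", "Mo", "V", "Ti", "Sn", "Pb", "Hg", "Cd", "Ag", "Au", "Pt",
    "Pd", "Ru", "Rh", "W", "Ga", "Ge")
  stopifnot(length(element_vocab) == 43L)
  hyb_vocab <- c("S", "SP", "SP2", "SP3", "SP3D", "SP3D2", "UNSPECIFIED")
  widths <- c(element = 44L, degree = 11L, charge = 11L, hybridization = 8L,
              num_h = 9L, aromatic = 1L, ring = 1L, chirality = 3L)
  structure(list(version = "dtakan-88-v1",
                 element_vocab = element_vocab,
                 hyb_vocab = hyb_vocab,
                 widths = widths,
                 width = sum(widths),
                 aromatic_bond_order = aromatic_bond_order,
                 kekulize = kekulize),
            class = "atom_feature_scheme")
}

one_hot <- function(idx, width) {
  v <- numeric(width)
  v[idx] <- 1
  v
}

atom_features <- function(a, scheme) {
  el <- match(a$sym, scheme$element_vocab)
  el <- if (is.na(el)) 44L else el
  deg <- min(max(a$degree, 0L), 10L) + 1L
  chg <- min(max(a$charge, -5L), 5L) + 6L
  hyb <- match(a$hyb, scheme$hyb_vocab)
  hyb <- if (is.na(hyb)) 8L else hyb
  nh <- min(max(a$numh, 0L), 8L) + 1L
  chi <- switch(a$cip, "R" = 2L, "S" = 3L, 1L)
  c(one_hot(el, 44L), one_hot(deg, 11L), one_hot(chg, 11L),
    one_hot(hyb, 8L), one_hot(nh, 9L), as.numeric(a$aromatic),
    as.numeric(a$ring), one_hot(chi, 3L))
}

#' Parse a SMILES string into a weighted molecular graph
#'
#' One node per heavy atom (implicit hydrogens are folded into the
#' hydrogen-count feature block); every chemical bond contributes both
#' directed edges with the bond order as weight (single 1.0, double 2.0,
#' triple 3.0, aromatic 1.5 unless the scheme kekulizes).
#'
#' @param smiles SMILES string.
#' @param scheme An [atom_feature_scheme()].
#' @return A [weighted_graph()] with 88-dimensional node features.
#' @export
smiles_to_graph <- function(smiles, scheme = atom_feature_scheme()) {
  res <- mol_bridge(smiles, kekulize = scheme$kekulize)[[1L]]
  if (!isTRUE(res$ok)) {
    abort(sprintf("cannot featurize SMILES '%s': %s.", smiles, res$error))
  }
  feats <- do.call(rbind, lapply(res$atoms, atom_features, scheme = scheme))
  if (length(res$bonds) == 0L) {
    return(weighted_graph(feats, matrix(integer(0), 0L, 2L), numeric(0)))
  }
  b <- do.call(rbind, lapply(res$bonds, unlist))
  src <- as.integer(b[, 1L]); dst <- as.integer(b[, 2L])
  ord <- as.numeric(b[, 3L])
  weighted_graph(feats,
                 cbind(c(src, dst), c(dst, src)),
                 c(ord, ord))
}

#' Canonical SMILES as produced by the chemistry backend
#'
#' @param smiles Character vector of SMILES strings.
#' @return Canonicalized SMILES strings.
#' @export
canonicalize_smiles <- function(smiles) {
  res <- mol_bridge(smiles)
  vapply(seq_along(res), function(i) {
    if (!isTRUE(res[[i]]$ok)) {
      abort(sprintf("cannot parse SMILES '%s': %s.", smiles[i],
                    res[[i]]$error))
    }
    res[[i]]$canonical
  }, character(1))
}

#' Tanimoto similarity of two molecules
#'
#' Jaccard index `|A n B| / |A u B|` over Morgan fingerprint on-bit sets
#' (radius 2, 2048 bits); the standard leakage audit between train and
#' test compounds.
#'
#' @param smiles_a,smiles_b SMILES strings.
#' @return Similarity in \[0, 1\].
#' @export
tanimoto_similarity <- function(smiles_a, smiles_b) {
  res <- mol_bridge(c(smiles_a, smiles_b), fingerprint = TRUE)
  for (i in 1:2) {
    if (!isTRUE(res[[i]]$ok)) {
      abort(sprintf("cannot parse SMILES '%s': %s.",
                    c(smiles_a, smiles_b)[i], res[[i]]$error))
    }
  }
  a <- unlist(res[[1L]]$fp_bits)
  b <- unlist(res[[2L]]$fp_bits)
  u <- length(union(a, b))
  if (u == 0L) return(0)
  length(intersect(a, b)) / u
}

# --- token batching ---------------------------------------------------------

pad_token_batch <- function(items, cap, what) {
  if (length(items) == 0L) abort(sprintf("empty %s batch.", what))
  embs <- lapply(items, function(x) {
    if (inherits(x, "protein_record") || inherits(x, "drug_record")) {
      x <- x$embeddings
    }
    as_matrix2d(x, "embeddings")
  })
  d <- unique(vapply(embs, ncol, integer(1)))
  if (length(d) != 1L) abort("all embedding matrices must share one width.")
  embs <- lapply(embs, function(e) {
    if (nrow(e) > cap) e[seq_len(cap), , drop = FALSE] else e
  })
  lens <- vapply(embs, nrow, integer(1))
  L <- min(max(lens), cap)
  B <- length(embs)
  arr <- array(0, dim = c(B, L, d))
  mask <- matrix(FALSE, B, L)
  for (i in seq_len(B)) {
    arr[i, seq_len(lens[i]), ] <- embs[[i]]
    mask[i, seq_len(lens[i])] <- TRUE
  }
  list(embeddings = arr, mask = mask, lengths = lens)
}

#' Pad a batch of drug token embeddings
#'
#' Sequences are padded to the batch maximum, capped at `cap` (longer
#' sequences are truncated); the logical mask marks real tokens.
#'
#' @param items List of embedding matrices or `drug_record`s.
#' @param cap Maximum token length (default 220).
#' @return List with a `B x L x d` array `embeddings`, a `B x L` logical
#'   `mask` and the true (possibly truncated) `lengths`.
#' @export
pad_drug_batch <- function(items, cap = 220L) {
  pad_token_batch(items, cap, "drug")
}
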