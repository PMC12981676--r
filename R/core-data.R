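# Domain record types and file IO shared across the package.
#
# A protein carries its amino-acid sequence, a residue- (or token-) level
# embedding matrix from a language-model-style provider, and a contact
# probability matrix; a drug carries a SMILES string, token embeddings and
# a molecular graph. Interaction tables, split manifests and predictions
# are tibbles throughout.

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                 "P", "Q", "R", "S", "T", "V", "W", "Y", "X")

#' Construct a protein record
#'
#' @param protein_id Identifier string.
#' @param sequence Amino-acid sequence over the 20-letter alphabet plus `X`
#'   (uppercased on input).
#' @param embeddings Optional token-embedding matrix. With
#'   `has_special_tokens = TRUE` the provider emits one start and one end
#'   token, so the matrix must have `nchar(sequence) + 2` rows; otherwise
#'   exactly `nchar(sequence)` rows.
#' @param contact Optional square contact-probability matrix with entries
#'   in \[0, 1\], indexed either by residue or by token (its side must
#'   match one of the two counts).
#' @param has_special_tokens Whether `embeddings` (and a token-indexed
#'   `contact`) include start/end special tokens.
#' @param embed_dim Expected embedding width (default 1152, the standard
#'   protein provider width; pass another value for non-standard
#'   providers).
#' @return A `protein_record` list.
#' @export
protein_record <- function(protein_id, sequence, embeddings = NULL,
                           contact = NULL, has_special_tokens = FALSE,
                           embed_dim = 1152L) {
  stopifnot(is.character(protein_id), length(protein_id) == 1L)
  sequence <- toupper(sequence)
  bad <- setdiff(unique(strsplit(sequence, "")[[1]]), AA_ALPHABET)
  if (length(bad) > 0L) {
    abort(sprintf("protein '%s': illegal residue(s) %s.", protein_id,
                  paste(bad, collapse = ", ")))
  }
  n_res <- nchar(sequence)
  n_tok <- if (has_special_tokens) n_res + 2L else n_res
  if (!is.null(embeddings)) {
    embeddings <- as_matrix2d(embeddings, "embeddings")
    if (nrow(embeddings) != n_tok) {
      abort(sprintf(
        "protein '%s': embeddings have %d rows but %d tokens expected (%d residues%s).",
        protein_id, nrow(embeddings), n_tok, n_res,
        if (has_special_tokens) " + 2 special tokens" else ""))
    }
    if (!is.null(embed_dim) && ncol(embeddings) != embed_dim) {
      abort(sprintf("protein '%s': embedding width %d != expected %d.",
                    protein_id, ncol(embeddings), embed_dim))
    }
  }
  if (!is.null(contact)) {
    contact <- as_matrix2d(contact, "contact")
    if (nrow(contact) != ncol(contact)) {
      abort(sprintf("protein '%s': contact matrix is %d x %d, must be square.",
                    protein_id, nrow(contact), ncol(contact)))
    }
    if (!(nrow(contact) %in% c(n_res, n_tok))) {
      abort(sprintf(
        "protein '%s': contact side %d matches neither residue count %d nor token count %d.",
        protein_id, nrow(contact), n_res, n_tok))
    }
    if (any(!is.finite(contact)) || any(contact < 0) || any(contact > 1)) {
      abort(sprintf("protein '%s': contact entries must be finite and in [0, 1].",
                    protein_id))
    }
  }
  structure(list(protein_id = protein_id, sequence = sequence,
                 embeddings = embeddings, contact = contact,
                 has_special_tokens = has_special_tokens),
            class = "protein_record")
}

#' @export
print.protein_record <- function(x, ...) {
  cat(sprintf("<protein_record> %s: %d residues%s%s\n", x$protein_id,
              nchar(x$sequence),
              if (!is.null(x$embeddings))
                sprintf(", embeddings %d x %d", nrow(x$embeddings),
                        ncol(x$embeddings)) else "",
              if (!is.null(x$contact))
                sprintf(", contact %d x %d", nrow(x$contact),
                        ncol(x$contact)) else ""))
  invisible(x)
}

#' Construct a weighted directed graph
#'
#' Shared container for protein residue graphs and drug molecular graphs.
#' Edges are stored directed with 0-based node indices; every undirected
#' contact or bond must contribute both `(i, j)` and `(j, i)`.
#'
#' @param node_features Numeric matrix, one row per node.
#' @param edges Integer matrix with two columns (`from`, `to`), 0-based.
#' @param edge_weights Positive weights aligned with `edges` rows.
#' @return A `weighted_graph` list.
#' @export
weighted_graph <- function(node_features, edges, edge_weights) {
  node_features <- as_matrix2d(node_features, "node_features")
  if (is.null(dim(edges))) edges <- matrix(as.integer(edges), ncol = 2L)
  edges <- matrix(as.integer(edges), ncol = 2L)
  n <- nrow(node_features)
  if (nrow(edges) != length(edge_weights)) {
    abort(sprintf("edge_weights length %d != number of edges %d.",
                  length(edge_weights), nrow(edges)))
  }
  if (nrow(edges) > 0L) {
    if (min(edges) < 0L || max(edges) >= n) {
      abort(sprintf("edge indices must lie in [0, %d).", n))
    }
    if (any(!is.finite(edge_weights)) || any(edge_weights <= 0)) {
      abort("edge weights must be finite and > 0.")
    }
    key <- paste(edges[, 1L], edges[, 2L])
    rev_key <- paste(edges[, 2L], edges[, 1L])
    if (!all(rev_key %in% key)) {
      abort("graph must contain both directions of every edge.")
    }
  }
  structure(list(node_features = node_features, edges = edges,
                 edge_weights = as.numeric(edge_weights)),
            class = "weighted_graph")
}

#' @export
print.weighted_graph <- function(x, ...) {
  cat(sprintf("<weighted_graph> %d nodes (%d features), %d directed edges\n",
              nrow(x$node_features), ncol(x$node_features), nrow(x$edges)))
  invisible(x)
}

#' Construct a drug record
#'
#' @param drug_id Identifier string.
#' @param smiles SMILES string; must describe a molecule with at least one
#'   heavy atom when a graph is attached.
#' @param embeddings Optional token-embedding matrix (one row per provider
#'   token).
#' @param graph Optional [weighted_graph()] of the molecule; node feature
#'   width must equal `feature_dim`.
#' @param embed_dim Expected embedding width (default 384).
#' @param feature_dim Expected atom-feature width (default 88).
#' @return A `drug_record` list.
#' @export
drug_record <- function(drug_id, smiles, embeddings = NULL, graph = NULL,
                        embed_dim = 384L, feature_dim = 88L) {
  stopifnot(is.character(drug_id), length(drug_id) == 1L,
            is.character(smiles), length(smiles) == 1L, nzchar(smiles))
  if (!is.null(embeddings)) {
    embeddings <- as_matrix2d(embeddings, "embeddings")
    if (!is.null(embed_dim) && ncol(embeddings) != embed_dim) {
      abort(sprintf("drug '%s': embedding width %d != expected %d.",
                    drug_id, ncol(embeddings), embed_dim))
    }
  }
  if (!is.null(graph)) {
    stopifnot(inherits(graph, "weighted_graph"))
    if (nrow(graph$node_features) < 1L) {
      abort(sprintf("drug '%s': molecular graph has no heavy atoms.", drug_id))
    }
    if (!is.null(feature_dim) && ncol(graph$node_features) != feature_dim) {
      abort(sprintf("drug '%s': atom feature width %d != expected %d.",
                    drug_id, ncol(graph$node_features), feature_dim))
    }
  }
  structure(list(drug_id = drug_id, smiles = smiles,
                 embeddings = embeddings, graph = graph),
            class = "drug_record")
}

#' @export
print.drug_record <- function(x, ...) {
  cat(sprintf("<drug_record> %s: %s%s\n", x$drug_id, x$smiles,
              if (!is.null(x$graph))
                sprintf(" (%d atoms)", nrow(x$graph$node_features)) else ""))
  invisible(x)
}

#' Build an interaction table
#'
#' @param drug_id,protein_id Character vectors of equal length.
#' @param affinity Finite numeric affinity labels (pKd, KIBA score or
#'   synthetic units).
#' @return A tibble with columns `drug_id`, `protein_id`, `affinity`.
#' @export
interaction_table <- function(drug_id, protein_id, affinity) {
  stopifnot(length(drug_id) == length(protein_id),
            length(drug_id) == length(affinity))
  if (any(!is.finite(affinity))) {
    abort(sprintf("affinity must be finite; %d offending value(s).",
                  sum(!is.finite(affinity))))
  }
  tibble::tibble(drug_id = as.character(drug_id),
                 protein_id = as.character(protein_id),
                 affinity = as.numeric(affinity))
}

#' Convert dissociation constants to pKd
#'
#' Community-standard transform `pKd = -log10(Kd[nM] * 1e-9)` for raw Kd
#' labels measured in nanomolar units. Opt-in: affinity columns are
#' otherwise passed through untouched.
#'
#' @param kd_nm Dissociation constants in nM.
#' @return pKd values.
#' @export
kd_to_pkd <- function(kd_nm) {
  if (any(kd_nm <= 0, na.rm = TRUE)) abort("Kd values must be positive.")
  -log10(kd_nm * 1e-9)
}

# --- readers ----------------------------------------------------------------

#' Read a protein FASTA file
#'
#' Parsed directly so malformed input can be reported with file and line
#' numbers. Sequences are uppercased; wrapped lines are concatenated;
#' residues outside the 20-letter alphabet plus `X` are rejected.
#'
#' @param path FASTA file path.
#' @return A tibble with columns `protein_id`, `sequence`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("%s: file not found.", path))
  lines <- readr::read_lines(path)
  lines <- lines[!grepl("^\\s*$", lines) | seq_along(lines) == 0]
  if (length(lines) == 0L) abort(sprintf("%s: empty FASTA file.", path))
  hdr <- grepl("^>", lines)
  if (!hdr[1L]) {
    abort(sprintf("%s:1: expected a '>' header, got '%s'.", path,
                  substr(lines[1L], 1L, 30L)))
  }
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- sub("\\s.*$", "", ids)
  if (anyDuplicated(ids)) {
    abort(sprintf("%s: duplicate protein id '%s'.", path,
                  ids[duplicated(ids)][1L]))
  }
  rec <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], rec[!hdr]), paste, character(1),
                 collapse = "")
  if (length(seqs) < length(ids)) {
    missing_idx <- setdiff(seq_along(ids), as.integer(names(seqs)))
    abort(sprintf("%s: record '%s' has no sequence lines.", path,
                  ids[missing_idx[1L]]))
  }
  seqs <- toupper(gsub("\\s", "", seqs[as.character(seq_along(ids))]))
  for (i in seq_along(ids)) {
    bad <- setdiff(unique(strsplit(seqs[i], "")[[1]]), AA_ALPHABET)
    if (length(bad) > 0L) {
      line_no <- which(hdr)[i]
      abort(sprintf("%s:%d: record '%s' has illegal residue(s) %s.",
                    path, line_no, ids[i], paste(bad, collapse = ", ")))
    }
  }
  tibble::tibble(protein_id = ids, sequence = unname(seqs))
}

sniff_delim <- function(path) {
  first <- readr::read_lines(path, n_max = 1L)
  if (length(first) == 0L) abort(sprintf("%s: empty file.", path))
  if (grepl("\t", first)) "\t" else ","
}

#' Read a drug-target interaction table
#'
#' Accepts CSV or TSV (dialect sniffed from the header line) with required
#' columns `drug_id`, `protein_id`, `affinity`.
#'
#' @param path Delimited file path.
#' @return A tibble in file order with `affinity` parsed as numeric.
#' @export
read_interaction_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("%s: file not found.", path))
  delim <- sniff_delim(path)
  df <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE)
  need <- c("drug_id", "protein_id", "affinity")
  if (!all(need %in% names(df))) {
    abort(sprintf("%s: missing column(s) %s; found: %s.", path,
                  paste(setdiff(need, names(df)), collapse = ", "),
                  paste(names(df), collapse = ", ")))
  }
  aff <- suppressWarnings(as.numeric(df$affinity))
  bad <- which(is.na(aff))
  if (length(bad) > 0L) {
    abort(sprintf("%s: non-numeric affinity '%s' at data row %d.", path,
                  df$affinity[bad[1L]], bad[1L]))
  }
  interaction_table(df$drug_id, df$protein_id, aff)
}

#' Read a drug table (drug_id, smiles)
#'
#' @param path Delimited file with columns `drug_id` and `smiles`.
#' @return A tibble with those columns.
#' @export
read_drug_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("%s: file not found.", path))
  delim <- sniff_delim(path)
  df <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE)
  if (!all(c("drug_id", "smiles") %in% names(df))) {
    abort(sprintf("%s: missing column(s) %s; found: %s.", path,
                  paste(setdiff(c("drug_id", "smiles"), names(df)),
                        collapse = ", "),
                  paste(names(df), collapse = ", ")))
  }
  tibble::tibble(drug_id = df$drug_id, smiles = df$smiles)
}

#' Read a dense matrix from NPY or whitespace-delimited text
#'
#' @param path Matrix file; format is detected from the NPY magic bytes.
#' @return A numeric matrix (rank 2 enforced).
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) abort(sprintf("%s: file not found.", path))
  if (is_npy_file(path)) {
    m <- read_npy(path)
  } else {
    lines <- readr::read_lines(path)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L) abort(sprintf("%s: empty matrix file.", path))
    rows <- strsplit(trimws(lines), "\\s+")
    widths <- lengths(rows)
    if (length(unique(widths)) != 1L) {
      bad <- which(widths != widths[1L])[1L]
      abort(sprintf("%s:%d: ragged row (%d values, expected %d).", path,
                    bad, widths[bad], widths[1L]))
    }
    m <- matrix(suppressWarnings(as.numeric(unlist(rows))),
                nrow = length(rows), byrow = TRUE)
  }
  if (any(!is.finite(m))) {
    abort(sprintf("%s: matrix contains non-finite or non-numeric entries.",
                  path))
  }
  m
}

#' Write a matrix as whitespace-delimited text
#'
#' @param x Numeric matrix.
#' @param path Output path.
#' @export
write_matrix_txt <- function(x, path) {
  x <- as_matrix2d(x, "x")
  readr::write_lines(apply(x, 1L, function(r)
    paste(format(r, digits = 17, trim = TRUE, scientific = TRUE),
          collapse = " ")), path)
  invisible(path)
}

# --- predictions ------------------------------------------------------------

#' Write a predictions table
#'
#' CSV with header `drug_id,protein_id,y_true,y_pred`; numeric values are
#' written with 6 decimal places, missing `y_true` as an empty field.
#'
#' @param predictions Data frame with columns `drug_id`, `protein_id`,
#'   `y_true` (may contain `NA`), `y_pred`.
#' @param path Output path.
#' @export
write_predictions <- function(predictions, path) {
  need <- c("drug_id", "protein_id", "y_true", "y_pred")
  if (!all(need %in% names(predictions))) {
    abort(sprintf("predictions must have columns %s.",
                  paste(need, collapse = ", ")))
  }
  fmt <- function(v) ifelse(is.na(v), "", sprintf("%.6f", v))
  lines <- c("drug_id,protein_id,y_true,y_pred",
             paste(predictions$drug_id, predictions$protein_id,
                   fmt(predictions$y_true), fmt(predictions$y_pred),
                   sep = ","))
  tryCatch(readr::write_lines(lines, path),
           error = function(e) abort(sprintf("cannot write %s: %s", path,
                                             conditionMessage(e))))
  invisible(path)
}

#' Read a predictions table written by [write_predictions()]
#'
#' @param path Predictions CSV path.
#' @return A tibble with `y_true` as numeric (`NA` for empty fields).
#' @export
read_predictions <- function(path) {
  df <- readr::read_csv(path, col_types = "ccdd", progress = FALSE)
  tibble::as_tibble(df)
}
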