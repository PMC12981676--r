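# Deterministic synthetic dataset generator.
#
# Emulates the outputs of pretrained embedding providers so every
# downstream stage can be exercised without downloads or a GPU: residue
# embeddings are unstructured Gaussians at the standard provider widths,
# contact maps have near-diagonal band structure plus sparse long-range
# contacts, drugs are drawn from a packaged list of real drug-like SMILES,
# and affinities follow a planted latent-factor model. Every entity is
# seeded by a stable string hash of (entity id, global seed), so adding
# entities never perturbs existing ones. These embeddings carry no
# biology: synthetic runs test mechanism, not benchmark performance.

# Canonical SMILES of common drugs/metabolites with heavy-atom counts,
# validated through the chemistry backend.
SMILES_LIBRARY <- local({
  tab <- matrix(c(
    "C", "1", "CCO", "3", "CCC", "3", "CC(=O)O", "4", "CC(C)O", "4",
    "NC(N)=O", "4", "c1c[nH]cn1", "5", "OCC(O)CO", "6", "c1ccncc1", "6",
    "c1ccccc1", "6", "CC(O)C(=O)O", "6", "C[C@H](N)C(=O)O", "6",
    "Oc1ccccc1", "7", "Cc1ccccc1", "7", "Nc1ccccc1", "7",
    "NCCc1c[nH]cn1", "8", "O=C(O)c1ccccc1", "9", "NC(=O)c1cccnc1", "9",
    "NC(=O)c1ccccc1", "9", "c1ccc2[nH]ccc2c1", "9",
    "CN(C)C(=N)NC(=N)N", "9", "c1ccc2ccccc2c1", "10",
    "c1ccc2ncccc2c1", "10", "CC(=O)Nc1ccc(O)cc1", "11",
    "COc1cc(C=O)ccc1O", "11", "NCCc1ccc(O)c(O)c1", "11",
    "Nc1ccc(S(N)(=O)=O)cc1", "11", "CN1CCCC1c1cccnc1", "12",
    "O=C1OC(C(O)CO)C(O)=C1O", "12",
    "OC[C@H]1OC(O)[C@H](O)[C@@H](O)[C@@H]1O", "12",
    "CC(=O)Oc1ccccc1C(=O)O", "13", "Cn1c(=O)c2[nH]cnc2n(C)c1=O", "13",
    "NCCc1c[nH]c2ccc(O)cc12", "13", "CNCC(O)c1ccc(O)c(O)c1", "13",
    "Cn1c(=O)c2c(ncn2C)n(C)c1=O", "14", "CC(C)Cc1ccc(C(C)C(=O)O)cc1", "15",
    "N[C@@H](Cc1c[nH]c2ccccc12)C(=O)O", "15",
    "CC(C)(C)NCC(O)c1ccc(O)c(CO)c1", "17",
    "COc1ccc2[nH]cc(CCNC(C)=O)c2c1", "17",
    "COc1ccc2cc(C(C)C(=O)O)ccc2c1", "17",
    "O=C(O)Cc1ccccc1Nc1c(Cl)cccc1Cl", "19",
    "CC(C)NCC(O)COc1ccc(CC(N)=O)cc1", "19",
    "CC(C)NCC(O)COc1cccc2ccccc12", "19",
    "CC12CCC(=O)C=C1CCC1C2CCC2(C)C(O)CCC12", "21",
    "CCN(CC)CCCC(C)Nc1ccnc2cc(Cl)ccc12", "22",
    "CC(=O)CC(c1ccccc1)c1c(O)c2ccccc2oc1=O", "23",
    "CC1(C)SC2C(NC(=O)Cc3ccccc3)C(=O)N2C1C(=O)O", "23",
    "CC1(C)SC2C(NC(=O)C(N)c3ccccc3)C(=O)N2C1C(=O)O", "24",
    "O=C(O)c1cn(C2CC2)c2cc(N3CCNCC3)c(F)cc2c1=O", "24",
    "CC(C)CCC[C@@H](C)[C@H]1CC[C@H]2[C@@H]3CC=C4C[C@@H](O)CC[C@]4(C)[C@H]3CC[C@]12C", "28",
    "COc1cc2ncnc(Nc3ccc(F)c(Cl)c3)c2cc1OCCCN1CCOCC1", "31",
    "CCCc1nn(C)c2c(=O)[nH]c(-c3cc(S(=O)(=O)N4CCN(C)CC4)ccc3OCC)nc12", "33",
    "Cc1ccc(NC(=O)c2ccc(CN3CCN(C)CC3)cc2)cc1Nc1nccc(-c2cccnc2)n1", "37"
  ), ncol = 2L, byrow = TRUE)
  tibble::tibble(smiles = tab[, 1L], n_atoms = as.integer(tab[, 2L]))
})

#' Configuration of the synthetic dataset generator
#'
#' Defaults describe the desk-scale study conditions used throughout the
#' package: a 40 x 40 drug-protein grid with 1200 observed pairs, a
#' rank-4 planted latent-factor affinity surface and Gaussian label noise
#' of 0.1. Provider widths default to the standard 1152 (protein) and 384
#' (drug).
#'
#' @param n_proteins,n_drugs,n_pairs Grid size and number of observed
#'   interactions (`n_pairs <= n_proteins * n_drugs`).
#' @param protein_len_range,drug_atoms_range Inclusive integer ranges for
#'   protein length (residues) and drug heavy-atom counts.
#' @param embed_dim_protein,embed_dim_drug Provider embedding widths.
#' @param contact_band_width Half-width of the near-diagonal contact band.
#' @param long_range_contact_prob Probability that an off-band residue
#'   pair is a (>0.5) contact.
#' @param latent_dim Rank of the planted affinity surface.
#' @param noise_sd Standard deviation of the Gaussian label noise.
#' @param intercept Global affinity offset (pKd-like scale).
#' @param seed Global integer seed; all entity-level seeds derive from it
#'   by stable string hashing.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_proteins = 40L, n_drugs = 40L,
                             n_pairs = 1200L,
                             protein_len_range = c(30L, 60L),
                             drug_atoms_range = c(8L, 24L),
                             embed_dim_protein = 1152L,
                             embed_dim_drug = 384L,
                             contact_band_width = 3L,
                             long_range_contact_prob = 0.02,
                             latent_dim = 4L, noise_sd = 0.1,
                             intercept = 5, seed = 1L) {
  stopifnot(is_count(n_proteins), is_count(n_drugs), is_count(n_pairs),
            length(protein_len_range) == 2L,
            protein_len_range[1L] <= protein_len_range[2L],
            protein_len_range[1L] >= 3L,
            length(drug_atoms_range) == 2L,
            drug_atoms_range[1L] <= drug_atoms_range[2L],
            drug_atoms_range[1L] >= 1L,
            is_count(latent_dim), noise_sd >= 0,
            long_range_contact_prob >= 0, long_range_contact_prob <= 1)
  if (n_pairs > n_proteins * n_drugs) {
    abort(sprintf("n_pairs (%d) exceeds the %d x %d grid.", n_pairs,
                  n_proteins, n_drugs))
  }
  structure(list(
    n_proteins = as.integer(n_proteins), n_drugs = as.integer(n_drugs),
    n_pairs = as.integer(n_pairs),
    protein_len_range = as.integer(protein_len_range),
    drug_atoms_range = as.integer(drug_atoms_range),
    embed_dim_protein = as.integer(embed_dim_protein),
    embed_dim_drug = as.integer(embed_dim_drug),
    contact_band_width = as.integer(contact_band_width),
    long_range_contact_prob = long_range_contact_prob,
    latent_dim = as.integer(latent_dim), noise_sd = noise_sd,
    intercept = intercept, seed = as.integer(seed)),
    class = "synthetic_config")
}

#' Generate a synthetic protein record
#'
#' The sequence is uniform over the 20 amino acids; embeddings are
#' standard normal scaled by `1/sqrt(embed_dim)` with two special
#' (start/end) token rows, mirroring providers that emit them; the
#' residue-indexed contact matrix is symmetric with unit diagonal, a
#' near-diagonal band of contacts (entries in (0.5, 1]) and sparse
#' long-range contacts.
#'
#' @param length Number of residues (>= 3).
#' @param seed Integer seed (fully determines the record).
#' @param band_width,long_range_prob Contact-map structure controls.
#' @param embed_dim Embedding width (default 1152).
#' @param protein_id Identifier (defaults to a seed-derived name).
#' @return A [protein_record()] with `has_special_tokens = TRUE`.
#' @export
gen_protein <- function(length, seed, band_width = 3L,
                        long_range_prob = 0.02, embed_dim = 1152L,
                        protein_id = sprintf("P%06d", seed %% 1000000L)) {
  if (!is_count(length) || length < 3L) {
    abort("protein `length` must be an integer >= 3.")
  }
  length <- as.integer(length)
  with_seed(seed, {
    sequence <- paste(sample(AA_ALPHABET[1:20], length, replace = TRUE),
                      collapse = "")
    emb <- matrix(rnorm((length + 2L) * embed_dim) / sqrt(embed_dim),
                  length + 2L, embed_dim)
    M <- matrix(0, length, length)
    iu <- which(upper.tri(M), arr.ind = TRUE)
    d <- abs(iu[, 1L] - iu[, 2L])
    in_band <- d <= band_width
    vals <- numeric(nrow(iu))
    vals[in_band] <- runif(sum(in_band), 0.55, 0.95)
    off <- !in_band
    hit <- runif(sum(off)) < long_range_prob
    voff <- runif(sum(off), 0, 0.45)
    voff[hit] <- runif(sum(hit), 0.55, 0.95)
    vals[off] <- voff
    M[iu] <- vals
    M <- M + t(M)
    diag(M) <- 1
    protein_record(protein_id, sequence, embeddings = emb, contact = M,
                   has_special_tokens = TRUE, embed_dim = embed_dim)
  })
}

#' Generate a synthetic drug record
#'
#' Picks a molecule from the packaged SMILES library whose heavy-atom
#' count is within 2 of `n_atoms`; when none matches, falls back to a
#' linear alkane chain of `n_atoms` carbons (always valid). Token
#' embeddings use one token per SMILES character, seeded from a stable
#' hash of the SMILES and the seed; no special tokens are emitted
#' (trimming is protein-side only).
#'
#' @param n_atoms Requested heavy-atom count (>= 1).
#' @param seed Integer seed.
#' @param embed_dim Token embedding width (default 384).
#' @param drug_id Identifier.
#' @return A [drug_record()] (without the molecular graph, which is built
#'   by the featurizer on demand).
#' @export
gen_drug <- function(n_atoms, seed, embed_dim = 384L,
                     drug_id = sprintf("D%06d", seed %% 1000000L)) {
  if (!is_count(n_atoms)) abort("`n_atoms` must be a positive integer.")
  cand <- SMILES_LIBRARY$smiles[abs(SMILES_LIBRARY$n_atoms - n_atoms) <= 2L]
  smiles <- if (length(cand) > 0L) {
    with_seed(seed, cand[sample.int(length(cand), 1L)])
  } else {
    strrep("C", n_atoms)
  }
  n_tok <- nchar(smiles)
  emb <- with_seed(hash_seed("drug-emb", smiles, seed), {
    matrix(rnorm(n_tok * embed_dim) / sqrt(embed_dim), n_tok, embed_dim)
  })
  drug_record(drug_id, smiles, embeddings = emb, embed_dim = embed_dim)
}

#' Generate a complete synthetic interaction dataset
#'
#' Every protein and drug receives a latent vector (seeded standard
#' normal, `latent_dim` components); the affinity of an observed pair is
#' `u_protein . v_drug + intercept + noise`. The planted latent structure
#' is returned so recovery tests can assert against it.
#'
#' @param cfg A [synthetic_config()].
#' @return A list of class `dta_dataset` with `proteins` (named list of
#'   records), `drugs`, `interactions` (tibble), `latent` (list with `u`,
#'   `v`, `intercept`) and the generating `config`.
#' @export
gen_dataset <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  pid <- sprintf("prot%03d", seq_len(cfg$n_proteins))
  did <- sprintf("drug%03d", seq_len(cfg$n_drugs))
  proteins <- lapply(seq_along(pid), function(i) {
    s <- hash_seed("protein", pid[i], cfg$seed)
    len <- with_seed(s, sample(cfg$protein_len_range[1L]:
                               cfg$protein_len_range[2L], 1L))
    gen_protein(len, seed = s, band_width = cfg$contact_band_width,
                long_range_prob = cfg$long_range_contact_prob,
                embed_dim = cfg$embed_dim_protein, protein_id = pid[i])
  })
  names(proteins) <- pid
  drugs <- lapply(seq_along(did), function(i) {
    s <- hash_seed("drug", did[i], cfg$seed)
    na <- with_seed(s, sample(cfg$drug_atoms_range[1L]:
                              cfg$drug_atoms_range[2L], 1L))
    gen_drug(na, seed = s, embed_dim = cfg$embed_dim_drug, drug_id = did[i])
  })
  names(drugs) <- did
  u <- do.call(rbind, lapply(pid, function(id) {
    with_seed(hash_seed("latent-u", id, cfg$seed), rnorm(cfg$latent_dim))
  }))
  v <- do.call(rbind, lapply(did, function(id) {
    with_seed(hash_seed("latent-v", id, cfg$seed), rnorm(cfg$latent_dim))
  }))
  rownames(u) <- pid
  rownames(v) <- did
  grid_n <- cfg$n_proteins * cfg$n_drugs
  sel <- with_seed(hash_seed("pairs", cfg$seed),
                   sort(sample.int(grid_n, cfg$n_pairs)))
  p_idx <- ((sel - 1L) %% cfg$n_proteins) + 1L
  d_idx <- ((sel - 1L) %/% cfg$n_proteins) + 1L
  eps <- vapply(seq_along(sel), function(k) {
    with_seed(hash_seed("eps", did[d_idx[k]], pid[p_idx[k]], cfg$seed),
              rnorm(1L, sd = cfg$noise_sd))
  }, numeric(1))
  aff <- rowSums(u[p_idx, , drop = FALSE] * v[d_idx, , drop = FALSE]) +
    cfg$intercept + eps
  structure(list(
    proteins = proteins,
    drugs = drugs,
    interactions = interaction_table(did[d_idx], pid[p_idx], aff),
    latent = list(u = u, v = v, intercept = cfg$intercept),
    config = cfg), class = "dta_dataset")
}

#' @export
print.dta_dataset <- function(x, ...) {
  cat(sprintf("<dta_dataset> %d proteins x %d drugs, %d interactions\n",
              length(x$proteins), length(x$drugs), nrow(x$interactions)))
  invisible(x)
}

#' Write a dataset directory in the package's on-disk formats
#'
#' Writes `proteins.fasta`, `drugs.csv`, `interactions.csv` and a
#' `matrices/` directory with per-entity embedding and contact matrices
#' (NPY by default).
#'
#' @param ds A `dta_dataset`.
#' @param dir Output directory (created if needed).
#' @param format `"npy"` or `"txt"` matrix encoding.
#' @param force Overwrite an existing non-empty directory.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir, format = c("npy", "txt"), force = FALSE) {
  format <- match.arg(format)
  if (dir.exists(dir) && length(dir(dir)) > 0L && !force) {
    abort(sprintf("%s exists and is not empty (use force = TRUE).", dir))
  }
  mdir <- file.path(dir, "matrices")
  dir.create(mdir, recursive = TRUE, showWarnings = FALSE)
  fasta <- unlist(lapply(ds$proteins, function(p) {
    c(paste0(">", p$protein_id), p$sequence)
  }), use.names = FALSE)
  readr::write_lines(fasta, file.path(dir, "proteins.fasta"))
  readr::write_csv(tibble::tibble(
    drug_id = vapply(ds$drugs, `[[`, character(1), "drug_id"),
    smiles = vapply(ds$drugs, `[[`, character(1), "smiles")),
    file.path(dir, "drugs.csv"), progress = FALSE)
  readr::write_csv(ds$interactions, file.path(dir, "interactions.csv"),
                   progress = FALSE)
  wm <- if (format == "npy") write_npy else write_matrix_txt
  ext <- if (format == "npy") ".npy" else ".txt"
  for (p in ds$proteins) {
    wm(p$embeddings, file.path(mdir, paste0(p$protein_id, "_embeddings", ext)))
    wm(p$contact, file.path(mdir, paste0(p$protein_id, "_contact", ext)))
  }
  for (d in ds$drugs) {
    wm(d$embeddings, file.path(mdir, paste0(d$drug_id, "_embeddings", ext)))
  }
  yaml::write_yaml(list(has_special_tokens = TRUE,
                        embed_dim_protein = ncol(ds$proteins[[1]]$embeddings),
                        embed_dim_drug = ncol(ds$drugs[[1]]$embeddings)),
                   file.path(dir, "provider.yaml"))
  invisible(dir)
}

#' Read a dataset directory written by [write_dataset()]
#'
#' @param dir Dataset directory.
#' @return A `dta_dataset` (without planted latent truth).
#' @export
read_dataset <- function(dir) {
  prov <- yaml::read_yaml(file.path(dir, "provider.yaml"))
  fa <- read_fasta(file.path(dir, "proteins.fasta"))
  dr <- read_drug_table(file.path(dir, "drugs.csv"))
  mdir <- file.path(dir, "matrices")
  mat_path <- function(stem) {
    for (ext in c(".npy", ".txt")) {
      p <- file.path(mdir, paste0(stem, ext))
      if (file.exists(p)) return(p)
    }
    abort(sprintf("no matrix file for '%s' under %s.", stem, mdir))
  }
  proteins <- lapply(seq_len(nrow(fa)), function(i) {
    protein_record(fa$protein_id[i], fa$sequence[i],
                   embeddings = read_matrix(mat_path(paste0(fa$protein_id[i],
                                                            "_embeddings"))),
                   contact = read_matrix(mat_path(paste0(fa$protein_id[i],
                                                         "_contact"))),
                   has_special_tokens = isTRUE(prov$has_special_tokens),
                   embed_dim = prov$embed_dim_protein)
  })
  names(proteins) <- fa$protein_id
  drugs <- lapply(seq_len(nrow(dr)), function(i) {
    drug_record(dr$drug_id[i], dr$smiles[i],
                embeddings = read_matrix(mat_path(paste0(dr$drug_id[i],
                                                         "_embeddings"))),
                embed_dim = prov$embed_dim_drug)
  })
  names(drugs) <- dr$drug_id
  structure(list(proteins = proteins, drugs = drugs,
                 interactions = read_interaction_table(
                   file.path(dir, "interactions.csv")),
                 latent = NULL, config = NULL),
            class = "dta_dataset")
}
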