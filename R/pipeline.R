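# Runnable pipelines tying the modules together: simulate, train,
# evaluate, predict. These back the command-line wrapper in
# `inst/scripts/dtakan` and are the package's top-level entry points.

#' Read a run configuration from YAML
#'
#' The file may contain `synthetic:`, `model:` and `split:` sections whose
#' keys are the arguments of [synthetic_config()], [model_config()] and
#' [split_spec()].
#'
#' @param path YAML file path.
#' @return List with `synthetic`, `model` and `split` objects (defaults
#'   where a section is absent).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("%s: file not found.", path))
  y <- yaml::read_yaml(path) %||% list()
  build <- function(section, ctor) {
    args <- y[[section]] %||% list()
    unknown <- setdiff(names(args), names(formals(ctor)))
    if (length(unknown) > 0L) {
      abort(sprintf("%s: unknown %s option(s): %s.", path, section,
                    paste(unknown, collapse = ", ")))
    }
    do.call(ctor, args)
  }
  list(synthetic = build("synthetic", synthetic_config),
       model = build("model", model_config),
       split = build("split", split_spec))
}

#' Simulate a dataset directory
#'
#' Generates a synthetic dataset and writes it in the package's on-disk
#' formats (FASTA, CSV tables, per-entity matrix files).
#'
#' @param cfg A [synthetic_config()].
#' @param out_dir Output directory.
#' @param format Matrix file format, `"npy"` or `"txt"`.
#' @param force Overwrite a non-empty directory.
#' @return The dataset (invisibly); side effect is the written directory.
#' @export
run_simulate <- function(cfg = synthetic_config(), out_dir,
                         format = c("npy", "txt"), force = FALSE) {
  ds <- gen_dataset(cfg)
  write_dataset(ds, out_dir, format = match.arg(format), force = force)
  invisible(ds)
}

#' Train a model on a dataset directory
#'
#' Splits the interaction table, trains with early stopping, and writes
#' `checkpoint.rds`, `history.csv`, `split.csv` and `metrics.json` under
#' `out_dir`.
#'
#' @param data_dir Dataset directory (from [run_simulate()] or assembled
#'   by hand in the same formats).
#' @param out_dir Output directory (created).
#' @param config A [model_config()].
#' @param split A [split_spec()].
#' @param verbose Per-epoch progress.
#' @return A list with `fit`, `split`, `metrics` (validation), invisibly.
#' @export
run_train <- function(data_dir, out_dir, config = model_config(),
                      split = split_spec(), verbose = FALSE) {
  ds <- read_dataset(data_dir)
  pdim <- ncol(ds$proteins[[1L]]$embeddings)
  ddim <- ncol(ds$drugs[[1L]]$embeddings)
  if (pdim != config$protein_embed_dim || ddim != config$drug_embed_dim) {
    abort(sprintf(
      "provider dims (%d protein / %d drug) do not match config (%d / %d).",
      pdim, ddim, config$protein_embed_dim, config$drug_embed_dim))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sp <- split_dataset(ds$interactions, split)
  write_split_manifest(sp, file.path(out_dir, "split.csv"))
  cache <- featurize_entities(ds$proteins, ds$drugs, config)
  model <- dta_model(config)
  fit <- dta_train(model, sp$train, sp$val, cache = cache, verbose = verbose)
  save_checkpoint(fit$model, file.path(out_dir, "checkpoint.rds"))
  readr::write_csv(fit$history, file.path(out_dir, "history.csv"),
                   progress = FALSE)
  ev <- dta_evaluate(fit, sp$val, cache = cache)
  jsonlite::write_json(as.list(ev$metrics), file.path(out_dir,
                                                      "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(fit = fit, split = sp, metrics = ev$metrics))
}

#' Evaluate a checkpoint on a dataset split
#'
#' @param checkpoint Path to a checkpoint from [run_train()] /
#'   [save_checkpoint()].
#' @param data_dir Dataset directory.
#' @param manifest Path to a split manifest CSV; its `test` rows are
#'   evaluated.
#' @param out_file Optional JSON output path.
#' @return List with `predictions` and `metrics`.
#' @export
run_eval <- function(checkpoint, data_dir, manifest, out_file = NULL) {
  model <- load_checkpoint(checkpoint)
  ds <- read_dataset(data_dir)
  if (!file.exists(manifest)) {
    abort(sprintf("%s: split manifest not found.", manifest))
  }
  man <- readr::read_csv(manifest, col_types = "ccc", progress = FALSE)
  test_ids <- dplyr::filter(man, .data$split == "test")
  pairs <- dplyr::inner_join(ds$interactions, test_ids,
                             by = c("drug_id", "protein_id")) |>
    dplyr::select("drug_id", "protein_id", "affinity")
  cache <- featurize_entities(ds$proteins, ds$drugs, model$config)
  ev <- dta_evaluate(model, pairs, cache = cache)
  if (!is.null(out_file)) {
    jsonlite::write_json(as.list(ev$metrics), out_file, auto_unbox = TRUE,
                         digits = NA)
  }
  ev
}

#' Compare two metric reports as relative improvements
#'
#' Reads two metric JSON files (as written by [run_train()] / [run_eval()])
#' and reports the percentage change of each shared metric, phrased in
#' its conventional direction: decreases for `mse`, increases for `ci`
#' and `rm2`.
#'
#' @param reference_json,new_json Paths to metric JSON files (or named
#'   lists).
#' @return A tibble with `metric`, `reference`, `new`, `change_pct`.
#' @export
compare_runs <- function(reference_json, new_json) {
  load_one <- function(x) {
    if (is.character(x)) jsonlite::read_json(x) else x
  }
  ref_v <- load_one(reference_json)
  new_v <- load_one(new_json)
  metrics <- intersect(intersect(names(ref_v), names(new_v)),
                       c("mse", "ci", "rm2"))
  if (length(metrics) == 0L) abort("no shared metrics to compare.")
  changes <- unname(vapply(metrics, function(m) {
    relative_change(as.numeric(ref_v[[m]]), as.numeric(new_v[[m]]),
                    if (m == "mse") "decrease" else "increase")
  }, numeric(1)))
  tibble::tibble(
    metric = metrics,
    reference = unname(vapply(ref_v[metrics], as.numeric, numeric(1))),
    new = unname(vapply(new_v[metrics], as.numeric, numeric(1))),
    change_pct = changes)
}

#' Rank candidate drugs against targets with a trained model
#'
#' Screens every drug against every protein (or the provided pair list),
#' sorting by predicted affinity (descending, ties broken by `drug_id`).
#' Drugs whose SMILES cannot be parsed are skipped with a warning.
#'
#' @param checkpoint Checkpoint path.
#' @param data_dir Dataset directory providing proteins and drug
#'   embeddings.
#' @param drugs Optional tibble (`drug_id`, `smiles`) or path to a drugs
#'   CSV of candidate compounds to screen instead of the dataset's drugs;
#'   their token embeddings come from the synthetic character-token
#'   provider.
#' @param top_n Optional truncation of the ranked list.
#' @param out_file Optional predictions CSV path.
#' @return Ranked predictions tibble with a `rank` column.
#' @export
run_predict <- function(checkpoint, data_dir, drugs = NULL, top_n = NULL,
                        out_file = NULL) {
  model <- load_checkpoint(checkpoint)
  ds <- read_dataset(data_dir)
  if (!is.null(drugs)) {
    if (is.character(drugs)) drugs <- read_drug_table(drugs)
    recs <- lapply(seq_len(nrow(drugs)), function(i) {
      n_tok <- nchar(drugs$smiles[i])
      emb <- with_seed(hash_seed("drug-emb", drugs$smiles[i],
                                 model$config$seed), {
        matrix(rnorm(n_tok * model$config$drug_embed_dim) /
                 sqrt(model$config$drug_embed_dim), n_tok,
               model$config$drug_embed_dim)
      })
      drug_record(drugs$drug_id[i], drugs$smiles[i], embeddings = emb,
                  embed_dim = model$config$drug_embed_dim)
    })
    names(recs) <- drugs$drug_id
    ds$drugs <- recs
  }
  keep <- names(ds$drugs)
  parse_ok <- vapply(ds$drugs, function(d) {
    isTRUE(mol_bridge(d$smiles)[[1L]]$ok)
  }, logical(1))
  if (any(!parse_ok)) {
    warn(sprintf("skipping %d drug(s) with unparseable SMILES: %s",
                 sum(!parse_ok),
                 paste(keep[!parse_ok], collapse = ", ")))
    ds$drugs <- ds$drugs[parse_ok]
  }
  pairs <- tidyr::crossing(drug_id = names(ds$drugs),
                           protein_id = names(ds$proteins))
  cache <- featurize_entities(ds$proteins, ds$drugs, model$config)
  preds <- predict_affinity(model, pairs, cache = cache)
  ranked <- dplyr::arrange(preds, dplyr::desc(.data$y_pred), .data$drug_id)
  ranked <- dplyr::mutate(ranked, rank = dplyr::row_number())
  if (!is.null(top_n)) ranked <- dplyr::slice_head(ranked, n = top_n)
  if (!is.null(out_file)) write_predictions(ranked, out_file)
  attr(ranked, "n_skipped") <- sum(!parse_ok)
  structure(ranked, class = c("dta_predictions", class(ranked)))
}
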