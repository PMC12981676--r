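# Warm and cold-start dataset splitting.

#' Splitting protocol specification
#'
#' @param mode One of `"warm"` (random pair-level split; entities may
#'   recur across splits but a pair never does), `"unseen_drug"` /
#'   `"unseen_protein"` (all pairs of a held-out entity follow it into
#'   its split), `"all_unseen"` (drug and protein identifiers are
#'   partitioned independently; a pair is kept only when both ids fall in
#'   the same bucket, mixed pairs are discarded).
#' @param ratios Train/validation/test fractions summing to 1 (default
#'   8:1:1).
#' @param seed Integer seed.
#' @return A `split_spec` list.
#' @export
split_spec <- function(mode = c("warm", "unseen_drug", "unseen_protein",
                                "all_unseen"),
                       ratios = c(0.8, 0.1, 0.1), seed = 1L) {
  mode <- match.arg(mode)
  if (length(ratios) != 3L || abs(sum(ratios) - 1) > 1e-8 ||
      any(ratios <= 0)) {
    abort("`ratios` must be three positive fractions summing to 1.")
  }
  structure(list(mode = mode, ratios = ratios, seed = as.integer(seed)),
            class = "split_spec")
}

# Partition `n` shuffled items: test and val get floor(ratio * n), the
# remainder goes to train.
partition_sizes <- function(n, ratios) {
  n_val <- floor(ratios[2L] * n)
  n_test <- floor(ratios[3L] * n)
  c(train = n - n_val - n_test, val = n_val, test = n_test)
}

assign_buckets <- function(ids, ratios) {
  sz <- partition_sizes(length(ids), ratios)
  stats::setNames(rep(c("train", "val", "test"), sz), sample(ids))
}

#' Split an interaction table into train/validation/test
#'
#' @param interactions Tibble with `drug_id`, `protein_id`, `affinity`.
#' @param spec A [split_spec()].
#' @return A `dta_split` list with tibbles `train`, `val`, `test`, a
#'   `manifest` tibble (`drug_id`, `protein_id`, `split`, where discarded
#'   mixed-bucket pairs of the all-unseen mode are marked `"discarded"`)
#'   and `info` (counts and discard fraction).
#' @export
split_dataset <- function(interactions, spec = split_spec()) {
  stopifnot(inherits(spec, "split_spec"))
  n <- nrow(interactions)
  if (n < 10L) abort(sprintf("need >= 10 interactions, got %d.", n))
  check_entities <- function(ids, kind) {
    if (length(unique(ids)) < 10L) {
      abort(sprintf("mode '%s' needs >= 10 distinct %ss, got %d.",
                    spec$mode, kind, length(unique(ids))))
    }
  }
  out <- with_seed(spec$seed, {
    switch(spec$mode,
      warm = {
        sz <- partition_sizes(n, spec$ratios)
        lab <- sample(rep(c("train", "val", "test"), sz))
        lab
      },
      unseen_drug = {
        check_entities(interactions$drug_id, "drug")
        b <- assign_buckets(unique(interactions$drug_id), spec$ratios)
        unname(b[interactions$drug_id])
      },
      unseen_protein = {
        check_entities(interactions$protein_id, "protein")
        b <- assign_buckets(unique(interactions$protein_id), spec$ratios)
        unname(b[interactions$protein_id])
      },
      all_unseen = {
        check_entities(interactions$drug_id, "drug")
        check_entities(interactions$protein_id, "protein")
        bd <- assign_buckets(unique(interactions$drug_id), spec$ratios)
        bp <- assign_buckets(unique(interactions$protein_id), spec$ratios)
        ld <- unname(bd[interactions$drug_id])
        lp <- unname(bp[interactions$protein_id])
        ifelse(ld == lp, ld, "discarded")
      })
  })
  manifest <- dplyr::mutate(interactions, split = out)
  pick <- function(lab) {
    dplyr::select(dplyr::filter(manifest, .data$split == lab), -"split")
  }
  res <- list(train = pick("train"), val = pick("val"), test = pick("test"),
              manifest = manifest,
              info = list(mode = spec$mode, n = n,
                          n_discarded = sum(out == "discarded"),
                          discard_fraction = mean(out == "discarded"),
                          seed = spec$seed))
  structure(res, class = "dta_split")
}

#' @export
print.dta_split <- function(x, ...) {
  cat(sprintf("<dta_split> mode %s: %d train / %d val / %d test",
              x$info$mode, nrow(x$train), nrow(x$val), nrow(x$test)))
  if (x$info$n_discarded > 0L) {
    cat(sprintf(" (%d mixed pairs discarded, %.1f%%)", x$info$n_discarded,
                100 * x$info$discard_fraction))
  }
  cat("\n")
  invisible(x)
}

#' Write a split manifest CSV
#'
#' @param split A `dta_split`.
#' @param path Output CSV path (`drug_id`, `protein_id`, `split`).
#' @export
write_split_manifest <- function(split, path) {
  readr::write_csv(dplyr::select(split$manifest, "drug_id", "protein_id",
                                 "split"), path, progress = FALSE)
  invisible(path)
}
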