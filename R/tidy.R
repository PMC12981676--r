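# broom-style accessors for fitted objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a fitted affinity model
#'
#' One row per parameter tensor with its shape and norms; a quick view of
#' where capacity sits in the network.
#'
#' @param x A `dta_fit` (or `dta_model`).
#' @param ... Unused.
#' @return A tibble with `parameter`, `rows`, `cols`, `n`, `l2` and
#'   `mean_abs`.
#' @export
tidy.dta_fit <- function(x, ...) {
  model <- if (inherits(x, "dta_fit")) x$model else x
  flat <- flatten_params(model$params)
  tibble::tibble(
    parameter = sub("^\\.", "", names(flat)),
    rows = vapply(flat, nrow, integer(1)),
    cols = vapply(flat, ncol, integer(1)),
    n = vapply(flat, length, integer(1)),
    l2 = vapply(flat, function(m) sqrt(sum(m^2)), numeric(1)),
    mean_abs = vapply(flat, function(m) mean(abs(m)), numeric(1)))
}

#' @rdname tidy.dta_fit
#' @export
tidy.dta_model <- tidy.dta_fit

#' One-row summary of a fit
#'
#' @param x A `dta_fit`.
#' @param ... Unused.
#' @return A tibble with epoch counts, best validation MSE, head type and
#'   parameter count.
#' @export
glance.dta_fit <- function(x, ...) {
  flat <- flatten_params(x$model$params)
  tibble::tibble(
    epochs_run = nrow(x$history),
    best_epoch = x$best_epoch,
    best_val_mse = x$best_val,
    final_train_mse = x$history$train_mse[nrow(x$history)],
    head = if (x$model$config$use_kan) "kan" else "mlp",
    n_parameters = sum(vapply(flat, length, integer(1))))
}

#' Tidy a repeated-experiment report
#'
#' @param x A `metric_repeats` from [repeat_experiment()].
#' @param ... Unused.
#' @return The summary tibble (`metric`, `mean`, `sd`, `label`).
#' @export
tidy.metric_repeats <- function(x, ...) x$summary
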