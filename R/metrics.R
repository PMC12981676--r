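# Affinity-regression metric suite: MSE, concordance index, r_m^2,
# relative-change reporting, and repeated-run aggregation.

#' Mean squared error
#'
#' @param y True values.
#' @param p Predicted values.
#' @return `mean((y - p)^2)`.
#' @export
mse <- function(y, p) {
  if (length(y) != length(p)) {
    abort(sprintf("length mismatch: %d true vs %d predicted.",
                  length(y), length(p)))
  }
  if (length(y) == 0L) abort("empty input.")
  mean((y - p)^2)
}

#' Concordance index
#'
#' Over all ordered pairs with `y_i > y_j`, credits 1 when `p_i > p_j`,
#' 0.5 when tied, 0 otherwise, normalized by the number of such pairs.
#' Prediction ties therefore pull the index toward 0.5; ties in `y`
#' contribute nothing.
#'
#' @param y True values (at least one strict inequality required).
#' @param p Predicted values.
#' @return Concordance index in \[0, 1\].
#' @export
concordance_index <- function(y, p) {
  if (length(y) != length(p)) {
    abort(sprintf("length mismatch: %d true vs %d predicted.",
                  length(y), length(p)))
  }
  if (length(y) < 2L) abort("need at least 2 samples.")
  dy <- outer(y, y, ">")
  if (!any(dy)) abort("all true values are equal: concordance undefined.")
  dp <- outer(p, p, "-")
  credit <- (dp > 0) + 0.5 * (dp == 0)
  sum(credit[dy]) / sum(dy)
}

#' External-validation r_m^2
#'
#' `r_m^2 = r^2 * (1 - sqrt(r^2 - r0^2))`, where `r^2` is the squared
#' Pearson correlation of predictions and observations and `r0^2` is the
#' coefficient of determination of the least-squares fit of `y` on `p`
#' through the origin (`r0^2 = 1 - sum((y - k p)^2) / sum((y - mean(y))^2)`
#' with `k = sum(y p) / sum(p^2)`). The radicand is clamped at zero.
#'
#' @param y True values.
#' @param p Predicted values.
#' @return The r_m^2 statistic.
#' @export
rm_squared <- function(y, p) {
  if (length(y) != length(p)) {
    abort(sprintf("length mismatch: %d true vs %d predicted.",
                  length(y), length(p)))
  }
  if (length(y) < 3L) abort("need at least 3 samples.")
  if (stats::sd(y) == 0 || stats::sd(p) == 0) {
    abort("zero variance in y or p: r_m^2 undefined.")
  }
  r2 <- stats::cor(p, y)^2
  k <- sum(y * p) / sum(p * p)
  r02 <- 1 - sum((y - k * p)^2) / sum((y - mean(y))^2)
  r2 * (1 - sqrt(max(r2 - r02, 0)))
}

#' Relative change between a reference and a new metric value
#'
#' For decrease-phrased metrics (MSE) reports
#' `100 * (reference - new) / reference`; for increase-phrased metrics
#' (CI, r_m^2) reports `100 * (new - reference) / reference`. Rounded to
#' two decimals, matching the conventional reporting style.
#'
#' @param reference Baseline value (nonzero).
#' @param new New value.
#' @param direction `"decrease"` or `"increase"`.
#' @return Signed percentage, rounded to 2 decimals.
#' @export
relative_change <- function(reference, new,
                            direction = c("decrease", "increase")) {
  direction <- match.arg(direction)
  if (reference == 0) abort("reference value must be nonzero.")
  pct <- if (direction == "decrease") {
    100 * (reference - new) / reference
  } else {
    100 * (new - reference) / reference
  }
  round(pct, 2L)
}

#' Compute the full metric report for a set of predictions
#'
#' @param y True values.
#' @param p Predicted values.
#' @return A one-row tibble with `mse`, `ci`, `rm2` and `n`.
#' @export
metric_report <- function(y, p) {
  tibble::tibble(mse = mse(y, p), ci = concordance_index(y, p),
                 rm2 = rm_squared(y, p), n = length(y))
}

#' Format a metric as "mean (sd)"
#'
#' @param mean_val,sd_val Numbers to format.
#' @param digits Decimal places (default 3).
#' @return A string such as `"0.204 (0.005)"`.
#' @export
format_mean_sd <- function(mean_val, sd_val, digits = 3L) {
  sprintf(paste0("%.", digits, "f (%.", digits, "f)"), mean_val, sd_val)
}

#' Repeat an experiment across seeds and aggregate
#'
#' Runs `run_fn(seed + 0), ..., run_fn(seed + n_repeats - 1)`; each call
#' must return a named numeric vector of metrics. The summary uses the
#' sample standard deviation (n - 1 denominator).
#'
#' @param run_fn Function of one integer seed.
#' @param seed Base seed.
#' @param n_repeats Number of repeats (default 5).
#' @return A `metric_repeats` list with the per-seed tibble and a summary
#'   tibble (`metric`, `mean`, `sd`, `label`).
#' @export
repeat_experiment <- function(run_fn, seed = 1L, n_repeats = 5L) {
  stopifnot(is.function(run_fn), is_count(n_repeats))
  runs <- lapply(seq_len(n_repeats) - 1L, function(k) {
    out <- run_fn(as.integer(seed + k))
    tibble::tibble(seed = seed + k, metric = names(out),
                   value = as.numeric(out))
  })
  per_seed <- dplyr::bind_rows(runs)
  summary <- per_seed |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(mean = mean(.data$value),
                     sd = if (dplyr::n() > 1L) stats::sd(.data$value) else 0,
                     .groups = "drop") |>
    dplyr::mutate(label = format_mean_sd(.data$mean, .data$sd))
  structure(list(per_seed = per_seed, summary = summary,
                 n_repeats = n_repeats), class = "metric_repeats")
}

#' @export
print.metric_repeats <- function(x, ...) {
  cat(sprintf("<metric_repeats> %d repeats\n", x$n_repeats))
  for (i in seq_len(nrow(x$summary))) {
    cat(sprintf("  %-6s %s\n", x$summary$metric[i], x$summary$label[i]))
  }
  invisible(x)
}
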