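# ggplot2 visualizations for fits and predictions.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point
#'   geom_abline geom_vline labs theme_minimal scale_colour_manual
NULL

#' Plot training and validation curves of a fit
#'
#' @param object A `dta_fit` from [dta_train()].
#' @param ... Unused.
#' @return A ggplot object (MSE per epoch, best epoch marked).
#' @export
autoplot.dta_fit <- function(object, ...) {
  long <- tidyr::pivot_longer(object$history, c("train_mse", "val_mse"),
                              names_to = "set", values_to = "mse")
  long$set <- ifelse(long$set == "train_mse", "train", "validation")
  ggplot(long, aes(x = .data$epoch, y = .data$mse,
                   colour = .data$set)) +
    geom_line() +
    geom_vline(xintercept = object$best_epoch, linetype = "dashed",
               colour = "grey50") +
    scale_colour_manual(values = c(train = "#2c7fb8",
                                   validation = "#de2d26")) +
    labs(x = "epoch", y = "mean squared error", colour = NULL,
         title = "Training history",
         subtitle = sprintf("best validation MSE %.4f at epoch %d",
                            object$best_val, object$best_epoch)) +
    theme_minimal()
}

#' Plot predicted versus observed affinities
#'
#' @param object A `dta_predictions` tibble (from [dta_evaluate()] or
#'   [run_predict()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dta_predictions <- function(object, ...) {
  df <- object[!is.na(object$y_true), , drop = FALSE]
  if (nrow(df) == 0L) abort("no observed affinities to plot against.")
  ggplot(df, aes(x = .data$y_true, y = .data$y_pred)) +
    geom_point(alpha = 0.5, colour = "#2c7fb8") +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                colour = "grey40") +
    labs(x = "observed affinity", y = "predicted affinity",
         title = "Predicted vs observed") +
    theme_minimal()
}

#' Plot a contact map with its thresholded graph edges
#'
#' @param record A [protein_record()] with a contact matrix.
#' @param spec A [contact_graph_spec()].
#' @return A ggplot object (tile map; retained edges outlined).
#' @export
plot_contact_map <- function(record, spec = contact_graph_spec()) {
  stopifnot(inherits(record, "protein_record"))
  M <- record$contact
  if (is.null(M)) abort("record has no contact matrix.")
  df <- tidyr::expand_grid(i = seq_len(nrow(M)), j = seq_len(ncol(M)))
  df$p <- as.vector(M)
  ggplot(df, aes(x = .data$j, y = .data$i, fill = .data$p)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "#08306b",
                                 limits = c(0, 1)) +
    ggplot2::scale_y_reverse() +
    labs(x = "residue", y = "residue", fill = "contact\nprobability",
         title = record$protein_id,
         subtitle = sprintf("edges: contact > %.2f", spec$threshold)) +
    theme_minimal()
}
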