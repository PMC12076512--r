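# ggplot2 visualizations for the main result types.

#' @importFrom ggplot2 ggplot aes geom_line geom_point geom_col geom_histogram
#'   geom_errorbar geom_boxplot facet_wrap labs theme_minimal autoplot
NULL

#' @export
ggplot2::autoplot

#' Training curves of a fingerprint-to-sequence model
#'
#' Reconstruction and weighted KL terms per epoch.
#'
#' @param object a `profis_model`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.profis_model <- function(object, ...) {
  df <- object$loss_log |>
    dplyr::mutate(weighted_kld = .data$beta_t * .data$kld) |>
    tidyr::pivot_longer(c("reconstruction", "weighted_kld", "total"),
                        names_to = "term", values_to = "value")
  ggplot(df, aes(x = .data$epoch, y = .data$value, colour = .data$term)) +
    geom_line() +
    labs(x = "epoch", y = "loss", colour = NULL,
         title = "Training loss decomposition") +
    theme_minimal()
}

#' Cross-validation performance per classifier family
#'
#' @param object a `profis_cv` report.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.profis_cv <- function(object, ...) {
  ggplot(object$summary,
         aes(x = .data$model, y = .data$roc_auc_mean)) +
    geom_col(fill = "steelblue") +
    geom_errorbar(aes(ymin = .data$roc_auc_mean - .data$roc_auc_sd,
                      ymax = .data$roc_auc_mean + .data$roc_auc_sd),
                  width = 0.2) +
    labs(x = NULL, y = "ROC-AUC (mean +- sd over outer folds)",
         title = "Nested cross-validation") +
    theme_minimal()
}

#' Tanimoto-distance distribution of an analog library
#'
#' @param object a `profis_analogs` report.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.profis_analogs <- function(object, ...) {
  ggplot(object$analogs, aes(x = .data$tanimoto_to_seed)) +
    geom_histogram(bins = 20, fill = "darkorange", colour = "white") +
    labs(x = "Tanimoto distance to seed molecule", y = "analogs",
         title = paste0("Analogs of ", object$seed_smiles,
                        " (k = ", object$k_flips, " flipped bits)")) +
    theme_minimal()
}

#' Prediction error across distance-to-model bins
#'
#' @param profile output of [dm_error_profile()].
#' @return a ggplot object.
#' @export
plot_dm_profile <- function(profile) {
  df <- dplyr::mutate(profile, bin = factor(.data$bin, levels = .data$bin))
  ggplot(df, aes(x = .data$bin, y = .data$median_abs_error)) +
    geom_col(fill = "firebrick") +
    labs(x = "distance to model (SCAvg complement)",
         y = "median absolute error",
         title = "Applicability domain profile") +
    theme_minimal()
}

#' Property distributions of a generated library
#'
#' @param props output of [property_profile()].
#' @return a ggplot object.
#' @export
plot_property_profile <- function(props) {
  df <- props |>
    dplyr::filter(.data$descriptor_ok) |>
    tidyr::pivot_longer(c("qed", "clogp", "tpsa", "hba", "hbd", "mw"),
                        names_to = "property", values_to = "value")
  ggplot(df, aes(x = .data$value)) +
    geom_histogram(bins = 20, fill = "seagreen", colour = "white") +
    facet_wrap(~property, scales = "free") +
    labs(x = NULL, y = "molecules", title = "Library property profile") +
    theme_minimal()
}
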