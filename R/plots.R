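# ggplot2 views of the result objects. These return plots, never print.

#' Heat map of per-patient log attention weights
#'
#' @param object An [extract_attention()] matrix.
#' @param sample_n,seed,base Passed to [heatmap_matrix()].
#' @param ... Unused.
#' @return A ggplot: patients on the y axis, features on the x axis, fill =
#'   log attention weight.
#' @method autoplot attention_matrix
#' @export
autoplot.attention_matrix <- function(object, sample_n = 50L, seed = 1L,
                                      base = exp(1), ...) {
  sample_n <- min(sample_n, nrow(object))
  hm <- heatmap_matrix(object, sample_n = sample_n, seed = seed, base = base)
  df <- as_tibble(as.data.frame(as.table(hm)))
  names(df) <- c("patient", "feature", "log_weight")
  ggplot(df, aes(x = .data$feature, y = .data$patient,
                 fill = .data$log_weight)) +
    geom_tile() +
    scale_fill_viridis_c(name = "log attention") +
    labs(x = "Feature", y = "Patient") +
    theme_minimal() +
    theme(axis.text.x = element_blank(), axis.text.y = element_blank())
}

#' Bar chart of one patient's top attention weights
#'
#' @param ranking A [rank_patient_features()] tibble.
#' @param title Optional plot title.
#' @return A ggplot bar chart, largest weight on top.
#' @export
plot_patient_attention <- function(ranking, title = NULL) {
  stopifnot(is.data.frame(ranking), all(c("feature", "weight") %in% names(ranking)))
  ggplot(ranking, aes(x = stats::reorder(.data$feature, .data$weight),
                      y = .data$weight)) +
    geom_col(fill = "#2c7fb8") +
    coord_flip() +
    labs(x = NULL, y = "Attention weight", title = title) +
    theme_minimal()
}

#' Performance against the number of hidden layers
#'
#' @param sweep A [hidden_layer_sweep()] table.
#' @param metric `"accuracy"` or `"auc"`.
#' @return A ggplot of mean metric (with per-repetition points) per depth
#'   and model.
#' @export
plot_hidden_layer_sweep <- function(sweep, metric = c("accuracy", "auc")) {
  metric <- match.arg(metric)
  means <- sweep |>
    dplyr::group_by(.data$model, .data$depth) |>
    dplyr::summarise(value = mean(.data[[metric]]), .groups = "drop")
  ggplot(means, aes(x = .data$depth, y = .data$value,
                    colour = .data$model)) +
    geom_line() +
    geom_point() +
    labs(x = "Hidden layers", y = metric, colour = "Model") +
    theme_minimal()
}

#' Metric summaries of a protocol run
#'
#' @param object A `protocol_result`.
#' @param ... Unused.
#' @return A ggplot of mean ± sd per model and metric.
#' @method autoplot protocol_result
#' @export
autoplot.protocol_result <- function(object, ...) {
  ggplot(object$summary,
         aes(x = .data$model, y = .data$mean, fill = .data$model)) +
    geom_col(show.legend = FALSE) +
    geom_errorbar(aes(ymin = .data$mean - .data$sd,
                      ymax = .data$mean + .data$sd), width = 0.2) +
    facet_wrap(~metric) +
    labs(x = NULL, y = "Score") +
    theme_minimal()
}

#' Training-history curve of a fitted network
#'
#' @param object An `attn_model`, `mlp_model` or `sdae_model`.
#' @param ... Unused.
#' @return A ggplot of training (and validation) loss by epoch.
#' @method autoplot risk_model
#' @export
autoplot.risk_model <- function(object, ...) {
  df <- object$history |>
    tidyr::pivot_longer(c("train_loss", "val_loss"), names_to = "set",
                        values_to = "loss") |>
    dplyr::filter(!is.na(.data$loss))
  ggplot(df, aes(x = .data$epoch, y = .data$loss, colour = .data$set)) +
    geom_line() +
    labs(x = "Epoch", y = "Loss", colour = NULL) +
    theme_minimal()
}
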