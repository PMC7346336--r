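# broom-style tidiers for the fitted objects.

#' Tidy a fitted logistic baseline
#'
#' @param x A `logit_model`.
#' @param ... Unused.
#' @return A tibble with one row per term (`(Intercept)` first):
#'   `term`, `estimate`.
#' @method tidy logit_model
#' @export
tidy.logit_model <- function(x, ...) {
  tibble(term = c("(Intercept)", names(x$coefficients)),
         estimate = c(x$intercept, unname(x$coefficients)))
}

#' @rdname tidy.logit_model
#' @method glance logit_model
#' @export
glance.logit_model <- function(x, ...) {
  tibble(n_features = length(x$coefficients), l2 = x$l2,
         converged = x$converged)
}

#' Tidy a fitted network model
#'
#' For an attention model, one row per feature with that feature's mean
#' attention logit bias; for any network, the per-layer weight norms.
#'
#' @param x An `attn_model`, `mlp_model` or `sdae_model`.
#' @param ... Unused.
#' @return A tibble with columns `component`, `term`, `value`.
#' @method tidy risk_model
#' @export
tidy.risk_model <- function(x, ...) {
  rows <- list()
  if (!is.null(x$params$attn)) {
    rows[[1L]] <- tibble(component = "attention_bias",
                         term = x$feature_names,
                         value = as.numeric(x$params$attn$b))
    rows[[2L]] <- tibble(component = "attention_weight_norm",
                         term = "W", value = sqrt(sum(x$params$attn$W^2)))
  }
  layer_norms <- vapply(x$params$layers, function(l) sqrt(sum(l$W^2)),
                        numeric(1))
  rows[[length(rows) + 1L]] <- tibble(
    component = "layer_weight_norm",
    term = sprintf("layer_%d", seq_along(layer_norms)),
    value = layer_norms)
  dplyr::bind_rows(rows)
}

#' @rdname tidy.risk_model
#' @method glance risk_model
#' @export
glance.risk_model <- function(x, ...) {
  h <- x$history
  tibble(
    n_features = length(x$feature_names),
    n_layers = length(x$params$layers),
    epochs_run = max(h$epoch),
    best_epoch = x$best_epoch,
    initial_loss = h$train_loss[h$epoch == 0],
    final_loss = h$train_loss[nrow(h)]
  )
}

#' Tidy a protocol result
#'
#' @param x A `protocol_result`.
#' @param ... Unused.
#' @return The per-model, per-repetition metric table in long form.
#' @method tidy protocol_result
#' @export
tidy.protocol_result <- function(x, ...) {
  x$metrics |>
    tidyr::pivot_longer(c("accuracy", "precision", "recall", "f1", "auc"),
                        names_to = "metric", values_to = "value")
}

#' @rdname tidy.protocol_result
#' @method glance protocol_result
#' @export
glance.protocol_result <- function(x, ...) {
  tibble(n_models = length(x$model_names),
         n_repeats = x$config$n_repeats,
         n_folds = x$config$n_folds,
         train_fraction = x$config$train_fraction)
}
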