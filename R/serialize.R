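# Model persistence: a single JSON file holding the config, the shapes and
# the parameter arrays at full double precision, so a reloaded model
# reproduces forward outputs exactly.

#' Save and load fitted models
#'
#' Serializes a fitted `attn_model`, `mlp_model`, `sdae_model` or
#' `logit_model` to one JSON file (parameters stored at full precision) and
#' restores it; a round-tripped model reproduces forward-pass outputs to
#' within 1e-12.
#'
#' @param model A fitted model.
#' @param path Output JSON path.
#' @return `write_model` returns `path` invisibly; `read_model` the restored
#'   model.
#' @export
write_model <- function(model, path) {
  kind <- class(model)[1L]
  if (!kind %in% c("attn_model", "mlp_model", "sdae_model", "logit_model")) {
    abort("Unsupported model class for serialization.")
  }
  payload <- list(kind = kind, feature_names = model$feature_names)
  if (kind == "logit_model") {
    payload$coefficients <- unname(model$coefficients)
    payload$intercept <- model$intercept
    payload$l2 <- model$l2
    payload$converged <- model$converged
    payload$threshold <- model$threshold
  } else {
    payload$config <- unclass(model$config)
    payload$attention <- model$attention
    payload$best_epoch <- model$best_epoch
    payload$params <- serialize_params(model$params)
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

serialize_params <- function(params) {
  ser_layer <- function(l) list(W = list(dim = dim(l$W), x = as.numeric(l$W)),
                                b = as.numeric(l$b))
  out <- list(layers = lapply(params$layers, ser_layer))
  if (!is.null(params$attn)) out$attn <- ser_layer(params$attn)
  out
}

deserialize_params <- function(ser) {
  de_layer <- function(l) list(
    W = matrix(as.numeric(l$W$x), l$W$dim[[1L]], l$W$dim[[2L]]),
    b = as.numeric(l$b))
  out <- list()
  if (!is.null(ser$attn)) out$attn <- de_layer(ser$attn)
  out$layers <- lapply(ser$layers, de_layer)
  out
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE,
                                 simplifyMatrix = FALSE)
  kind <- payload$kind
  if (kind == "logit_model") {
    return(structure(list(
      coefficients = setNames(as.numeric(payload$coefficients),
                              payload$feature_names),
      intercept = payload$intercept, l2 = payload$l2,
      converged = payload$converged,
      feature_names = payload$feature_names, threshold = payload$threshold
    ), class = "logit_model"))
  }
  cfg <- payload$config
  class(cfg) <- if (kind == "sdae_model") "sdae_config" else "model_config"
  structure(list(
    params = deserialize_params(payload$params), config = cfg,
    feature_names = payload$feature_names,
    history = tibble(epoch = integer(), train_loss = numeric(),
                     val_loss = numeric()),
    best_epoch = payload$best_epoch, attention = isTRUE(payload$attention)
  ), class = c(kind, "risk_model"))
}
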