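#' Configuration for the attention-gated network and the plain MLP
#'
#' Bundles the architecture and optimization settings. Defaults follow common
#' practice for small tabular networks: one hidden ReLU layer of width 64,
#' Adam at learning rate 0.001, L2 weight penalty `lambda = 0.001` on all
#' weight matrices (biases exempt), mini-batches of 32, up to 300 epochs with
#' early stopping on a 10% validation split (patience 20), and a 0.5
#' classification threshold applied strictly (`prob > threshold` maps to 1).
#'
#' @param n_hidden_layers Number of hidden layers, 1 to 5.
#' @param hidden_width Units per hidden layer.
#' @param learning_rate Adam step size.
#' @param lambda L2 penalty coefficient on weight matrices.
#' @param threshold Classification threshold in `(0, 1)`.
#' @param epochs Maximum training epochs.
#' @param batch_size Mini-batch size.
#' @param patience Early-stopping patience in epochs; `0` disables early
#'   stopping and the validation split.
#' @param validation_fraction Fraction of the training data held out to
#'   monitor early stopping.
#' @param activation Hidden-layer nonlinearity: `"relu"` (default),
#'   `"tanh"` or `"linear"`.
#' @param seed Integer seed controlling initialization, batching and the
#'   validation split.
#' @return A list of class `model_config`.
#' @export
model_config <- function(n_hidden_layers = 1L, hidden_width = 64L,
                         learning_rate = 0.001, lambda = 0.001,
                         threshold = 0.5, epochs = 300L, batch_size = 32L,
                         patience = 20L, validation_fraction = 0.1,
                         activation = "relu", seed = 1L) {
  if (n_hidden_layers < 1L || n_hidden_layers > 5L) {
    abort("`n_hidden_layers` must be between 1 and 5.")
  }
  if (threshold <= 0 || threshold >= 1) abort("`threshold` must be in (0, 1).")
  if (learning_rate <= 0) abort("`learning_rate` must be positive.")
  if (lambda < 0) abort("`lambda` must be nonnegative.")
  structure(list(
    n_hidden_layers = as.integer(n_hidden_layers),
    hidden_width = as.integer(hidden_width),
    learning_rate = learning_rate, lambda = lambda, threshold = threshold,
    epochs = as.integer(epochs), batch_size = as.integer(batch_size),
    patience = as.integer(patience),
    validation_fraction = validation_fraction,
    activation = activation, seed = as.integer(seed)
  ), class = "model_config")
}

#' Attention weights for one patient
#'
#' Computes `softmax(W x + b)`: a probability vector over the `m` features,
#' read as each feature's contribution to this patient's prediction. The
#' softmax is max-stabilised, so any finite logits are safe.
#'
#' @param x Length-`m` numeric feature vector.
#' @param W `m`-by-`m` attention weight matrix.
#' @param b Length-`m` attention bias.
#' @return A length-`m` vector in `(0, 1)` summing to 1.
#' @export
#' @examples
#' compute_attention(c(1, 2), matrix(0, 2, 2), c(0, log(3)))  # 0.25, 0.75
compute_attention <- function(x, W, b) {
  x <- as.numeric(x)
  check_finite(x, "`x`"); check_finite(W, "`W`"); check_finite(b, "`b`")
  m <- length(x)
  if (!is.matrix(W) || nrow(W) != m || ncol(W) != m || length(b) != m) {
    abort("Dimension mismatch: `W` must be m-by-m and `b` length m.")
  }
  as.numeric(softmax_rows(matrix(as.numeric(W %*% x + b), 1L)))
}

#' Gate a feature vector by its attention weights
#'
#' Element-wise product `g_j = alpha_j * x_j`: the attended input
#' representation fed to the classifier.
#'
#' @param x Length-`m` feature vector.
#' @param alpha Length-`m` attention vector (a probability simplex point).
#' @return The gated length-`m` vector.
#' @export
gate_input <- function(x, alpha) {
  if (length(x) != length(alpha)) {
    abort("`x` and `alpha` must have the same length.")
  }
  as.numeric(x) * as.numeric(alpha)
}

#' Fit the attention-gated classifier
#'
#' Trains the full model — softmax attention over the input features,
#' element-wise gating, then an MLP with sigmoid output — by minimizing the
#' mean binary cross-entropy plus `lambda` times the squared L2 norm of all
#' weight matrices, using mini-batch Adam. Attention and classifier are
#' trained jointly. Deterministic given `config$seed`.
#'
#' @param data A complete, preprocessed cohort tibble (features plus a 0/1
#'   outcome column). Features should be standardized (see
#'   [standardize_features()]) so attention magnitudes are comparable.
#' @param outcome Name of the outcome column; 1 is the positive (e.g.
#'   readmitted) class.
#' @param config A [model_config()].
#' @return An object of class `c("attn_model", "risk_model")` with the fitted
#'   parameters, the config, feature names and a per-epoch training history.
#' @seealso [predict.risk_model()], [extract_attention()], [compute_loss()]
#' @export
fit_attention <- function(data, outcome = "outcome", config = model_config()) {
  fit_network_model(data, outcome, config, attention = TRUE)
}

# Shared trainer for the attention model and the plain MLP.
fit_network_model <- function(data, outcome, config, attention) {
  stopifnot(inherits(config, "model_config"))
  mats <- cohort_matrices(data, outcome)
  check_finite(mats$X, "feature matrix")
  check_both_classes(mats$y, "training data")
  m <- ncol(mats$X)
  n <- nrow(mats$X)

  use_val <- config$patience > 0L && config$validation_fraction > 0 &&
    n >= 20L
  if (use_val) {
    tr_idx <- local_seed(config$seed + 1L,
                         stratified_first_part(mats$y, 1 - config$validation_fraction))
    val_idx <- setdiff(seq_len(n), tr_idx)
  } else {
    tr_idx <- seq_len(n)
    val_idx <- integer(0)
  }
  Xtr <- mats$X[tr_idx, , drop = FALSE]
  ytr <- mats$y[tr_idx]
  Xval <- mats$X[val_idx, , drop = FALSE]
  yval <- mats$y[val_idx]

  params <- init_params(m, rep(config$hidden_width, config$n_hidden_layers),
                        attention = attention, seed = config$seed)
  grad_fn <- function(p, idx) {
    nn_loss_grad(p, Xtr[idx, , drop = FALSE], ytr[idx], config$lambda,
                 config$activation)
  }
  loss_fn <- function(p) nn_loss_value(p, Xtr, ytr, config$lambda, config$activation)
  val_fn <- if (use_val) {
    function(p) nn_loss_value(p, Xval, yval, config$lambda, config$activation)
  } else {
    NULL
  }
  opt <- adam_optimize(params, nrow(Xtr), grad_fn, loss_fn, val_fn,
                       epochs = config$epochs, batch_size = config$batch_size,
                       lr = config$learning_rate, patience = config$patience,
                       seed = config$seed + 2L)
  structure(list(
    params = opt$params, config = config, feature_names = mats$feature_names,
    history = opt$history, best_epoch = opt$best_epoch,
    attention = attention
  ), class = c(if (attention) "attn_model" else "mlp_model", "risk_model"))
}

#' Forward pass of a fitted (or hand-built) network
#'
#' Runs attention, gating and the classifier over every row of `data` and
#' returns both the predicted probabilities and the per-patient attention
#' matrix (each row the softmax attention vector used in that patient's
#' forward pass; `NULL` for a plain MLP).
#'
#' @param model An `attn_model` or `mlp_model`.
#' @param data Cohort tibble (the outcome column, if present, is ignored) or
#'   a numeric matrix with `m` columns.
#' @param outcome Name of the outcome column to ignore, if present.
#' @return A list with `probs` (length-`n` vector in `(0, 1)`) and `alpha`
#'   (`n`-by-`m` matrix or `NULL`).
#' @export
forward_pass <- function(model, data, outcome = "outcome") {
  X <- model_matrix_from(model, data, outcome)
  nn_forward(model$params, X, model$config$activation)
}

model_matrix_from <- function(model, data, outcome) {
  if (is.matrix(data)) {
    X <- data
  } else {
    cols <- setdiff(names(data), outcome)
    if (!setequal(cols, model$feature_names)) {
      abort("`data` feature columns do not match the model's features.")
    }
    X <- as.matrix(data[model$feature_names])
  }
  if (ncol(X) != length(model$feature_names)) {
    abort(sprintf("Model expects %d features, got %d.",
                  length(model$feature_names), ncol(X)))
  }
  check_finite(X, "feature matrix")
  storage.mode(X) <- "double"
  X
}

#' Regularized cross-entropy loss of a model on a dataset
#'
#' Evaluates `-(1/n) sum_i [y_i log y'_i + (1 - y_i) log(1 - y'_i)] +
#' lambda * ||Theta||_2^2`, where `y'` are the forward-pass probabilities,
#' `Theta` collects all weight matrices (attention and classifier; biases are
#' not penalised), and probabilities are clipped to `[1e-7, 1 - 1e-7]` before
#' the logs.
#'
#' @param model An `attn_model` or `mlp_model`.
#' @param data Cohort tibble or feature matrix.
#' @param outcome Name of the 0/1 outcome column (required when `data` is a
#'   tibble); alternatively pass `y` directly with a matrix.
#' @param y Optional 0/1 label vector when `data` is a matrix.
#' @param lambda Penalty coefficient; defaults to the model's configured
#'   value.
#' @return A single nonnegative number.
#' @export
compute_loss <- function(model, data, outcome = "outcome", y = NULL,
                         lambda = NULL) {
  lambda <- lambda %||% model$config$lambda
  X <- model_matrix_from(model, data, outcome)
  if (is.null(y)) {
    if (is.matrix(data) || !outcome %in% names(data)) {
      abort("Labels required: supply `y` or a tibble with the outcome column.")
    }
    y <- data[[outcome]]
  }
  if (!all(y %in% c(0, 1))) abort("Labels must be strictly binary (0/1).")
  nn_loss_value(model$params, X, as.numeric(y), lambda,
                model$config$activation)
}

#' Predict outcome probabilities and labels
#'
#' Labels are 1 exactly when the predicted probability strictly exceeds the
#' threshold; a probability equal to the threshold maps to 0.
#'
#' @param object A fitted `attn_model`, `mlp_model` or `sdae_model`.
#' @param newdata Cohort tibble or feature matrix.
#' @param type `"response"` returns a tibble of probabilities and thresholded
#'   labels; `"prob"` a bare probability vector.
#' @param threshold Classification threshold in `(0, 1)`; defaults to the
#'   model's configured value.
#' @param outcome Outcome column name to ignore in `newdata`.
#' @param ... Unused.
#' @return A tibble with columns `.prob` and `.label` (for
#'   `type = "response"`).
#' @export
predict.risk_model <- function(object, newdata, type = c("response", "prob"),
                               threshold = NULL, outcome = "outcome", ...) {
  type <- match.arg(type)
  threshold <- threshold %||% object$config$threshold
  if (threshold <= 0 || threshold >= 1) abort("`threshold` must be in (0, 1).")
  probs <- forward_pass(object, newdata, outcome)$probs
  if (type == "prob") return(probs)
  tibble(.prob = probs, .label = as.integer(probs > threshold))
}

#' @export
print.attn_model <- function(x, ...) {
  cat(sprintf(
    "Attention-gated classifier: %d features, %d hidden layer(s) of %d (%s)\n",
    length(x$feature_names), x$config$n_hidden_layers, x$config$hidden_width,
    x$config$activation))
  cat(sprintf("Final training loss %.4f (best epoch %d)\n",
              tail_loss(x), x$best_epoch))
  invisible(x)
}

#' @export
print.mlp_model <- function(x, ...) {
  cat(sprintf("Plain MLP classifier: %d features, %d hidden layer(s) of %d (%s)\n",
              length(x$feature_names), x$config$n_hidden_layers,
              x$config$hidden_width, x$config$activation))
  cat(sprintf("Final training loss %.4f (best epoch %d)\n",
              tail_loss(x), x$best_epoch))
  invisible(x)
}

tail_loss <- function(model) {
  model$history$train_loss[nrow(model$history)]
}

#' Fit a plain MLP (no attention) with the same training engine
#'
#' Identical to [fit_attention()] except the attention layer and gating are
#' omitted: the raw feature vector feeds the MLP directly.
#'
#' @inheritParams fit_attention
#' @return An object of class `c("mlp_model", "risk_model")`.
#' @export
fit_plain_mlp <- function(data, outcome = "outcome", config = model_config()) {
  fit_network_model(data, outcome, config, attention = FALSE)
}
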