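#' Fit a logistic regression baseline
#'
#' Maximizes the Bernoulli log-likelihood, optionally ridge-penalized:
#' `-(1/n) loglik + l2 * ||beta||^2` is minimized by BFGS with analytic
#' gradients (the intercept is never penalized). With `l2 = 0` this is the
#' plain MLE and matches `stats::glm`. A small default penalty keeps the fit
#' finite under near-separation; with `l2 = 0` and (quasi-)separated data the
#' coefficients diverge and a warning reports the growing norm.
#'
#' @inheritParams fit_attention
#' @param l2 Ridge penalty coefficient, `>= 0`. Default `1e-4`.
#' @return An object of class `logit_model` with `coefficients` (named),
#'   `intercept`, `l2` and `converged`.
#' @export
fit_logistic <- function(data, outcome = "outcome", l2 = 1e-4) {
  if (l2 < 0) abort("`l2` must be nonnegative.")
  mats <- cohort_matrices(data, outcome)
  check_both_classes(mats$y, "training data")
  X <- mats$X
  y <- mats$y
  n <- nrow(X)
  m <- ncol(X)

  obj <- function(theta) {
    eta <- theta[1L] + as.numeric(X %*% theta[-1L])
    p <- plogis(eta)
    pc <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -mean(y * log(pc) + (1 - y) * log(1 - pc)) + l2 * sum(theta[-1L]^2)
  }
  grad <- function(theta) {
    p <- plogis(theta[1L] + as.numeric(X %*% theta[-1L]))
    r <- (p - y) / n
    c(sum(r), as.numeric(crossprod(X, r)) + 2 * l2 * theta[-1L])
  }
  fit <- optim(rep(0, m + 1L), obj, grad, method = "BFGS",
               control = list(maxit = 2000L, reltol = 1e-14))
  theta <- fit$par
  if (l2 == 0 && sqrt(sum(theta[-1L]^2)) > 15) {
    warn(sprintf(
      "Possible separation: unpenalized coefficient norm %.1f is diverging.",
      sqrt(sum(theta[-1L]^2))))
  }
  structure(list(
    coefficients = setNames(theta[-1L], mats$feature_names),
    intercept = theta[1L], l2 = l2, converged = fit$convergence == 0L,
    feature_names = mats$feature_names, threshold = 0.5
  ), class = "logit_model")
}

#' @export
print.logit_model <- function(x, ...) {
  cat(sprintf("Logistic regression: %d features, l2 = %g\n",
              length(x$coefficients), x$l2))
  invisible(x)
}

#' @param object A fitted `logit_model`.
#' @param newdata Cohort tibble or feature matrix.
#' @param type `"response"` for a tibble of probabilities and thresholded
#'   labels, `"prob"` for a probability vector.
#' @param threshold Classification threshold; default 0.5, strict rule.
#' @param outcome Outcome column name to ignore in `newdata`.
#' @param ... Unused.
#' @rdname fit_logistic
#' @export
predict.logit_model <- function(object, newdata, type = c("response", "prob"),
                                threshold = NULL, outcome = "outcome", ...) {
  type <- match.arg(type)
  threshold <- threshold %||% object$threshold
  if (is.matrix(newdata)) {
    X <- newdata
  } else {
    X <- as.matrix(newdata[object$feature_names])
  }
  probs <- plogis(object$intercept + as.numeric(X %*% object$coefficients))
  if (type == "prob") return(probs)
  tibble(.prob = probs, .label = as.integer(probs > threshold))
}

#' Configuration for the stacked denoising autoencoder baseline
#'
#' The SDAE is pretrained greedily: each encoder layer learns to reconstruct
#' its (uncorrupted) input from a masking-corrupted copy (random cells set to
#' zero) under squared-error loss with a linear decoder; the decoders are
#' then discarded and a sigmoid classification head on top of the encoder
#' stack is fine-tuned end-to-end with the regularized cross-entropy.
#'
#' @param layer_widths Encoder widths, outermost first. Default `c(64, 32)`
#'   (two encoding/decoding layers).
#' @param corruption_rate Probability a cell is zeroed during pretraining.
#' @param pretrain_epochs,finetune_epochs Epochs for each phase.
#' @param learning_rate Adam step size for both phases.
#' @param batch_size Mini-batch size.
#' @param lambda L2 penalty on weight matrices during fine-tuning.
#' @param threshold Classification threshold.
#' @param activation Encoder nonlinearity (`"relu"`, `"tanh"`, `"linear"`).
#' @param patience Early-stopping patience for fine-tuning (0 disables).
#' @param seed Integer seed.
#' @return A list of class `sdae_config`.
#' @export
sdae_config <- function(layer_widths = c(64L, 32L), corruption_rate = 0.2,
                        pretrain_epochs = 50L, finetune_epochs = 150L,
                        learning_rate = 0.001, batch_size = 32L,
                        lambda = 0.001, threshold = 0.5, activation = "relu",
                        patience = 0L, seed = 1L) {
  if (length(layer_widths) < 1L) abort("At least one encoder layer is required.")
  if (corruption_rate < 0 || corruption_rate >= 1) {
    abort("`corruption_rate` must be in [0, 1).")
  }
  structure(list(
    layer_widths = as.integer(layer_widths), corruption_rate = corruption_rate,
    pretrain_epochs = as.integer(pretrain_epochs),
    finetune_epochs = as.integer(finetune_epochs),
    learning_rate = learning_rate, batch_size = as.integer(batch_size),
    lambda = lambda, threshold = threshold, activation = activation,
    patience = as.integer(patience), validation_fraction = 0.1,
    seed = as.integer(seed)
  ), class = "sdae_config")
}

# One denoising-autoencoder layer: ReLU (or chosen) encoder, linear decoder,
# squared error per cell against the clean input.
pretrain_dae_layer <- function(H, width, config, layer_seed) {
  n <- nrow(H)
  d_in <- ncol(H)
  act <- activation_fun(config$activation)
  params <- local_seed(layer_seed, list(
    enc = list(W = glorot_matrix(d_in, width), b = rep(0, width)),
    dec = list(W = glorot_matrix(width, d_in), b = rep(0, d_in))
  ))
  recon_mse <- function(p, Hc, Htarget) {
    E <- act$f(Hc %*% p$enc$W + matrix(p$enc$b, nrow(Hc), width, byrow = TRUE))
    Xhat <- E %*% p$dec$W + matrix(p$dec$b, nrow(Hc), d_in, byrow = TRUE)
    mean((Htarget - Xhat)^2)
  }
  grad_fn <- function(p, idx) {
    Hb <- H[idx, , drop = FALSE]
    Hc <- Hb
    if (config$corruption_rate > 0) {
      mask <- matrix(runif(length(Hb)) < config$corruption_rate,
                     nrow(Hb), ncol(Hb))
      Hc[mask] <- 0
    }
    nb <- nrow(Hb)
    Z <- Hc %*% p$enc$W + matrix(p$enc$b, nb, width, byrow = TRUE)
    E <- act$f(Z)
    Xhat <- E %*% p$dec$W + matrix(p$dec$b, nb, d_in, byrow = TRUE)
    dXhat <- 2 * (Xhat - Hb) / (nb * d_in)
    dE <- dXhat %*% t(p$dec$W)
    dZ <- dE * act$df(Z)
    list(
      loss = mean((Hb - Xhat)^2),
      grads = list(
        enc = list(W = crossprod(Hc, dZ), b = colSums(dZ)),
        dec = list(W = crossprod(E, dXhat), b = colSums(dXhat))
      )
    )
  }
  loss_fn <- function(p) recon_mse(p, H, H)   # clean-input reconstruction
  opt <- adam_optimize(params, n, grad_fn, loss_fn, val_fn = NULL,
                       epochs = config$pretrain_epochs,
                       batch_size = config$batch_size,
                       lr = config$learning_rate, patience = 0L,
                       seed = layer_seed + 1L)
  list(enc = opt$params$enc, recon_mse = loss_fn(opt$params))
}

#' Fit the stacked denoising autoencoder classifier
#'
#' Greedy layerwise denoising pretraining followed by end-to-end fine-tuning
#' of the encoder stack plus a sigmoid head (see [sdae_config()]).
#' Deterministic given `config$seed`.
#'
#' @inheritParams fit_attention
#' @param config An [sdae_config()].
#' @return An object of class `c("sdae_model", "risk_model")`; the
#'   `pretraining` element records each layer's final clean-input
#'   reconstruction mean squared error.
#' @export
fit_sdae <- function(data, outcome = "outcome", config = sdae_config()) {
  stopifnot(inherits(config, "sdae_config"))
  mats <- cohort_matrices(data, outcome)
  check_finite(mats$X, "feature matrix")
  check_both_classes(mats$y, "training data")
  act <- activation_fun(config$activation)

  H <- mats$X
  encoders <- vector("list", length(config$layer_widths))
  recon <- numeric(length(config$layer_widths))
  for (l in seq_along(config$layer_widths)) {
    pre <- pretrain_dae_layer(H, config$layer_widths[l], config,
                              layer_seed = config$seed + 10L * l)
    encoders[[l]] <- pre$enc
    recon[l] <- pre$recon_mse
    H <- act$f(H %*% pre$enc$W +
                 matrix(pre$enc$b, nrow(H), config$layer_widths[l], byrow = TRUE))
  }

  head_params <- local_seed(config$seed + 99L, list(
    W = glorot_matrix(ncol(H), 1L), b = 0
  ))
  params <- list(layers = c(encoders, list(head_params)))

  n <- nrow(mats$X)
  use_val <- config$patience > 0L && n >= 20L
  if (use_val) {
    tr_idx <- local_seed(config$seed + 1L,
                         stratified_first_part(mats$y, 1 - config$validation_fraction))
    val_idx <- setdiff(seq_len(n), tr_idx)
  } else {
    tr_idx <- seq_len(n); val_idx <- integer(0)
  }
  Xtr <- mats$X[tr_idx, , drop = FALSE]; ytr <- mats$y[tr_idx]
  grad_fn <- function(p, idx) {
    nn_loss_grad(p, Xtr[idx, , drop = FALSE], ytr[idx], config$lambda,
                 config$activation)
  }
  loss_fn <- function(p) nn_loss_value(p, Xtr, ytr, config$lambda, config$activation)
  val_fn <- if (use_val) {
    Xval <- mats$X[val_idx, , drop = FALSE]; yval <- mats$y[val_idx]
    function(p) nn_loss_value(p, Xval, yval, config$lambda, config$activation)
  } else {
    NULL
  }
  opt <- adam_optimize(params, nrow(Xtr), grad_fn, loss_fn, val_fn,
                       epochs = config$finetune_epochs,
                       batch_size = config$batch_size,
                       lr = config$learning_rate, patience = config$patience,
                       seed = config$seed + 2L)

  structure(list(
    params = opt$params, config = config, feature_names = mats$feature_names,
    history = opt$history, best_epoch = opt$best_epoch,
    pretraining = tibble(layer = seq_along(recon),
                         width = config$layer_widths, recon_mse = recon),
    attention = FALSE
  ), class = c("sdae_model", "risk_model"))
}

#' @export
print.sdae_model <- function(x, ...) {
  cat(sprintf("SDAE classifier: %d features, encoder widths [%s]\n",
              length(x$feature_names),
              paste(x$config$layer_widths, collapse = ", ")))
  print(x$pretraining)
  invisible(x)
}
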