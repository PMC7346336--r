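# Internal neural-network engine: parameter containers, forward/backward
# passes and an Adam loop. The attention classifier, the plain MLP and the
# SDAE all train through this code so determinism and gradient correctness
# are established once.

sigmoid <- function(z) plogis(z)

# Row-wise numerically stabilised softmax (max subtraction), so arbitrarily
# large finite logits never overflow.
softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

glorot_matrix <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(runif(n_in * n_out, -lim, lim), n_in, n_out)
}

# Parameter container: optional attention block (W m-by-m, b length m) plus a
# chain of dense layers; the final layer has one output unit (sigmoid), the
# hidden layers use `activation`. Biases start at zero, weights Glorot-uniform.
init_params <- function(m, hidden_widths, attention = TRUE, seed = 1L) {
  local_seed(seed, {
    params <- list()
    if (attention) {
      params$attn <- list(W = glorot_matrix(m, m), b = rep(0, m))
    }
    sizes <- c(m, hidden_widths, 1L)
    params$layers <- lapply(seq_len(length(sizes) - 1L), function(l) {
      list(W = glorot_matrix(sizes[l], sizes[l + 1L]), b = rep(0, sizes[l + 1L]))
    })
    params
  })
}

# Forward pass. Returns probabilities, the attention matrix (NULL for a plain
# MLP) and, when keep_cache, the intermediates backprop needs.
nn_forward <- function(params, X, activation = "relu", keep_cache = FALSE) {
  n <- nrow(X)
  act <- activation_fun(activation)
  if (!is.null(params$attn)) {
    Zl <- X %*% t(params$attn$W) +
      matrix(params$attn$b, n, length(params$attn$b), byrow = TRUE)
    A <- softmax_rows(Zl)
    dimnames(A) <- NULL
    H <- A * X
  } else {
    A <- NULL
    H <- X
  }
  L <- length(params$layers)
  Hs <- vector("list", L)   # input to each dense layer
  Zs <- vector("list", L)   # pre-activation of each dense layer
  for (l in seq_len(L)) {
    Hs[[l]] <- H
    Z <- H %*% params$layers[[l]]$W +
      matrix(params$layers[[l]]$b, n, ncol(params$layers[[l]]$W), byrow = TRUE)
    Zs[[l]] <- Z
    H <- if (l < L) act$f(Z) else sigmoid(Z)
  }
  probs <- as.numeric(H)
  out <- list(probs = probs, alpha = A)
  if (keep_cache) out$cache <- list(Hs = Hs, Zs = Zs, A = A, X = X)
  out
}

activation_fun <- function(name) {
  switch(name,
    relu    = list(f = function(z) pmax(z, 0), df = function(z) (z > 0) * 1),
    linear  = list(f = identity,               df = function(z) z * 0 + 1),
    tanh    = list(f = tanh,                   df = function(z) 1 - tanh(z)^2),
    abort(sprintf("Unknown activation '%s'.", name))
  )
}

# Mean binary cross-entropy with probabilities clipped to [eps, 1 - eps]
# before the logs, plus lambda * sum of squared weight-matrix entries
# (biases are never penalised).
nn_loss_value <- function(params, X, y, lambda, activation = "relu",
                          eps = 1e-7) {
  p <- nn_forward(params, X, activation)$probs
  pc <- pmin(pmax(p, eps), 1 - eps)
  ce <- -mean(y * log(pc) + (1 - y) * log(1 - pc))
  ce + lambda * weight_sq_norm(params)
}

weight_sq_norm <- function(params) {
  s <- if (!is.null(params$attn)) sum(params$attn$W^2) else 0
  s + sum(vapply(params$layers, function(l) sum(l$W^2), numeric(1)))
}

# Loss and analytic gradients in one pass. The gradient is exactly the
# derivative of the clipped loss: where a probability falls in the clipped
# region its cross-entropy derivative is zero.
nn_loss_grad <- function(params, X, y, lambda, activation = "relu",
                         eps = 1e-7) {
  n <- nrow(X)
  act <- activation_fun(activation)
  fw <- nn_forward(params, X, activation, keep_cache = TRUE)
  p <- fw$probs
  cache <- fw$cache
  pc <- pmin(pmax(p, eps), 1 - eps)
  loss <- -mean(y * log(pc) + (1 - y) * log(1 - pc)) +
    lambda * weight_sq_norm(params)

  inside <- (p > eps) & (p < 1 - eps)
  dp <- ifelse(inside, (-(y / pc) + (1 - y) / (1 - pc)) / n, 0)
  dZ <- matrix(dp * p * (1 - p), n, 1L)    # through the output sigmoid

  L <- length(params$layers)
  grads <- list(layers = vector("list", L))
  for (l in rev(seq_len(L))) {
    grads$layers[[l]] <- list(
      W = crossprod(cache$Hs[[l]], dZ) + 2 * lambda * params$layers[[l]]$W,
      b = colSums(dZ)
    )
    if (l > 1L) {
      dH <- dZ %*% t(params$layers[[l]]$W)
      dZ <- dH * act$df(cache$Zs[[l - 1L]])
    }
  }
  if (!is.null(params$attn)) {
    dG <- dZ %*% t(params$layers[[1L]]$W)   # gradient at the gated input
    A <- cache$A
    dA <- dG * cache$X
    dZl <- A * (dA - rowSums(dA * A))       # softmax Jacobian, row-wise
    grads$attn <- list(
      W = crossprod(dZl, cache$X) + 2 * lambda * params$attn$W,
      b = colSums(dZl)
    )
    grads <- grads[c("attn", "layers")]
  }
  list(loss = loss, grads = grads, probs = p)
}

# Apply `f` leaf-wise across parallel nested lists of numeric arrays.
map_leaves <- function(f, ...) {
  dots <- list(...)
  if (is.list(dots[[1L]])) {
    out <- vector("list", length(dots[[1L]]))
    names(out) <- names(dots[[1L]])
    for (i in seq_along(out)) {
      out[[i]] <- do.call(map_leaves, c(list(f), lapply(dots, `[[`, i)))
    }
    out
  } else {
    do.call(f, dots)
  }
}

# Mini-batch Adam with optional early stopping. `grad_fn(params, idx)` must
# return list(loss, grads); `loss_fn(params)` scores the full training set for
# the history; `val_fn(params)`, when given, drives early stopping with the
# stated patience and the best parameters are restored.
adam_optimize <- function(params, n_obs, grad_fn, loss_fn, val_fn = NULL,
                          epochs = 300L, batch_size = 32L, lr = 1e-3,
                          patience = 20L, seed = 1L,
                          beta1 = 0.9, beta2 = 0.999, adam_eps = 1e-8) {
  m_state <- map_leaves(function(x) x * 0, params)
  v_state <- map_leaves(function(x) x * 0, params)
  t_step <- 0L
  history <- list()
  best <- list(score = Inf, params = params, epoch = 0L)
  wait <- 0L

  init_train <- loss_fn(params)
  init_val <- if (!is.null(val_fn)) val_fn(params) else NA_real_
  history[[1L]] <- tibble(epoch = 0L, train_loss = init_train, val_loss = init_val)
  monitor0 <- if (!is.null(val_fn)) init_val else init_train
  best$score <- monitor0

  local_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n_obs)
      starts <- seq(1L, n_obs, by = batch_size)
      for (s in starts) {
        idx <- ord[s:min(s + batch_size - 1L, n_obs)]
        g <- grad_fn(params, idx)
        if (!is.finite(g$loss)) {
          abort(sprintf("Non-finite training loss at epoch %d; aborting fit.", ep))
        }
        t_step <- t_step + 1L
        m_state <- map_leaves(function(m, gr) beta1 * m + (1 - beta1) * gr,
                               m_state, g$grads)
        v_state <- map_leaves(function(v, gr) beta2 * v + (1 - beta2) * gr^2,
                               v_state, g$grads)
        bc1 <- 1 - beta1^t_step
        bc2 <- 1 - beta2^t_step
        params <- map_leaves(function(p, m, v) {
          p - lr * (m / bc1) / (sqrt(v / bc2) + adam_eps)
        }, params, m_state, v_state)
      }
      tr <- loss_fn(params)
      vl <- if (!is.null(val_fn)) val_fn(params) else NA_real_
      history[[ep + 1L]] <- tibble(epoch = ep, train_loss = tr, val_loss = vl)
      monitor <- if (!is.null(val_fn)) vl else tr
      if (monitor < best$score - 1e-12) {
        best <- list(score = monitor, params = params, epoch = ep)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (patience > 0L && wait >= patience) break
      }
    }
  })

  final_params <- if (patience > 0L) best$params else params
  list(params = final_params, history = dplyr::bind_rows(history),
       best_epoch = best$epoch)
}
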