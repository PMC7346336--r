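# Fixtures and oracles shared across the suite. Everything is generated in
# code; no stored data.

# Two well-separated Gaussian blobs in 2-D: linearly separable by a wide
# margin, so any sensible classifier should reach training accuracy 1.
make_blobs <- function(n = 200L, sep = 3, sd = 0.5, seed = 42L) {
  withr::with_seed(seed, {
    n1 <- n %/% 2L
    n0 <- n - n1
    x1 <- cbind(rnorm(n1, sep, sd), rnorm(n1, sep, sd))
    x0 <- cbind(rnorm(n0, -sep, sd), rnorm(n0, -sep, sd))
    tibble::tibble(
      f1 = c(x1[, 1], x0[, 1]),
      f2 = c(x1[, 2], x0[, 2]),
      outcome = c(rep(1L, n1), rep(0L, n0))
    )
  })
}

# Random network parameters in the engine's container format.
rand_params <- function(m, widths, attention = TRUE, seed = 1L) {
  withr::with_seed(seed, {
    p <- list()
    if (attention) {
      p$attn <- list(W = matrix(rnorm(m * m, sd = 0.5), m, m),
                     b = rnorm(m, sd = 0.5))
    }
    sizes <- c(m, widths, 1L)
    p$layers <- lapply(seq_len(length(sizes) - 1L), function(l) {
      list(W = matrix(rnorm(sizes[l] * sizes[l + 1L], sd = 0.5),
                      sizes[l], sizes[l + 1L]),
           b = rnorm(sizes[l + 1L], sd = 0.3))
    })
    p
  })
}

# Central finite differences over every parameter entry; the independent
# oracle for the analytic backprop gradients.
numerical_grad <- function(params, f, h = 1e-5) {
  v <- unlist(params)
  g <- numeric(length(v))
  for (i in seq_along(v)) {
    vp <- v; vp[i] <- v[i] + h
    vm <- v; vm[i] <- v[i] - h
    g[i] <- (f(utils::relist(vp, params)) - f(utils::relist(vm, params))) / (2 * h)
  }
  g
}

# Brute-force pairwise concordance: the oracle for compute_auc.
brute_auc <- function(y, s) {
  pos <- s[y == 1]
  neg <- s[y == 0]
  mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
}

# A tiny complete cohort for protocol-shape tests.
small_cohort <- function(n = 120L, m = 4L, seed = 7L) {
  spec <- attnrisk::synthetic_spec(n, m, informative_idx = c(1L, 2L),
                                   beta = c(1.5, -1.5), seed = seed)
  attnrisk::generate_cohort(spec)$data
}

# Wrap raw engine parameters as a model object, for hand-built networks.
as_net_model <- function(params, feature_names,
                         config = attnrisk::model_config()) {
  structure(list(
    params = params, config = config, feature_names = feature_names,
    history = tibble::tibble(epoch = 0L, train_loss = NA_real_,
                             val_loss = NA_real_),
    best_epoch = 0L, attention = !is.null(params$attn)
  ), class = c(if (!is.null(params$attn)) "attn_model" else "mlp_model",
               "risk_model"))
}

fast_config <- function(...) {
  attnrisk::model_config(epochs = 15L, batch_size = 64L, patience = 0L, ...)
}
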