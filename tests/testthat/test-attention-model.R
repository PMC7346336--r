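test_that("attention is uniform under zero logits and matches hand softmax", {
  expect_equal(compute_attention(c(3, -1, 2, 0), matrix(0, 4, 4), rep(0, 4)),
               rep(0.25, 4))
  # W = 0, b = (0, ln 3): exp-and-normalize gives (1, 3) / 4
  expect_equal(compute_attention(c(5, 5), matrix(0, 2, 2), c(0, log(3))),
               c(0.25, 0.75))
})

test_that("attention is invariant to constant logit shifts and always normalized", {
  withr::with_seed(2, {
    for (i in 1:20) {
      m <- sample(2:8, 1)
      W <- matrix(rnorm(m * m, sd = 2), m, m)
      b <- rnorm(m)
      x <- rnorm(m)
      a <- compute_attention(x, W, b)
      expect_equal(sum(a), 1, tolerance = 1e-12)
      expect_true(all(a > 0 & a < 1))
      expect_equal(compute_attention(x, W, b + 7), a, tolerance = 1e-12)
    }
  })
  # very large finite logits must not overflow
  a <- compute_attention(c(1, 1), diag(2) * 500, c(400, 0))
  expect_equal(sum(a), 1, tolerance = 1e-12)
  expect_error(compute_attention(c(1, NA), matrix(0, 2, 2), c(0, 0)),
               "Non-finite")
  expect_error(compute_attention(c(1, 2, 3), matrix(0, 2, 2), c(0, 0)),
               "Dimension")
})

test_that("gating multiplies element-wise", {
  x <- c(2, -4, 6)
  expect_equal(gate_input(x, rep(1 / 3, 3)), x / 3)
  expect_equal(gate_input(x, c(0, 1, 0)), c(0, -4, 0))
  expect_equal(gate_input(rep(0, 3), c(0.2, 0.3, 0.5)), rep(0, 3))
  expect_error(gate_input(x, c(0.5, 0.5)), "same length")
})

test_that("an all-zero network predicts one half everywhere", {
  params <- list(attn = list(W = matrix(0, 3, 3), b = rep(0, 3)),
                 layers = list(list(W = matrix(0, 3, 4), b = rep(0, 4)),
                               list(W = matrix(0, 4, 1), b = 0)))
  model <- as_net_model(params, c("a", "b", "c"))
  X <- matrix(rnorm(15), 5, 3)
  fw <- forward_pass(model, X)
  expect_equal(fw$probs, rep(0.5, 5))
  expect_equal(fw$alpha, matrix(1 / 3, 5, 3), tolerance = 1e-12)
})

test_that("zero attention parameters reduce to a plain MLP on x / m", {
  m <- 6L
  base <- rand_params(m, c(5, 4), attention = FALSE, seed = 10)
  attn_params <- c(list(attn = list(W = matrix(0, m, m), b = rep(0, m))),
                   base)
  fnames <- sprintf("f%d", 1:m)
  attn_model <- as_net_model(attn_params, fnames)
  mlp_model <- as_net_model(base, fnames)
  X <- withr::with_seed(3, matrix(rnorm(40 * m), 40, m))
  p_attn <- forward_pass(attn_model, X)$probs
  p_mlp <- forward_pass(mlp_model, X / m)$probs
  expect_equal(p_attn, p_mlp, tolerance = 1e-12)
})

test_that("probabilities are strictly inside (0, 1) for finite inputs", {
  params <- rand_params(4, 8, seed = 6)
  model <- as_net_model(params, sprintf("f%d", 1:4))
  X <- withr::with_seed(4, matrix(rnorm(200), 50, 4))
  p <- forward_pass(model, X)$probs
  expect_true(all(p > 0 & p < 1))
})

test_that("the loss equals ln 2 at chance and the penalty is linear in lambda", {
  params <- list(attn = list(W = matrix(0, 2, 2), b = rep(0, 2)),
                 layers = list(list(W = matrix(0, 2, 1), b = 0)))
  model <- as_net_model(params, c("a", "b"))
  X <- matrix(rnorm(10), 5, 2)
  y <- c(1, 0, 1, 1, 0)
  expect_equal(compute_loss(model, X, y = y, lambda = 0), log(2),
               tolerance = 1e-12)

  rp <- rand_params(3, 4, seed = 77)
  rmodel <- as_net_model(rp, c("a", "b", "c"))
  Xr <- withr::with_seed(5, matrix(rnorm(24), 8, 3))
  yr <- rep(c(0, 1), 4)
  sqnorm <- sum(rp$attn$W^2) + sum(rp$layers[[1]]$W^2) + sum(rp$layers[[2]]$W^2)
  l1 <- compute_loss(rmodel, Xr, y = yr, lambda = 0.1)
  l2 <- compute_loss(rmodel, Xr, y = yr, lambda = 0.7)
  expect_equal(l2 - l1, (0.7 - 0.1) * sqnorm, tolerance = 1e-10)
  expect_error(compute_loss(rmodel, Xr, y = c(0, 2, rep(1, 6))), "binary")
})

test_that("a model that separates the data attains near-zero loss", {
  # single feature passed straight through a huge output weight
  params <- list(layers = list(list(W = matrix(50, 1, 1), b = 0)))
  model <- as_net_model(params, "a")
  X <- matrix(c(-1, -1, 1, 1), 4, 1)
  y <- c(0, 0, 1, 1)
  expect_lt(compute_loss(model, X, y = y, lambda = 0), 1e-6)
})

test_that("analytic gradients match finite differences for every group", {
  m <- 4L
  X <- withr::with_seed(11, matrix(rnorm(6 * m), 6, m))
  y <- rep(c(0, 1), 3)
  for (widths in list(4L, c(5L, 3L))) {
    params <- rand_params(m, widths, attention = TRUE, seed = 12)
    g <- attnrisk:::nn_loss_grad(params, X, y, lambda = 0.01)
    gn <- numerical_grad(params, function(p) {
      attnrisk:::nn_loss_value(p, X, y, lambda = 0.01)
    })
    ga <- unlist(g$grads)
    expect_lt(max(abs(ga - gn) / pmax(abs(gn), 1e-3)), 1e-5)
  }
})

test_that("training separates well-separated blobs perfectly", {
  blobs <- make_blobs(200)
  # independent check that the blobs really are linearly separable
  lin <- suppressWarnings(glm(outcome ~ f1 + f2, data = blobs,
                              family = binomial()))
  expect_true(all((fitted(lin) > 0.5) == (blobs$outcome == 1)))

  model <- fit_attention(blobs, config = model_config(epochs = 80,
                                                      patience = 0, seed = 2))
  pred <- predict(model, blobs)
  expect_equal(mean(pred$.label == blobs$outcome), 1.0)
})

test_that("fits are deterministic given the seed", {
  d <- small_cohort(80)
  cfg <- model_config(epochs = 10, seed = 123, patience = 0)
  m1 <- fit_attention(d, config = cfg)
  m2 <- fit_attention(d, config = cfg)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$history, m2$history)
  m3 <- fit_plain_mlp(d, config = cfg)
  m4 <- fit_plain_mlp(d, config = cfg)
  expect_identical(m3$params, m4$params)
})

test_that("training reduces the loss on non-degenerate data", {
  d <- small_cohort(100)
  for (s in 1:3) {
    m <- fit_attention(d, config = model_config(epochs = 20, seed = s,
                                                patience = 0))
    h <- m$history
    expect_lt(h$train_loss[nrow(h)], h$train_loss[1])
  }
})

test_that("an overwhelming penalty drives all weight matrices to zero", {
  # at the penalty-dominated optimum every penalised weight matrix vanishes;
  # the (unpenalised) attention bias is then a free parameter, so attention
  # collapses to the same softmax(b) vector for every patient
  d <- small_cohort(60, m = 4)
  d <- standardize_features(d)
  cfg <- model_config(n_hidden_layers = 1, hidden_width = 8, lambda = 1e6,
                      learning_rate = 1e-3, epochs = 2000, batch_size = 32,
                      patience = 0, seed = 3)
  m <- fit_attention(d, config = cfg)
  expect_lt(sqrt(sum(m$params$attn$W^2)), 1e-2)
  for (l in m$params$layers) expect_lt(sqrt(sum(l$W^2)), 1e-2)
  A <- extract_attention(m, d)
  # patient-independent: every row equals softmax(b)
  expect_lt(max(abs(sweep(unclass(A), 2, compute_attention(
    rep(0, 4), m$params$attn$W * 0, m$params$attn$b)))), 1e-6)
  expect_equal(unclass(A)[1, ], unclass(A)[60, ], tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("training loss at the optimum is nondecreasing in lambda", {
  d <- small_cohort(80, m = 3)
  losses <- vapply(c(0.001, 0.1, 10), function(lam) {
    cfg <- model_config(lambda = lam, epochs = 60, patience = 0, seed = 4)
    m <- fit_attention(d, config = cfg)
    compute_loss(m, d, lambda = lam)
  }, numeric(1))
  expect_true(all(diff(losses) > -1e-8))
})

test_that("thresholding is strict: a probability equal to the threshold is negative", {
  params <- list(attn = list(W = matrix(0, 2, 2), b = rep(0, 2)),
                 layers = list(list(W = matrix(0, 2, 1), b = 0)))
  model <- as_net_model(params, c("a", "b"))   # every prob is exactly 0.5
  X <- matrix(rnorm(8), 4, 2)
  expect_equal(predict(model, X)$.label, rep(0L, 4))
  expect_equal(predict(model, X, threshold = 0.49)$.label, rep(1L, 4))
  expect_error(predict(model, X, threshold = 1.5), "threshold")
})

test_that("single-class training data is rejected", {
  d <- dplyr::mutate(small_cohort(40), outcome = 0)
  expect_error(fit_attention(d), "Both outcome classes")
})

test_that("models round-trip through JSON serialization exactly", {
  d <- small_cohort(60)
  m <- fit_attention(d, config = fast_config(seed = 5))
  path <- withr::local_tempfile(fileext = ".json")
  write_model(m, path)
  m2 <- read_model(path)
  X <- as.matrix(d[m$feature_names])
  expect_equal(forward_pass(m2, X)$probs, forward_pass(m, X)$probs,
               tolerance = 1e-12)
  expect_equal(forward_pass(m2, X)$alpha, forward_pass(m, X)$alpha,
               tolerance = 1e-12)

  lr <- fit_logistic(d)
  write_model(lr, path)
  lr2 <- read_model(path)
  expect_equal(predict(lr2, d, type = "prob"), predict(lr, d, type = "prob"),
               tolerance = 1e-12)
})

test_that("tidiers summarise fitted networks", {
  d <- small_cohort(60)
  m <- fit_attention(d, config = fast_config(seed = 6))
  td <- tidy(m)
  expect_true(all(c("component", "term", "value") %in% names(td)))
  expect_equal(sum(td$component == "attention_bias"), 4L)
  gl <- glance(m)
  expect_equal(gl$n_features, 4L)
  expect_lt(gl$final_loss, gl$initial_loss)
})
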