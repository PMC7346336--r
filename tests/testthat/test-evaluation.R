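test_that("metrics match the hand-computed confusion matrix", {
  # TP=2, FP=1, FN=1, TN=1
  y_true <- c(1, 1, 1, 0, 0)
  y_pred <- c(1, 1, 0, 1, 0)
  m <- compute_metrics(y_true, y_pred, c(0.9, 0.8, 0.4, 0.6, 0.2))
  expect_equal(m$accuracy, 0.6)
  expect_equal(m$precision, 2 / 3)
  expect_equal(m$recall, 2 / 3)
  expect_equal(m$f1, 2 / 3)
})

test_that("metric boundary conventions hold", {
  y <- c(1, 1, 0, 0)
  perfect <- compute_metrics(y, y, c(0.9, 0.8, 0.2, 0.1))
  expect_equal(unlist(perfect), c(accuracy = 1, precision = 1, recall = 1,
                                  f1 = 1, auc = 1))
  all_pos <- compute_metrics(y, rep(1, 4), c(0.9, 0.9, 0.9, 0.9))
  expect_equal(all_pos$recall, 1)
  expect_equal(all_pos$precision, 0.5)   # prevalence
  expect_warning(res <- compute_metrics(y, rep(0, 4)), "precision")
  expect_equal(res$precision, 0)
  expect_equal(res$f1, 0)
  expect_error(compute_metrics(c(1, 0), c(1, 0, 1)), "length")
})

test_that("metrics are invariant to simultaneous permutation", {
  withr::with_seed(40, {
    y <- rbinom(50, 1, 0.5)
    yhat <- rbinom(50, 1, 0.5)
    s <- runif(50)
    p <- sample(50)
    expect_equal(compute_metrics(y, yhat, s),
                 compute_metrics(y[p], yhat[p], s[p]))
  })
})

test_that("AUC equals brute-force pairwise concordance on random instances", {
  expect_equal(compute_auc(c(1, 0), c(0.9, 0.1)), 1.0)
  expect_equal(compute_auc(c(1, 1, 0, 0), rep(0.5, 4)), 0.5)
  expect_equal(compute_auc(c(1, 1, 0, 0), c(0.8, 0.4, 0.6, 0.2)), 0.75)
  withr::with_seed(41, {
    for (i in 1:200) {
      n <- sample(4:30, 1)
      y <- c(0, 1, rbinom(n - 2, 1, 0.5))   # both classes guaranteed
      s <- sample(round(runif(n), 2))        # rounded so ties occur
      expect_equal(compute_auc(y, s), brute_auc(y, s))
    }
  })
  expect_error(compute_auc(c(1, 1), c(0.2, 0.4)), "both classes")
})

test_that("AUC agrees with an independent reference implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(42, {
    for (i in 1:10) {
      y <- c(0, 1, rbinom(48, 1, 0.6))
      s <- runif(50)
      ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                            direction = "<")))
      expect_equal(compute_auc(y, s), ref, tolerance = 1e-12)
    }
  })
})

test_that("the paired t-test matches the closed form and its conventions", {
  same <- paired_t_test(c(1, 0, 1), c(1, 0, 1))
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_value, 1)

  res <- paired_t_test(c(1, -1, 2, 0), c(0, 0, 0, 0))
  expect_equal(res$t_statistic, 0.5 / (sd(c(1, -1, 2, 0)) / 2),
               tolerance = 1e-10)
  expect_equal(res$t_statistic, 0.7745967, tolerance = 1e-6)
  expect_equal(res$p_value, 2 * pt(-0.7745967, df = 3), tolerance = 1e-6)

  const <- paired_t_test(c(2, 2, 2), c(1, 1, 1))
  expect_true(is.infinite(const$t_statistic))
  expect_equal(const$p_value, 0)
  expect_true(const$degenerate)
  expect_error(paired_t_test(1, 2), "At least 2")
})

test_that("the paired t-test matches stats::t.test on random vectors", {
  withr::with_seed(43, {
    for (i in 1:20) {
      a <- rnorm(15)
      b <- rnorm(15)
      mine <- paired_t_test(a, b)
      ref <- t.test(a, b, paired = TRUE)
      expect_equal(mine$t_statistic, unname(ref$statistic), tolerance = 1e-10)
      expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
    }
  })
})

test_that("mcnemar test counts discordant pairs and handles agreement", {
  y <- c(1, 1, 1, 0, 0, 0)
  a <- c(1, 1, 0, 0, 0, 1)
  b <- c(1, 0, 1, 0, 1, 1)
  res <- mcnemar_test(a, b, y)
  expect_equal(res$n_discordant, 3L)
  agree <- mcnemar_test(a, a, y)
  expect_equal(agree$p_value, 1)
})

test_that("the protocol produces the declared shape and an oracle aces it", {
  d <- small_cohort(120)
  cfg <- protocol_config(n_repeats = 3, base_seed = 50)
  res <- run_protocol(d, list(logistic_spec(), oracle_spec()), cfg)

  expect_equal(nrow(res$metrics), 2L * 3L)
  expect_true(all(table(res$metrics$model) == 3L))
  expect_true(all(res$summary$n == 3L))
  long <- tidy(res)
  expect_true(all(long$value >= 0 & long$value <= 1))

  orc <- dplyr::filter(res$summary, model == "oracle", metric == "accuracy")
  expect_equal(orc$mean, 1.0)
  expect_equal(orc$sd, 0.0)

  expect_equal(nrow(res$t_tests), 1L)
  tm <- t_test_matrix(res)
  expect_equal(dim(tm), c(2L, 3L))
  expect_false(is.na(tm$oracle[tm$model == "lr"]))
  expect_true(is.na(tm$lr[tm$model == "lr"]))
})

test_that("the protocol is deterministic given its base seed", {
  d <- small_cohort(100)
  cfg <- protocol_config(n_repeats = 2, base_seed = 60)
  r1 <- run_protocol(d, list(logistic_spec()), cfg)
  r2 <- run_protocol(d, list(logistic_spec()), cfg)
  expect_identical(r1$metrics, r2$metrics)
})

test_that("cross-validation tunes over the declared grid", {
  d <- small_cohort(150)
  spec <- mlp_spec(fast_config(), grid = 1:2)
  cfg <- protocol_config(n_repeats = 2, base_seed = 70)
  res <- run_protocol(d, list(spec), cfg)
  expect_true(all(res$chosen_hyper$hyper %in% 1:2))
  expect_equal(nrow(res$chosen_hyper), 2L)
})

test_that("per-repetition t-test mode compares accuracy vectors", {
  d <- small_cohort(100)
  cfg <- protocol_config(n_repeats = 3, base_seed = 80,
                         t_test_mode = "per_repeat")
  res <- run_protocol(d, list(logistic_spec(), oracle_spec()), cfg)
  expect_equal(res$t_tests$n_pairs, 3L)
})

test_that("the hidden-layer sweep emits a tidy model-by-depth table", {
  d <- small_cohort(120)
  cfg <- protocol_config(n_repeats = 1, base_seed = 90)
  sw <- hidden_layer_sweep(d, cfg, depths = 1:2,
                           models = c("attention", "mlp"),
                           base_config = fast_config())
  expect_equal(nrow(sw), 4L)   # 2 models x 2 depths x 1 repetition
  expect_setequal(unique(sw$model), c("attention", "mlp"))
  expect_setequal(unique(sw$depth), 1:2)
  expect_true(all(sw$accuracy >= 0 & sw$accuracy <= 1))
  expect_true(all(sw$auc >= 0 & sw$auc <= 1))
  sw2 <- hidden_layer_sweep(d, cfg, depths = 1:2,
                            models = c("attention", "mlp"),
                            base_config = fast_config())
  expect_identical(sw, sw2)
})

test_that("standardization inside the protocol never sees test rows", {
  # a feature with a wild outlier: if test rows leaked into the scaling
  # statistics, the training-split mean would shift with the split; instead
  # the train stats must be recomputed per repetition from train rows only
  d <- small_cohort(100)
  parts <- split_holdout(d, train_fraction = 0.8, seed = 101)
  tr <- standardize_features(parts$train)
  st <- scaling_stats(tr)
  direct_mean <- mean(parts$train$f001)
  expect_equal(st$mean[st$feature == "f001"], direct_mean,
               ignore_attr = TRUE)
  expect_false(isTRUE(all.equal(direct_mean, mean(d$f001))))
})
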