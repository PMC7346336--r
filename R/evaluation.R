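#' Classification metrics for binary predictions
#'
#' Accuracy, precision, recall, F1 and AUC in one row. Precision is defined
#' as 0 (with a warning) when no positives are predicted, and F1 as 0 when
#' precision and recall are both 0. AUC comes from [compute_auc()] and
#' requires scores plus both classes in `y_true`.
#'
#' @param y_true 0/1 truth.
#' @param y_pred 0/1 predicted labels.
#' @param y_score Predicted probabilities/scores (for AUC); optional, in
#'   which case `auc` is `NA`.
#' @return A one-row tibble with columns `accuracy`, `precision`, `recall`,
#'   `f1`, `auc`.
#' @export
#' @examples
#' compute_metrics(c(1, 1, 1, 0, 0), c(1, 1, 0, 1, 0), c(.9, .8, .4, .6, .2))
compute_metrics <- function(y_true, y_pred, y_score = NULL) {
  if (length(y_true) != length(y_pred)) {
    abort("`y_true` and `y_pred` must have the same length.")
  }
  if (!all(y_true %in% c(0, 1)) || !all(y_pred %in% c(0, 1))) {
    abort("Labels must be strictly binary (0/1).")
  }
  tp <- sum(y_true == 1 & y_pred == 1)
  fp <- sum(y_true == 0 & y_pred == 1)
  fn <- sum(y_true == 1 & y_pred == 0)
  tn <- sum(y_true == 0 & y_pred == 0)
  accuracy <- (tp + tn) / length(y_true)
  if (tp + fp == 0) {
    warn("No positives predicted; precision reported as 0.")
    precision <- 0
  } else {
    precision <- tp / (tp + fp)
  }
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  auc <- if (is.null(y_score)) NA_real_ else compute_auc(y_true, y_score)
  tibble(accuracy = accuracy, precision = precision, recall = recall,
         f1 = f1, auc = auc)
}

#' Area under the ROC curve
#'
#' The Mann–Whitney concordance probability: over all (positive, negative)
#' pairs, the fraction where the positive is scored higher, counting ties as
#' 1/2. Computed via midranks, so it is exact.
#'
#' @param y_true 0/1 truth containing both classes.
#' @param y_score Real-valued scores.
#' @return A number in `[0, 1]`.
#' @export
compute_auc <- function(y_true, y_score) {
  if (length(y_true) != length(y_score)) {
    abort("`y_true` and `y_score` must have the same length.")
  }
  if (!all(y_true %in% c(0, 1))) abort("Labels must be strictly binary (0/1).")
  n_pos <- sum(y_true == 1)
  n_neg <- sum(y_true == 0)
  if (n_pos == 0 || n_neg == 0) {
    abort("AUC undefined: both classes must be present in `y_true`.")
  }
  r <- rank(y_score, ties.method = "average")
  (sum(r[y_true == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Paired-samples t-test on matched prediction vectors
#'
#' Tests whether the mean of the per-item differences `a - b` is zero:
#' `t = mean(d) / (sd(d) / sqrt(n))` with the sample standard deviation
#' (`n - 1` denominator) and a two-sided p-value from Student's t with
#' `n - 1` degrees of freedom. Conventions at the boundaries: all-zero
#' differences give `t = 0, p = 1`; a constant nonzero difference has zero
#' variance and is reported as infinite `t`, `p = 0`, with `degenerate =
#' TRUE`. Note that applying a t-test to paired binary labels is a
#' questionable (if common) practice; see [mcnemar_test()] for the standard
#' alternative.
#'
#' @param pred_a,pred_b Numeric vectors of equal length `n >= 2`.
#' @param names Optional length-2 character vector naming the two models.
#' @return A one-row tibble: `model_a`, `model_b`, `mean_diff`,
#'   `t_statistic`, `p_value`, `n_pairs`, `degenerate`.
#' @export
paired_t_test <- function(pred_a, pred_b, names = c("a", "b")) {
  if (length(pred_a) != length(pred_b)) {
    abort("`pred_a` and `pred_b` must have the same length.")
  }
  n <- length(pred_a)
  if (n < 2L) abort("At least 2 pairs are required.")
  d <- as.numeric(pred_a) - as.numeric(pred_b)
  md <- mean(d)
  s <- sd(d)
  degenerate <- FALSE
  if (all(d == 0)) {
    t_stat <- 0
    p <- 1
  } else if (s == 0) {
    t_stat <- sign(md) * Inf
    p <- 0
    degenerate <- TRUE
  } else {
    t_stat <- md / (s / sqrt(n))
    p <- 2 * pt(-abs(t_stat), df = n - 1)
  }
  tibble(model_a = names[1L], model_b = names[2L], mean_diff = md,
         t_statistic = t_stat, p_value = p, n_pairs = n,
         degenerate = degenerate)
}

#' McNemar test on paired classifier correctness
#'
#' The standard test for comparing two classifiers on the same patients:
#' counts the discordant pairs (one model correct, the other wrong) and
#' tests their symmetry with a continuity-corrected chi-squared statistic.
#' Offered as the statistically conventional alternative to
#' [paired_t_test()] on predicted labels.
#'
#' @param pred_a,pred_b 0/1 predicted labels of the two models.
#' @param y_true 0/1 ground truth.
#' @param names Optional model names.
#' @return A one-row tibble: `model_a`, `model_b`, `statistic`, `p_value`,
#'   `n_discordant`.
#' @export
mcnemar_test <- function(pred_a, pred_b, y_true, names = c("a", "b")) {
  correct_a <- factor(pred_a == y_true, levels = c(FALSE, TRUE))
  correct_b <- factor(pred_b == y_true, levels = c(FALSE, TRUE))
  tab <- table(correct_a, correct_b)
  n01 <- tab[1L, 2L]
  n10 <- tab[2L, 1L]
  if (n01 + n10 == 0) {
    stat <- 0; p <- 1
  } else {
    res <- stats::mcnemar.test(tab)
    stat <- unname(res$statistic); p <- res$p.value
  }
  tibble(model_a = names[1L], model_b = names[2L], statistic = stat,
         p_value = p, n_discordant = as.integer(n01 + n10))
}

#' Declare a model for the evaluation protocol
#'
#' A model spec bundles a name, a fitting function, a probability predictor
#' and an optional hyperparameter grid (tuned by cross-validated AUC inside
#' [run_protocol()]). Ready-made specs exist for the four study models plus a
#' truth-oracle used to validate the harness.
#'
#' @param name Display name.
#' @param fit `function(data, outcome, hyper, seed)` returning a fitted model.
#' @param predict_prob `function(model, data, outcome)` returning
#'   probabilities.
#' @param grid Vector of hyperparameter values (e.g. hidden-layer depths);
#'   `NULL` or length 1 means no tuning.
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(name, fit, predict_prob, grid = NULL) {
  structure(list(name = name, fit = fit, predict_prob = predict_prob,
                 grid = grid), class = "model_spec")
}

#' @rdname model_spec
#' @param config Base [model_config()] (or [sdae_config()]) whose depth/seed
#'   fields the protocol overrides per hyperparameter point and repetition.
#' @export
attention_spec <- function(config = model_config(), grid = NULL) {
  model_spec(
    name = "attention",
    fit = function(data, outcome, hyper, seed) {
      cfg <- config
      if (!is.null(hyper)) cfg$n_hidden_layers <- as.integer(hyper)
      cfg$seed <- as.integer(seed)
      fit_attention(data, outcome, cfg)
    },
    predict_prob = function(model, data, outcome) {
      predict(model, data, type = "prob", outcome = outcome)
    },
    grid = grid
  )
}

#' @rdname model_spec
#' @export
mlp_spec <- function(config = model_config(), grid = NULL) {
  model_spec(
    name = "mlp",
    fit = function(data, outcome, hyper, seed) {
      cfg <- config
      if (!is.null(hyper)) cfg$n_hidden_layers <- as.integer(hyper)
      cfg$seed <- as.integer(seed)
      fit_plain_mlp(data, outcome, cfg)
    },
    predict_prob = function(model, data, outcome) {
      predict(model, data, type = "prob", outcome = outcome)
    },
    grid = grid
  )
}

#' @rdname model_spec
#' @param l2 Ridge penalty for the logistic baseline.
#' @export
logistic_spec <- function(l2 = 1e-4) {
  model_spec(
    name = "lr",
    fit = function(data, outcome, hyper, seed) fit_logistic(data, outcome, l2),
    predict_prob = function(model, data, outcome) {
      predict(model, data, type = "prob", outcome = outcome)
    }
  )
}

#' @rdname model_spec
#' @param sdae Base [sdae_config()].
#' @export
sdae_spec <- function(sdae = sdae_config(), grid = NULL) {
  model_spec(
    name = "sdae",
    fit = function(data, outcome, hyper, seed) {
      cfg <- sdae
      if (!is.null(hyper)) {
        depth <- as.integer(hyper)
        cfg$layer_widths <- rep_len(cfg$layer_widths, depth)
      }
      cfg$seed <- as.integer(seed)
      fit_sdae(data, outcome, cfg)
    },
    predict_prob = function(model, data, outcome) {
      predict(model, data, type = "prob", outcome = outcome)
    },
    grid = grid
  )
}

#' @rdname model_spec
#' @export
oracle_spec <- function() {
  model_spec(
    name = "oracle",
    fit = function(data, outcome, hyper, seed) {
      structure(list(outcome = outcome), class = "oracle_model")
    },
    predict_prob = function(model, data, outcome) {
      # reads the true labels: a harness check, not a real model
      ifelse(data[[outcome]] == 1, 0.999, 0.001)
    }
  )
}

#' Protocol configuration
#'
#' Settings for the repeated holdout evaluation: per repetition `r` the
#' cohort is split 80/20 stratified with seed `base_seed + r`, hyperparameters
#' are tuned by five-fold cross-validated AUC on the training 80%, the model
#' is refit on the full 80% and scored on the 20%. Metrics are summarized as
#' mean and standard deviation over the `n_repeats` repetitions.
#'
#' @param n_repeats Number of repetitions (default 10).
#' @param n_folds Cross-validation folds (default 5).
#' @param train_fraction Holdout training fraction (default 0.8).
#' @param base_seed Base integer seed.
#' @param standardize Standardize features per split using training-split
#'   statistics (default `TRUE`).
#' @param threshold Classification threshold applied to probabilities.
#' @param t_test_mode `"pooled"` runs pairwise t-tests on per-patient
#'   predicted labels pooled across repetitions; `"per_repeat"` on the
#'   per-repetition accuracy values.
#' @return A list of class `protocol_config`.
#' @export
protocol_config <- function(n_repeats = 10L, n_folds = 5L,
                            train_fraction = 0.8, base_seed = 1L,
                            standardize = TRUE, threshold = 0.5,
                            t_test_mode = c("pooled", "per_repeat")) {
  if (n_folds < 2L) abort("`n_folds` must be at least 2.")
  if (n_repeats < 1L) abort("`n_repeats` must be at least 1.")
  structure(list(
    n_repeats = as.integer(n_repeats), n_folds = as.integer(n_folds),
    train_fraction = train_fraction, base_seed = as.integer(base_seed),
    standardize = standardize, threshold = threshold,
    t_test_mode = match.arg(t_test_mode)
  ), class = "protocol_config")
}

#' Run the repeated holdout + cross-validation evaluation protocol
#'
#' For each repetition: a stratified 80/20 split (redrawn per repetition so
#' the repeat-to-repeat spread is meaningful); per model, when a grid is
#' declared, five-fold cross-validation on the training 80% picks the
#' hyperparameter with the best mean CV AUC; the model is refit on the full
#' 80% and scored on the held-out 20% with accuracy, precision, recall, F1
#' and AUC. After all repetitions, each metric is summarized as mean ± sd and
#' every model pair is compared with a paired t-test on the pooled
#' per-patient predicted test labels (see [protocol_config()] for the
#' per-repetition alternative), plus McNemar tests on the same pairs.
#'
#' @param data A complete cohort tibble (features + 0/1 outcome).
#' @param model_specs List of [model_spec()] objects.
#' @param config A [protocol_config()].
#' @param outcome Outcome column name.
#' @return An object of class `protocol_result` with tibbles `metrics`
#'   (per model x repetition), `summary` (mean/sd per model x metric),
#'   `t_tests`, `mcnemar`, and `chosen_hyper`.
#' @export
run_protocol <- function(data, model_specs, config = protocol_config(),
                         outcome = "outcome") {
  if (length(model_specs) < 1L) abort("At least one model spec is required.")
  if (inherits(model_specs, "model_spec")) model_specs <- list(model_specs)
  mats <- cohort_matrices(data, outcome)
  check_both_classes(mats$y, "cohort")
  nm <- vapply(model_specs, function(s) s$name, character(1))
  if (anyDuplicated(nm)) abort("Model spec names must be unique.")

  metrics <- list()
  chosen <- list()
  pooled_labels <- setNames(vector("list", length(nm)), nm)
  pooled_truth <- list()

  for (r in seq_len(config$n_repeats)) {
    seed_r <- config$base_seed + r
    parts <- split_holdout(data, outcome, config$train_fraction, seed = seed_r)
    train <- parts$train
    test <- parts$test
    if (config$standardize) {
      train <- standardize_features(train, outcome)
      test <- standardize_features(test, outcome, stats = scaling_stats(train))
    }
    pooled_truth[[r]] <- test[[outcome]]

    for (s in model_specs) {
      hyper <- NULL
      if (!is.null(s$grid) && length(s$grid) > 1L) {
        hyper <- tune_by_cv(train, s, config, outcome, seed_r)
      } else if (!is.null(s$grid)) {
        hyper <- s$grid[[1L]]
      }
      model <- s$fit(train, outcome, hyper, seed_r)
      probs <- s$predict_prob(model, test, outcome)
      labels <- as.integer(probs > config$threshold)
      metrics[[length(metrics) + 1L]] <- dplyr::bind_cols(
        tibble(model = s$name, repetition = r,
               hyper = if (is.null(hyper)) NA_real_ else as.numeric(hyper)),
        compute_metrics(test[[outcome]], labels, probs)
      )
      chosen[[length(chosen) + 1L]] <- tibble(
        model = s$name, repetition = r,
        hyper = if (is.null(hyper)) NA_real_ else as.numeric(hyper))
      pooled_labels[[s$name]] <- c(pooled_labels[[s$name]], labels)
    }
  }

  metrics <- dplyr::bind_rows(metrics)
  summary_tbl <- metrics |>
    tidyr::pivot_longer(c("accuracy", "precision", "recall", "f1", "auc"),
                        names_to = "metric", values_to = "value") |>
    dplyr::group_by(.data$model, .data$metric) |>
    dplyr::summarise(mean = mean(.data$value), sd = sd(.data$value),
                     n = dplyr::n(), .groups = "drop")

  t_tests <- list()
  mcn <- list()
  if (length(nm) > 1L) {
    truth_vec <- unlist(pooled_truth)
    for (i in seq_along(nm)) {
      for (j in seq_along(nm)) {
        if (j <= i) next
        if (config$t_test_mode == "pooled") {
          a <- pooled_labels[[nm[i]]]
          b <- pooled_labels[[nm[j]]]
        } else {
          a <- metrics$accuracy[metrics$model == nm[i]]
          b <- metrics$accuracy[metrics$model == nm[j]]
        }
        t_tests[[length(t_tests) + 1L]] <-
          paired_t_test(a, b, names = c(nm[i], nm[j]))
        if (config$t_test_mode == "pooled") {
          mcn[[length(mcn) + 1L]] <- mcnemar_test(
            pooled_labels[[nm[i]]], pooled_labels[[nm[j]]], truth_vec,
            names = c(nm[i], nm[j]))
        }
      }
    }
  }

  structure(list(
    metrics = metrics, summary = summary_tbl,
    t_tests = dplyr::bind_rows(t_tests), mcnemar = dplyr::bind_rows(mcn),
    chosen_hyper = dplyr::bind_rows(chosen), config = config,
    model_names = nm
  ), class = "protocol_result")
}

# Five-fold (stratified) CV on the training split; returns the grid value
# with the best mean fold AUC.
tune_by_cv <- function(train, spec, config, outcome, seed_r) {
  y <- train[[outcome]]
  folds <- local_seed(seed_r * 1000L + 7L,
                      stratified_folds(y, config$n_folds))
  mean_auc <- vapply(spec$grid, function(h) {
    aucs <- vapply(seq_len(config$n_folds), function(k) {
      tr <- train[folds != k, , drop = FALSE]
      va <- train[folds == k, , drop = FALSE]
      if (length(unique(va[[outcome]])) < 2L ||
          length(unique(tr[[outcome]])) < 2L) {
        abort("A cross-validation fold contains a single class; use more data or fewer folds.")
      }
      model <- spec$fit(tr, outcome, h, seed_r)
      compute_auc(va[[outcome]], spec$predict_prob(model, va, outcome))
    }, numeric(1))
    mean(aucs)
  }, numeric(1))
  spec$grid[[which.max(mean_auc)]]
}

#' @export
print.protocol_result <- function(x, ...) {
  cat(sprintf("Evaluation protocol: %d model(s), %d repetition(s)\n",
              length(x$model_names), x$config$n_repeats))
  wide <- x$summary |>
    dplyr::mutate(cell = sprintf("%.3f ± %.3f", .data$mean, .data$sd)) |>
    dplyr::select("model", "metric", "cell") |>
    tidyr::pivot_wider(names_from = "metric", values_from = "cell")
  print(wide)
  if (nrow(x$t_tests) > 0L) {
    cat("\nPaired t-tests on predicted labels:\n")
    print(dplyr::select(x$t_tests, "model_a", "model_b", "t_statistic",
                        "p_value"))
  }
  invisible(x)
}

#' Upper-triangular p-value matrix of the pairwise model tests
#'
#' @param result A `protocol_result`.
#' @return A tibble, one row per model, with p-values in the upper triangle.
#' @export
t_test_matrix <- function(result) {
  stopifnot(inherits(result, "protocol_result"))
  nm <- result$model_names
  mat <- matrix(NA_real_, length(nm), length(nm), dimnames = list(nm, nm))
  for (k in seq_len(nrow(result$t_tests))) {
    row <- result$t_tests[k, ]
    mat[row$model_a, row$model_b] <- row$p_value
  }
  dplyr::bind_cols(tibble(model = nm), as_tibble(mat))
}

#' Sweep the number of hidden layers
#'
#' Evaluates the attention model and the plain MLP (and optionally the SDAE
#' at matching coder depths) at each depth in `depths`, using the repeated
#' holdout protocol with no inner tuning (the depth is fixed per run), and
#' returns a tidy table of per-repetition accuracy and AUC, ready for
#' plotting performance against depth.
#'
#' @param data Complete cohort tibble.
#' @param config A [protocol_config()] (its `n_repeats` applies per depth).
#' @param depths Integer vector of hidden-layer counts (default 1:5).
#' @param models Character subset of `c("attention", "mlp", "sdae")`.
#' @param base_config [model_config()] used for the network models.
#' @param sdae Base [sdae_config()] when `"sdae"` is included.
#' @param outcome Outcome column name.
#' @return A tibble with columns `model`, `depth`, `repetition`, `accuracy`,
#'   `auc`.
#' @export
hidden_layer_sweep <- function(data, config = protocol_config(),
                               depths = 1:5,
                               models = c("attention", "mlp"),
                               base_config = model_config(),
                               sdae = sdae_config(), outcome = "outcome") {
  models <- match.arg(models, c("attention", "mlp", "sdae"), several.ok = TRUE)
  rows <- list()
  for (d in depths) {
    specs <- list()
    if ("attention" %in% models) {
      specs <- c(specs, list(attention_spec(base_config, grid = d)))
    }
    if ("mlp" %in% models) {
      specs <- c(specs, list(mlp_spec(base_config, grid = d)))
    }
    if ("sdae" %in% models) {
      specs <- c(specs, list(sdae_spec(sdae, grid = d)))
    }
    res <- run_protocol(data, specs, config, outcome)
    rows[[length(rows) + 1L]] <- res$metrics |>
      dplyr::mutate(depth = as.integer(d)) |>
      dplyr::select("model", "depth", "repetition", "accuracy", "auc")
  }
  dplyr::bind_rows(rows)
}
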