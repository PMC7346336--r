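#' Extract the per-patient attention matrix
#'
#' Returns exactly the softmax attention vectors used in each patient's
#' forward pass: an `n`-by-`m` matrix whose rows live on the probability
#' simplex, read as each feature's contribution to that patient's
#' prediction. Attention weights are nonnegative and directionless — they
#' say how much a feature mattered, not in which direction; pair them with
#' signed logistic coefficients ([lr_coefficient_ranking()]) for direction.
#'
#' @param model A fitted `attn_model`.
#' @param data Cohort tibble or feature matrix, preprocessed identically to
#'   the training data.
#' @param outcome Outcome column name to ignore, if present.
#' @return An `n`-by-`m` matrix of class `attention_matrix` with feature
#'   names as column names.
#' @export
extract_attention <- function(model, data, outcome = "outcome") {
  if (is.null(model$params$attn)) {
    abort("`model` has no attention layer (is it a plain MLP?).")
  }
  fw <- forward_pass(model, data, outcome)
  A <- fw$alpha
  colnames(A) <- model$feature_names
  rownames(A) <- NULL
  class(A) <- c("attention_matrix", class(A))
  A
}

#' Rank one patient's features by attention weight
#'
#' Sorts a patient's attention vector descending, truncates to the top `k`
#' and, when `min_weight` is given, to weights strictly above it. Ties keep
#' the original feature order (stable).
#'
#' @param alpha_row Length-`m` attention vector (one row of an
#'   [extract_attention()] matrix).
#' @param feature_names Length-`m` feature names.
#' @param k Number of top features to keep.
#' @param min_weight Optional strict lower bound on reported weights.
#' @return A tibble with columns `rank`, `feature`, `weight`.
#' @export
rank_patient_features <- function(alpha_row, feature_names = NULL,
                                  k = 10L, min_weight = NULL) {
  alpha_row <- as.numeric(alpha_row)
  m <- length(alpha_row)
  if (k <= 0L) abort("`k` must be positive.")
  if (k > m) abort("`k` cannot exceed the number of features.")
  feature_names <- feature_names %||% sprintf("f%03d", seq_len(m))
  if (length(feature_names) != m) {
    abort("`feature_names` must match the attention vector length.")
  }
  ord <- order(-alpha_row, seq_len(m))[seq_len(k)]
  out <- tibble(rank = seq_len(k), feature = feature_names[ord],
                weight = alpha_row[ord])
  if (!is.null(min_weight)) out <- dplyr::filter(out, .data$weight > min_weight)
  out
}

#' Global feature ranking by top-k attention frequency
#'
#' For each patient, takes the `k` features with the highest attention; then
#' counts, per feature, in how many patients' top-`k` it appears, and returns
#' the `top` most frequent features with their counts. This is the
#' cohort-level importance readout: a feature appearing in every patient's
#' top-`k` has count `n`.
#'
#' @param alpha An [extract_attention()] matrix (or any `n`-by-`m` matrix of
#'   attention rows).
#' @param feature_names Optional feature names (default: column names).
#' @param k Per-patient top-list size (default 10).
#' @param top Number of features to return (default 10).
#' @return A tibble with columns `rank`, `feature`, `count`.
#' @export
global_frequency_ranking <- function(alpha, feature_names = NULL, k = 10L,
                                     top = 10L) {
  alpha <- unclass(alpha)
  if (!is.matrix(alpha) || nrow(alpha) == 0L) {
    abort("`alpha` must be a nonempty attention matrix.")
  }
  m <- ncol(alpha)
  if (k > m) abort("`k` cannot exceed the number of features.")
  feature_names <- feature_names %||% colnames(alpha) %||%
    sprintf("f%03d", seq_len(m))
  counts <- integer(m)
  for (i in seq_len(nrow(alpha))) {
    topk <- order(-alpha[i, ], seq_len(m))[seq_len(k)]
    counts[topk] <- counts[topk] + 1L
  }
  ord <- order(-counts, seq_len(m))[seq_len(min(top, m))]
  tibble(rank = seq_along(ord), feature = feature_names[ord],
         count = counts[ord])
}

#' Rank features by absolute logistic-regression coefficient
#'
#' The classical transparent-model importance: features sorted by
#' `|coefficient|` descending (signed coefficients retained in the output so
#' direction is not lost). Complements the magnitude-only attention
#' rankings.
#'
#' @param model A fitted [fit_logistic()] model.
#' @param top Number of features to return.
#' @return A tibble with columns `rank`, `feature`, `coefficient`,
#'   `abs_coefficient`.
#' @export
lr_coefficient_ranking <- function(model, top = 10L) {
  if (!inherits(model, "logit_model")) {
    abort("`model` must be a fitted logit_model.")
  }
  co <- model$coefficients
  m <- length(co)
  ord <- order(-abs(co), seq_len(m))[seq_len(min(top, m))]
  tibble(rank = seq_along(ord), feature = names(co)[ord],
         coefficient = unname(co[ord]), abs_coefficient = abs(unname(co[ord])))
}

#' Log-attention matrix for heat-map display
#'
#' Element-wise log of the attention weights (natural log by default),
#' optionally restricted to a seeded random subset of patients — the usual
#' way to display per-patient attention across a cohort, since raw weights
#' on the simplex are compressed near zero.
#'
#' @param alpha An attention matrix.
#' @param sample_n Optional number of patients to subsample (e.g. 50);
#'   `NULL` keeps all rows.
#' @param seed Seed for the row subsample.
#' @param base Log base; default `exp(1)`.
#' @return A matrix of log attention weights (all `<= 0`) with `patient`
#'   row labels, carrying the selected row indices as attribute `rows`.
#' @export
heatmap_matrix <- function(alpha, sample_n = 50L, seed = 1L, base = exp(1)) {
  alpha <- unclass(alpha)
  if (!is.matrix(alpha)) abort("`alpha` must be an attention matrix.")
  if (any(alpha <= 0)) abort("Attention weights must be strictly positive.")
  n <- nrow(alpha)
  rows <- seq_len(n)
  if (!is.null(sample_n)) {
    if (sample_n > n) {
      abort(sprintf("Requested %d patients but the matrix has %d rows.",
                    sample_n, n))
    }
    rows <- local_seed(seed, sort(sample(n, sample_n)))
  }
  out <- log(alpha[rows, , drop = FALSE], base = base)
  rownames(out) <- sprintf("patient_%d", rows)
  attr(out, "rows") <- rows
  out
}
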