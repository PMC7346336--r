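#' Specify a synthetic patient cohort
#'
#' Describes a simulated tabular cohort: equicorrelated Gaussian features, a
#' small set of truly informative features acting through a logistic model,
#' and optional per-cell missingness. The generated data mimics the shape of
#' a numeric clinical feature table with a binary outcome (e.g. readmission),
#' so models and their attention-based feature attributions can be checked
#' against a known ground truth.
#'
#' @param n Number of patients (rows); at least 2.
#' @param m Number of features (columns).
#' @param informative_idx Integer indices (in `1..m`) of the truly
#'   informative features.
#' @param beta Log-odds coefficient per informative feature; same length as
#'   `informative_idx`.
#' @param beta0 Intercept on the log-odds scale; shifts the outcome
#'   prevalence.
#' @param feature_corr Equicorrelation among features, in `[0, 1)`.
#' @param missing_rate Per-cell probability of masking a feature value, in
#'   `[0, 1)`.
#' @param binary_idx Optional indices of features to dichotomize at 0 into
#'   0/1 indicators (mimicking comorbidity flags); applied before the linear
#'   predictor is formed.
#' @param seed Integer seed; the cohort is fully reproducible given the spec.
#' @return A list of class `synthetic_spec`.
#' @seealso [generate_cohort()], [study_shaped_spec()]
#' @export
synthetic_spec <- function(n, m, informative_idx = integer(0),
                           beta = numeric(0), beta0 = 0, feature_corr = 0,
                           missing_rate = 0, binary_idx = integer(0),
                           seed = 1L) {
  n <- as.integer(n); m <- as.integer(m)
  informative_idx <- as.integer(informative_idx)
  if (n < 2L) abort("`n` must be at least 2.")
  if (m < 1L) abort("`m` must be at least 1.")
  if (length(informative_idx) != length(beta)) {
    abort("`beta` must have one coefficient per informative feature.")
  }
  if (length(informative_idx) > 0L &&
      (anyDuplicated(informative_idx) || any(informative_idx < 1L) ||
       any(informative_idx > m))) {
    abort("`informative_idx` must be distinct indices in 1..m.")
  }
  if (feature_corr < 0 || feature_corr >= 1) {
    abort("`feature_corr` must be in [0, 1).")
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    abort("`missing_rate` must be in [0, 1).")
  }
  if (length(binary_idx) > 0L &&
      (any(binary_idx < 1L) || any(binary_idx > m))) {
    abort("`binary_idx` must be indices in 1..m.")
  }
  structure(list(
    n = n, m = m, informative_idx = informative_idx, beta = as.numeric(beta),
    beta0 = as.numeric(beta0), feature_corr = as.numeric(feature_corr),
    missing_rate = as.numeric(missing_rate),
    binary_idx = as.integer(binary_idx), seed = as.integer(seed)
  ), class = "synthetic_spec")
}

#' Cohort preset shaped like a mid-size heart-failure readmission study
#'
#' A convenience [synthetic_spec()] with 736 patients, 105 features, ten
#' informative features with log-odds coefficients of magnitude 0.3, and the
#' intercept chosen by bisection so the expected outcome prevalence is 0.63
#' (about 461 events in 736 patients).
#'
#' @param seed Integer seed passed to the spec.
#' @param prevalence Target expected prevalence; default 0.63.
#' @return A `synthetic_spec`.
#' @export
study_shaped_spec <- function(seed = 1L, prevalence = 0.63) {
  informative_idx <- c(3L, 7L, 12L, 21L, 32L, 57L, 60L, 78L, 87L, 99L)
  beta <- rep(c(0.3, -0.3), 5L)
  beta0 <- calibrate_intercept(beta, feature_corr = 0, prevalence = prevalence)
  synthetic_spec(n = 736L, m = 105L, informative_idx = informative_idx,
                 beta = beta, beta0 = beta0, seed = seed)
}

# Expected prevalence E[sigmoid(beta0 + s Z)], Z ~ N(0,1), where s is the sd
# of the linear predictor under the equicorrelated Gaussian design; solved
# for beta0 by uniroot (bisection-style bracketing on a monotone function).
calibrate_intercept <- function(beta, feature_corr, prevalence) {
  k <- length(beta)
  s2 <- (1 - feature_corr) * sum(beta^2) + feature_corr * sum(beta)^2
  s <- sqrt(s2)
  expected_prev <- function(b0) {
    stats::integrate(function(z) plogis(b0 + s * z) * stats::dnorm(z),
                     -Inf, Inf)$value - prevalence
  }
  uniroot(expected_prev, interval = c(-10, 10), tol = 1e-10)$root
}

#' Generate a synthetic cohort with known informative features
#'
#' Draws `n` patients with `m` standard-normal features under an
#' equicorrelation structure, forms the linear predictor
#' `eta = beta0 + sum_j beta_j x_j` over the informative features, draws the
#' binary outcome from `Bernoulli(sigmoid(eta))`, and optionally masks
#' feature cells at the spec's `missing_rate`.
#'
#' @param spec A [synthetic_spec()].
#' @return A list of class `synthetic_cohort` with elements `data` (tibble of
#'   features plus `outcome`; contains `NA` when `missing_rate > 0`),
#'   `truth_mask` (length-`m` logical marking informative features),
#'   `true_probs` (length-`n` generative probabilities), and `spec`.
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "synthetic_spec")) {
    abort("`spec` must be created with synthetic_spec().")
  }
  out <- local_seed(spec$seed, {
    rho <- spec$feature_corr
    Z <- matrix(rnorm(spec$n * spec$m), spec$n, spec$m)
    X <- if (rho > 0) {
      z0 <- rnorm(spec$n)
      sqrt(rho) * z0 + sqrt(1 - rho) * Z
    } else {
      Z
    }
    if (length(spec$binary_idx) > 0L) {
      X[, spec$binary_idx] <- (X[, spec$binary_idx] > 0) * 1
    }
    eta <- rep(spec$beta0, spec$n)
    if (length(spec$informative_idx) > 0L) {
      eta <- eta + as.numeric(X[, spec$informative_idx, drop = FALSE] %*% spec$beta)
    }
    p <- plogis(eta)
    y <- rbinom(spec$n, 1L, p)
    list(X = X, p = p, y = y)
  })
  feature_names <- sprintf("f%03d", seq_len(spec$m))
  data <- as_tibble(as.data.frame(out$X, col.names = feature_names))
  names(data) <- feature_names
  data$outcome <- out$y
  if (spec$missing_rate > 0) {
    data <- inject_missingness(data, spec$missing_rate,
                               seed = spec$seed + 1L, outcome = "outcome")
  }
  truth_mask <- seq_len(spec$m) %in% spec$informative_idx
  structure(list(data = data, truth_mask = truth_mask,
                 true_probs = out$p, spec = spec),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic cohort: %d patients x %d features, %d informative, prevalence %.3f\n",
    x$spec$n, x$spec$m, sum(x$truth_mask), mean(x$data$outcome)))
  invisible(x)
}

#' Mask feature cells at random
#'
#' Independently replaces each feature cell with `NA` with probability
#' `missing_rate`; the outcome column is never masked. Deterministic given
#' `seed`. Used to exercise the missingness filter and median imputation on
#' data whose complete version is known.
#'
#' @param data A complete cohort tibble.
#' @param missing_rate Per-cell masking probability in `[0, 1)`.
#' @param seed Integer seed for the mask.
#' @param outcome Name of the outcome column.
#' @return The tibble with masked feature cells.
#' @export
inject_missingness <- function(data, missing_rate, seed = 1L,
                               outcome = "outcome") {
  if (!is.data.frame(data)) abort("`data` must be a data frame.")
  if (missing_rate < 0 || missing_rate >= 1) {
    abort("`missing_rate` must be in [0, 1).")
  }
  if (missing_rate == 0) return(tibble::as_tibble(data))
  feats <- setdiff(names(data), outcome)
  out <- tibble::as_tibble(data)
  mask <- local_seed(seed, {
    matrix(runif(nrow(data) * length(feats)) < missing_rate,
           nrow(data), length(feats))
  })
  for (i in seq_along(feats)) {
    col <- out[[feats[i]]]
    col[mask[, i]] <- NA
    out[[feats[i]]] <- col
  }
  out
}

#' Write a synthetic cohort to disk
#'
#' Emits the cohort as a CSV (the same dialect [read_feature_table()] reads)
#' plus a JSON sidecar holding the generating spec and the informative-feature
#' mask.
#'
#' @param cohort A `synthetic_cohort`.
#' @param path Output CSV path; the sidecar is written next to it with a
#'   `.truth.json` suffix.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  if (!inherits(cohort, "synthetic_cohort")) {
    abort("`cohort` must be a synthetic_cohort.")
  }
  readr::write_csv(cohort$data, path, na = "")
  sidecar <- sub("\\.csv$", "", path)
  sidecar <- paste0(sidecar, ".truth.json")
  jsonlite::write_json(
    list(spec = unclass(cohort$spec), truth_mask = cohort$truth_mask),
    sidecar, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
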