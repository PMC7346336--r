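# Internal helpers shared across the package.

# Run `code` under a fixed RNG seed without disturbing the caller's RNG state.
local_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# Split a cohort data frame into the numeric design matrix, the 0/1 label
# vector and the feature names. All user-facing functions funnel through here
# so validation lives in one place.
cohort_matrices <- function(data, outcome) {
  if (!is.data.frame(data)) {
    abort("`data` must be a data frame of patient features plus an outcome column.")
  }
  if (!is.character(outcome) || length(outcome) != 1L) {
    abort("`outcome` must be a single column name.")
  }
  if (!outcome %in% names(data)) {
    abort(sprintf("Outcome column '%s' not found in `data`.", outcome))
  }
  feature_names <- setdiff(names(data), outcome)
  if (length(feature_names) == 0L) {
    abort("`data` has no feature columns besides the outcome.")
  }
  X <- as.matrix(data[feature_names])
  if (!is.numeric(X)) {
    abort("All feature columns must be numeric.")
  }
  y <- data[[outcome]]
  if (!all(y %in% c(0, 1))) {
    abort(sprintf("Outcome column '%s' must be strictly binary (0/1).", outcome))
  }
  storage.mode(X) <- "double"
  list(X = X, y = as.numeric(y), feature_names = feature_names)
}

check_both_classes <- function(y, what = "data") {
  if (length(unique(y)) < 2L) {
    abort(sprintf("Both outcome classes must be present in the %s.", what))
  }
  invisible(y)
}

check_finite <- function(x, what) {
  if (!all(is.finite(x))) {
    abort(sprintf("Non-finite values in %s.", what))
  }
  invisible(x)
}

# Stratified index split: returns the indices assigned to the first part.
# Sizes are rounded per class so prevalence is preserved to within one
# patient per class.
stratified_first_part <- function(y, fraction) {
  idx1 <- integer(0)
  for (cls in sort(unique(y))) {
    cls_idx <- which(y == cls)
    n_take <- round(length(cls_idx) * fraction)
    n_take <- max(1L, min(length(cls_idx) - 1L, n_take))
    idx1 <- c(idx1, sample(cls_idx, n_take))
  }
  sort(idx1)
}

# Stratified fold assignment: a length-n integer vector of fold ids 1..k.
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    cls_idx <- sample(which(y == cls))
    fold[cls_idx] <- rep_len(seq_len(k), length(cls_idx))
  }
  fold
}
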