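#' Read a delimited patient feature table
#'
#' Reads a CSV/TSV file with a header row into a tibble of numeric feature
#' columns plus one binary outcome column. Cells equal to any of the
#' `missing` markers (the empty cell included) become `NA`; any other
#' non-numeric cell is an error naming the offending column and row.
#'
#' @param path Path to a delimited text file with a header row.
#' @param outcome Name of the outcome (label) column; values must be 0/1 or
#'   missing.
#' @param missing Character vector of missing-value markers.
#' @param delim Field delimiter; `NULL` guesses `","` vs `"\t"` from the
#'   header line.
#' @return A tibble with all feature columns numeric (`NA` where missing) and
#'   the outcome column last.
#' @seealso [filter_missing_features()], [impute_median()]
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("age,sbp,outcome", "63,NA,1", "71,122,0"), f)
#' read_feature_table(f, outcome = "outcome")
read_feature_table <- function(path, outcome = "outcome",
                               missing = c("", "NA", "NaN"), delim = NULL) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  header <- readLines(path, n = 1L)
  if (is.null(delim)) {
    delim <- if (grepl("\t", header)) "\t" else ","
  }
  raw_names <- gsub('^"|"$', "", strsplit(header, delim, fixed = TRUE)[[1L]])
  if (anyDuplicated(raw_names)) {
    abort(sprintf("Duplicated header name(s): %s",
                  paste(unique(raw_names[duplicated(raw_names)]), collapse = ", ")))
  }
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()
  ), na = character(), progress = FALSE, show_col_types = FALSE)
  nm <- names(raw)
  if (!outcome %in% nm) {
    abort(sprintf("Label column '%s' not found in header (%s).",
                  outcome, paste(nm, collapse = ", ")))
  }
  parsed <- purrr::imap(raw, function(col, name) {
    col[col %in% missing] <- NA_character_
    num <- suppressWarnings(as.numeric(col))
    bad <- which(!is.na(col) & is.na(num))
    if (length(bad) > 0L) {
      abort(sprintf("Non-numeric value '%s' in column '%s', row %d.",
                    col[bad[1L]], name, bad[1L]))
    }
    num
  })
  out <- as_tibble(parsed)
  lab <- out[[outcome]]
  if (!all(lab[!is.na(lab)] %in% c(0, 1))) {
    abort(sprintf("Label column '%s' must contain only 0/1 (or missing).", outcome))
  }
  dplyr::relocate(out, !!rlang::sym(outcome), .after = dplyr::last_col())
}

#' Drop features with excessive missingness
#'
#' Removes every feature column whose fraction of missing values is strictly
#' greater than `max_missing` (a feature missing exactly that fraction is
#' kept). The order of retained columns is preserved. The dropped features
#' and counts are recorded and retrievable with [preprocess_report()].
#'
#' @param data A data frame of feature columns (may contain `NA`) plus the
#'   outcome column.
#' @param outcome Name of the outcome column (never filtered).
#' @param max_missing Maximum tolerated missing fraction, in `[0, 1)`.
#'   Default 0.30: features more than 30% missing are excluded.
#' @return `data` without the over-missing features, with the preprocessing
#'   record attached.
#' @export
filter_missing_features <- function(data, outcome = "outcome",
                                    max_missing = 0.30) {
  if (!is.data.frame(data)) abort("`data` must be a data frame.")
  if (!outcome %in% names(data)) {
    abort(sprintf("Outcome column '%s' not found in `data`.", outcome))
  }
  if (!is.numeric(max_missing) || max_missing < 0 || max_missing >= 1) {
    abort("`max_missing` must be in [0, 1).")
  }
  feats <- setdiff(names(data), outcome)
  frac <- vapply(data[feats], function(x) mean(is.na(x)), numeric(1))
  drop <- feats[frac > max_missing]
  keep <- setdiff(feats, drop)
  if (length(keep) == 0L) {
    abort("All features exceed the missingness threshold; no features remain.")
  }
  out <- tibble::as_tibble(data[c(keep, outcome)])
  attr(out, "dropped_features") <- tibble(
    feature = drop, missing_fraction = unname(frac[drop])
  )
  attr(out, "n_cols_before") <- length(feats)
  out
}

#' Impute missing feature values by the feature median
#'
#' Replaces each missing cell with the median of that feature's non-missing
#' values, computed over all rows of `data`. Errors if a feature is entirely
#' missing (it should have been filtered first) or if any label is missing.
#'
#' @inheritParams filter_missing_features
#' @return A complete tibble (no `NA`), with the imputation medians attached
#'   (see [preprocess_report()]).
#' @export
impute_median <- function(data, outcome = "outcome") {
  if (!is.data.frame(data)) abort("`data` must be a data frame.")
  if (!outcome %in% names(data)) {
    abort(sprintf("Outcome column '%s' not found in `data`.", outcome))
  }
  if (anyNA(data[[outcome]])) {
    abort(sprintf("Missing values in label column '%s'.", outcome))
  }
  feats <- setdiff(names(data), outcome)
  fully_missing <- feats[vapply(data[feats], function(x) all(is.na(x)), logical(1))]
  if (length(fully_missing) > 0L) {
    abort(sprintf("Feature(s) entirely missing, cannot impute: %s",
                  paste(fully_missing, collapse = ", ")))
  }
  meds <- vapply(data[feats], function(x) median(x, na.rm = TRUE), numeric(1))
  out <- data
  for (f in feats) {
    miss <- is.na(out[[f]])
    if (any(miss)) out[[f]][miss] <- meds[[f]]
  }
  out <- tibble::as_tibble(out)
  attr(out, "imputation_medians") <- tibble(feature = feats, median = unname(meds))
  attr(out, "dropped_features") <- attr(data, "dropped_features", exact = TRUE)
  attr(out, "n_cols_before") <- attr(data, "n_cols_before", exact = TRUE)
  out
}

#' Summarise the preprocessing applied to a cohort
#'
#' Collects the record left behind by [filter_missing_features()] and
#' [impute_median()]: which features were dropped and at what missing
#' fraction, the imputation medians, and the table dimensions.
#'
#' @param data A tibble returned by the preprocessing verbs.
#' @param outcome Name of the outcome column.
#' @return A list of class `preprocess_report` with elements
#'   `dropped_features` (tibble), `imputation_medians` (tibble), `n_rows`,
#'   `n_cols_before`, `n_cols_after`.
#' @export
preprocess_report <- function(data, outcome = "outcome") {
  n_after <- length(setdiff(names(data), outcome))
  rep <- list(
    dropped_features = attr(data, "dropped_features", exact = TRUE) %||%
      tibble(feature = character(), missing_fraction = numeric()),
    imputation_medians = attr(data, "imputation_medians", exact = TRUE) %||%
      tibble(feature = character(), median = numeric()),
    n_rows = nrow(data),
    n_cols_before = attr(data, "n_cols_before", exact = TRUE) %||% n_after,
    n_cols_after = n_after
  )
  structure(rep, class = "preprocess_report")
}

#' @export
print.preprocess_report <- function(x, ...) {
  cat(sprintf("Preprocessing report: %d rows, %d -> %d features\n",
              x$n_rows, x$n_cols_before, x$n_cols_after))
  if (nrow(x$dropped_features) > 0L) {
    cat("Dropped (missing fraction above threshold):\n")
    print(x$dropped_features)
  } else {
    cat("No features dropped.\n")
  }
  invisible(x)
}

#' Standardize features to zero mean and unit variance
#'
#' Transforms each feature to `(x - mean) / sd` (sample standard deviation,
#' `n - 1` denominator). When `stats` is supplied — typically the statistics
#' computed on a training split — those means and sds are applied instead of
#' recomputing, so test data is scaled exactly as the training data was.
#' A zero-variance feature is centered but left unscaled.
#'
#' @inheritParams filter_missing_features
#' @param stats Optional tibble with columns `feature`, `mean`, `sd`, one row
#'   per feature column of `data` (as returned by a previous call via
#'   [scaling_stats()]).
#' @return The transformed tibble with the scaling statistics attached;
#'   retrieve them with [scaling_stats()].
#' @export
standardize_features <- function(data, outcome = "outcome", stats = NULL) {
  mats <- cohort_check_features(data, outcome)
  feats <- mats$feature_names
  if (is.null(stats)) {
    stats <- tibble(
      feature = feats,
      mean = vapply(data[feats], mean, numeric(1)),
      sd = vapply(data[feats], sd, numeric(1))
    )
  } else {
    if (!all(c("feature", "mean", "sd") %in% names(stats))) {
      abort("`stats` must have columns feature, mean, sd.")
    }
    if (!setequal(stats$feature, feats) || nrow(stats) != length(feats)) {
      abort("`stats` must have exactly one row per feature column of `data`.")
    }
    stats <- stats[match(feats, stats$feature), ]
  }
  out <- data
  for (i in seq_along(feats)) {
    f <- feats[i]
    s <- stats$sd[i]
    centered <- out[[f]] - stats$mean[i]
    out[[f]] <- if (is.na(s) || s == 0) centered else centered / s
  }
  out <- tibble::as_tibble(out)
  attr(out, "scaling_stats") <- stats
  out
}

#' @rdname standardize_features
#' @export
scaling_stats <- function(data) {
  attr(data, "scaling_stats", exact = TRUE)
}

# Feature-column validation shared by functions that need complete numeric
# features but not a binary label (standardization runs pre- or post-split).
cohort_check_features <- function(data, outcome) {
  if (!is.data.frame(data)) abort("`data` must be a data frame.")
  if (!outcome %in% names(data)) {
    abort(sprintf("Outcome column '%s' not found in `data`.", outcome))
  }
  feats <- setdiff(names(data), outcome)
  if (!all(vapply(data[feats], is.numeric, logical(1)))) {
    abort("All feature columns must be numeric.")
  }
  list(feature_names = feats)
}

#' Stratified train/test holdout split
#'
#' Splits a cohort into disjoint, exhaustive train and test sets, stratified
#' by the outcome so both parts keep the cohort prevalence to within one
#' patient per class. Deterministic given `seed`.
#'
#' @inheritParams filter_missing_features
#' @param train_fraction Fraction of patients assigned to the training set,
#'   in `(0, 1)`. Default 0.8.
#' @param seed Integer seed controlling the split.
#' @return A list with tibbles `train` and `test`.
#' @export
split_holdout <- function(data, outcome = "outcome", train_fraction = 0.8,
                          seed = 1L) {
  mats <- cohort_matrices(data, outcome)
  if (train_fraction <= 0 || train_fraction >= 1) {
    abort("`train_fraction` must be in (0, 1).")
  }
  check_both_classes(mats$y, "cohort being split")
  idx <- local_seed(seed, stratified_first_part(mats$y, train_fraction))
  list(train = tibble::as_tibble(data[idx, , drop = FALSE]),
       test = tibble::as_tibble(data[-idx, , drop = FALSE]))
}
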