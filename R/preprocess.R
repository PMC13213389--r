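#' Clean a cohort by listwise deletion
#'
#' Drops administrative columns and removes every row with at least one
#' missing biomarker or target cell (no imputation). Row order is otherwise
#' preserved.
#'
#' @param cohort A cohort tibble.
#' @param excluded_columns Column names to drop; absent names are ignored.
#' @return The cleaned tibble.
#' @export
#' @examples
#' cohort <- generate_cohort(seed = 1)
#' cleaned <- clean_cohort(cohort)
clean_cohort <- function(cohort, excluded_columns = c("Site", "Race")) {
  keep <- setdiff(names(cohort), excluded_columns)
  cohort <- cohort[, keep]
  value_cols <- intersect(
    c(biomarker_names(), "ALM", "BFP", "BMD"), names(cohort)
  )
  complete <- stats::complete.cases(cohort[, value_cols])
  out <- cohort[complete, ]
  if (nrow(out) == 0) {
    abort("cleaning removed every row: no complete cases remain")
  }
  out
}

#' Split a cohort into male, female and combined strata
#'
#' The sex column is consumed: none of the three returned tables carries it,
#' matching the convention of fitting each stratum separately.
#'
#' @param cohort A cohort tibble with a `sex` column in `{male, female}`.
#' @return Named list of tibbles: `male`, `female`, `combined`.
#' @export
stratify_by_sex <- function(cohort) {
  if (!"sex" %in% names(cohort)) abort("cohort has no `sex` column")
  bad <- setdiff(unique(cohort$sex), c("male", "female"))
  if (length(bad) > 0) {
    abort(paste0("unknown sex category: ", paste(bad, collapse = ", ")))
  }
  drop_sex <- function(d) d[, setdiff(names(d), "sex")]
  list(
    male = drop_sex(cohort[cohort$sex == "male", ]),
    female = drop_sex(cohort[cohort$sex == "female", ]),
    combined = drop_sex(cohort)
  )
}

#' Fit a z-score scaler
#'
#' Estimates per-column means and population SDs (divide by n) from a
#' reference set, for later application to any compatible matrix. The split
#' into fit and apply keeps fold-internal scaling leak-free: fit on the
#' training fold, apply to both folds.
#'
#' @param X Numeric matrix or data frame of features.
#' @return An object of class `zscore_params`.
#' @export
#' @examples
#' p <- zscore_fit(matrix(1:6, ncol = 2))
#' zscore_apply(p, matrix(1:6, ncol = 2))
zscore_fit <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) == 0) abort("cannot fit scaler on empty data")
  mu <- colMeans(X)
  sigma <- sqrt(colMeans(sweep(X, 2, mu)^2))
  if (any(sigma < 1e-12)) {
    abort(paste0(
      "constant feature(s): ",
      paste(colnames(X)[sigma < 1e-12], collapse = ", ")
    ))
  }
  structure(list(mean = mu, sd = sigma), class = "zscore_params")
}

#' Apply a fitted z-score scaler
#'
#' @param params A `zscore_params` from [zscore_fit()].
#' @param X Matrix or data frame with the same columns as the fit set.
#' @return Numeric matrix of standardized features.
#' @export
zscore_apply <- function(params, X) {
  X <- as.matrix(X)
  sweep(sweep(X, 2, params$mean), 2, params$sd, "/")
}

#' Rank features by correlation with a target
#'
#' Computes the Pearson correlation (sample convention, n - 1) of every
#' feature with the target and orders features by descending absolute
#' correlation. Ties keep original column order.
#'
#' @param X Numeric matrix or data frame of features.
#' @param y Numeric target vector.
#' @return Tibble with columns `feature` and `r`, strongest first.
#' @export
#' @examples
#' X <- data.frame(a = c(1, 2, 3), b = c(3, 1, 2))
#' pearson_rank(X, c(1, 2, 4))
pearson_rank <- function(X, y) {
  X <- as.matrix(X)
  if (nrow(X) < 2) abort("need at least 2 rows")
  if (stats::sd(y) == 0) abort("constant target: correlation undefined")
  r <- as.numeric(stats::cor(X, y))
  out <- tibble::tibble(
    feature = colnames(X) %||% as.character(seq_len(ncol(X))), r = r
  )
  out[order(-abs(out$r)), ]
}

#' Top-m features of a correlation ranking
#'
#' @param ranked Output of [pearson_rank()].
#' @param m Number of features to keep (default 10).
#' @return Character vector of feature names.
#' @export
top_m <- function(ranked, m = 10) {
  if (m > nrow(ranked)) abort("m exceeds the number of ranked features")
  ranked$feature[seq_len(m)]
}

#' Write a feature ranking as CSV
#'
#' @param ranked Output of [pearson_rank()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_ranked_features <- function(ranked, path) {
  readr::write_csv(ranked, path)
  invisible(path)
}
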