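#' Generate a synthetic anthropometric cohort
#'
#' Draws a sex-stratified cohort from a Gaussian copula whose latent
#' correlation matrix is assembled by [spec_correlation_matrix()]. Marginals
#' are transformed per variable: normal marginals by an affine map to the
#' specified mean/SD; right-skewed marginals (appendicular lean mass, age)
#' by a shifted lognormal matched to the same mean/SD. Body fat percentage
#' is clipped to (0.1, 99.9). The same `(spec, seed)` pair always yields a
#' byte-identical table.
#'
#' @param spec A [cohort_spec]; defaults to [default_cohort_spec()].
#' @param seed Integer RNG seed.
#' @return Tibble with columns `id`, `sex`, `Site`, `Race`, the 44
#'   biomarkers in [biomarker_names()] order, and `ALM`, `BFP`, `BMD`.
#' @export
#' @examples
#' cohort <- generate_cohort(seed = 1)
#' nrow(cohort)   # 515 = 245 males + 270 females
generate_cohort <- function(spec = default_cohort_spec(), seed) {
  if (any(spec$group_sizes < 1)) abort("non-positive group size")
  withr::with_seed(as.integer(seed), {
    parts <- lapply(c("male", "female"), function(sx) {
      generate_stratum(spec, sx, spec$group_sizes[[sx]])
    })
    cohort <- dplyr::bind_rows(parts)
    n <- nrow(cohort)
    cohort$id <- sprintf("P%04d", seq_len(n))
    cohort$Site <- sample(c("proscanner", "styku", "ss20"), n, replace = TRUE)
    cohort$Race <- sample(
      c("group_a", "group_b", "group_c", "unreported"), n,
      replace = TRUE, prob = c(0.55, 0.25, 0.1, 0.1)
    )
    dplyr::select(
      cohort, "id", "sex", "Site", "Race",
      dplyr::all_of(biomarker_names()), "ALM", "BFP", "BMD"
    )
  })
}

generate_stratum <- function(spec, sex, n) {
  R <- spec_correlation_matrix(spec, sex)
  vars <- colnames(R)
  Z <- matrix(stats::rnorm(n * length(vars)), nrow = n) %*% chol(R)
  colnames(Z) <- vars

  moments <- dplyr::bind_rows(
    spec$biomarkers[, c("name", paste0(sex, "_mean"), paste0(sex, "_sd"))] |>
      stats::setNames(c("name", "mean", "sd")),
    spec$targets[, c("name", paste0(sex, "_mean"), paste0(sex, "_sd"))] |>
      stats::setNames(c("name", "mean", "sd"))
  )
  out <- lapply(vars, function(v) {
    m <- moments$mean[moments$name == v]
    s <- moments$sd[moments$name == v]
    shape <- spec$marginal_shapes[[v]] %||% "normal"
    transform_marginal(Z[, v], m, s, shape, spec$lognormal_sigma[[v]])
  })
  names(out) <- vars
  out$BFP <- pmin(pmax(out$BFP, 0.1), 99.9)
  tibble::as_tibble(out) |> dplyr::mutate(sex = sex, .before = 1)
}

# Map a standard-normal draw to the requested marginal. The shifted
# lognormal a + b*exp(sigma*z) is matched to (mean, sd) in closed form,
# so moments are exact in expectation for any shape parameter sigma.
transform_marginal <- function(z, mean, sd, shape, sigma = NA_real_) {
  if (identical(shape, "lognormal")) {
    if (!is.finite(sigma) || sigma <= 0) {
      abort("lognormal marginal requires a positive sigma")
    }
    sd_ln <- sqrt(exp(sigma^2) * (exp(sigma^2) - 1))
    b <- sd / sd_ln
    a <- mean - b * exp(sigma^2 / 2)
    a + b * exp(sigma * z)
  } else {
    mean + sd * z
  }
}

#' Blank biomarker cells in randomly chosen rows
#'
#' Selects exactly `n_incomplete` rows uniformly at random (missing
#' completely at random) and sets at least one randomly chosen biomarker
#' cell in each to `NA`. Used to build cleaning fixtures that reproduce an
#' enrollment of complete plus incomplete records.
#'
#' @param cohort A cohort tibble.
#' @param n_incomplete Number of rows to damage (0 returns the cohort
#'   unchanged).
#' @param seed Integer RNG seed.
#' @return The cohort with `NA`s injected.
#' @export
#' @examples
#' cohort <- generate_cohort(seed = 1)
#' damaged <- inject_missingness(cohort, 100, seed = 2)
#' sum(!stats::complete.cases(damaged[, biomarker_names()]))
inject_missingness <- function(cohort, n_incomplete, seed) {
  n <- nrow(cohort)
  if (n_incomplete < 0 || n_incomplete > n) {
    abort("n_incomplete must be between 0 and nrow(cohort)")
  }
  if (n_incomplete == 0) return(cohort)
  cols <- intersect(biomarker_names(), names(cohort))
  withr::with_seed(as.integer(seed), {
    rows <- sample.int(n, n_incomplete)
    for (r in rows) {
      k <- sample.int(3L, 1L)
      blank <- sample(cols, k)
      cohort[r, blank] <- NA_real_
    }
  })
  cohort
}

#' Write / read a cohort as CSV
#'
#' UTF-8, `.` decimal separator, missing cells written empty.
#'
#' @param cohort A cohort tibble.
#' @param path File path.
#' @return `write_cohort_csv()` returns `path` invisibly;
#'   `read_cohort_csv()` returns a tibble.
#' @export
write_cohort_csv <- function(cohort, path) {
  readr::write_csv(cohort, path, na = "")
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  readr::read_csv(path, na = "", show_col_types = FALSE)
}
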