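#' Default synthetic-cohort specification
#'
#' Builds the [cohort_spec] calibrated to the reference cohort: 245 males and
#' 270 females; 44 biomarkers in [biomarker_names()] order; per-sex marginal
#' means and SDs for the three targets (ALM 21.88/7.95 male, 15.77/4.24
#' female; BFP 25.20/7.67 male, 34.71/7.37 female; BMD 1.07/0.19 male,
#' 1.00/0.14 female) plus height, weight and age; (biomarker, target)
#' correlations from [reference_correlations()]; bilateral left/right pairs
#' set to high mutual correlation; appendicular lean mass and age drawn with
#' right-skewed (shifted-lognormal) marginals.
#'
#' @return An object of class `cohort_spec`.
#' @export
#' @examples
#' spec <- default_cohort_spec()
#' spec$group_sizes
default_cohort_spec <- function() {
  marg <- default_biomarker_marginals()
  marg <- marg[match(biomarker_names(), marg$name), ]
  targets <- tibble::tibble(
    name = c("ALM", "BFP", "BMD"),
    unit = c("kg", "%", "g/cm^2"),
    male_mean = c(21.88, 25.20, 1.07),
    male_sd = c(7.95, 7.67, 0.19),
    female_mean = c(15.77, 34.71, 1.00),
    female_sd = c(4.24, 7.37, 0.14)
  )
  shapes <- stats::setNames(rep("normal", 47), c(marg$name, targets$name))
  shapes[c("ALM", "age")] <- "lognormal"
  # lognormal shape: mild skew for lean mass, strong right skew for age
  sigmas <- stats::setNames(rep(NA_real_, 47), names(shapes))
  sigmas["ALM"] <- 0.25
  sigmas["age"] <- 1.0
  cohort_spec(
    group_sizes = c(male = 245L, female = 270L),
    biomarkers = marg,
    targets = targets,
    target_correlations = dplyr::filter(
      reference_correlation_table(), .data$dataset %in% c("male", "female")
    ),
    bilateral = bilateral_pairs(),
    bilateral_rho = 0.95,
    fill_rho = 0.3,
    marginal_shapes = shapes,
    lognormal_sigma = sigmas
  )
}

#' Construct a cohort specification
#'
#' Low-level constructor for the synthetic-cohort generator settings. Most
#' users want [default_cohort_spec()] and should modify its fields.
#'
#' @param group_sizes Named integer vector `c(male = ..., female = ...)`.
#' @param biomarkers Tibble with columns `name`, `male_mean`, `male_sd`,
#'   `female_mean`, `female_sd`, one row per biomarker, in column order.
#' @param targets Same layout for the target variables `ALM`, `BFP`, `BMD`.
#' @param target_correlations Tibble `(target, dataset, biomarker, rho)` of
#'   calibrated per-sex Pearson correlations (`dataset` in male/female).
#' @param bilateral Tibble of left/right biomarker pairs.
#' @param bilateral_rho Correlation assigned to bilateral pairs.
#' @param fill_rho Floor correlation for unspecified pairs.
#' @param marginal_shapes Named character vector, `"normal"` or
#'   `"lognormal"`, one entry per biomarker and target.
#' @param lognormal_sigma Named numeric vector of lognormal shape
#'   parameters (NA for normal marginals).
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(group_sizes, biomarkers, targets, target_correlations,
                        bilateral, bilateral_rho = 0.95, fill_rho = 0.3,
                        marginal_shapes = NULL, lognormal_sigma = NULL) {
  spec <- structure(
    list(
      group_sizes = group_sizes,
      biomarkers = tibble::as_tibble(biomarkers),
      targets = tibble::as_tibble(targets),
      target_correlations = tibble::as_tibble(target_correlations),
      bilateral = tibble::as_tibble(bilateral),
      bilateral_rho = bilateral_rho,
      fill_rho = fill_rho,
      marginal_shapes = marginal_shapes,
      lognormal_sigma = lognormal_sigma
    ),
    class = "cohort_spec"
  )
  validate_cohort_spec(spec)
  spec
}

#' Validate a cohort specification
#'
#' Checks positivity of SDs and group sizes, correlation bounds, and that the
#' assembled per-sex correlation matrices are positive semi-definite after
#' repair (minimum eigenvalue above -1e-8).
#'
#' @param spec A `cohort_spec`.
#' @return `spec`, invisibly; aborts on violation.
#' @export
validate_cohort_spec <- function(spec) {
  if (any(spec$group_sizes < 1)) {
    abort("all group sizes must be >= 1")
  }
  sds <- c(
    spec$biomarkers$male_sd, spec$biomarkers$female_sd,
    spec$targets$male_sd, spec$targets$female_sd
  )
  if (any(!is.finite(sds)) || any(sds <= 0)) {
    abort("all marginal SDs must be positive")
  }
  if (any(abs(spec$target_correlations$rho) > 1)) {
    abort("all correlations must satisfy |rho| <= 1")
  }
  for (sx in c("male", "female")) {
    R <- spec_correlation_matrix(spec, sx)
    ev <- min(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
    if (ev < -1e-8) {
      abort(sprintf(
        "correlation matrix for %s cohort not repairable (min eigenvalue %.3g)",
        sx, ev
      ))
    }
  }
  invisible(spec)
}

#' Assembled latent correlation matrix for one sex
#'
#' Builds the 47x47 (44 biomarkers + 3 targets) correlation matrix used by
#' the Gaussian copula. Calibrated (biomarker, target) correlations are taken
#' from the spec; unspecified predictor-predictor entries are filled with the
#' value implied by a shared-factor structure (product of the two variables'
#' target loadings through the target-target couplings), floored at
#' `fill_rho`; bilateral pairs are raised to `bilateral_rho`; the result is
#' projected to the nearest correlation matrix (Higham-style eigenvalue
#' clipping via [Matrix::nearPD()]) if it is not already positive
#' semi-definite.
#'
#' @param spec A `cohort_spec`.
#' @param sex `"male"` or `"female"`.
#' @return Symmetric correlation matrix with dimnames (biomarkers then
#'   ALM, BFP, BMD).
#' @export
spec_correlation_matrix <- function(spec, sex) {
  sex <- match.arg(sex, c("male", "female"))
  bn <- spec$biomarkers$name
  tn <- spec$targets$name
  nb <- length(bn)
  nt <- length(tn)
  nv <- nb + nt

  # loading matrix: calibrated biomarker-target correlations, 0 elsewhere
  L <- matrix(0, nb, nt, dimnames = list(bn, tn))
  tc <- dplyr::filter(spec$target_correlations, .data$dataset == sex)
  for (r in seq_len(nrow(tc))) {
    L[tc$biomarker[r], tc$target[r]] <- tc$rho[r]
  }
  # propagate loadings across bilateral pairs: if one side is calibrated
  # and its mirror is not, the mirror inherits bilateral_rho * loading,
  # keeping the (pair, target) triangles internally consistent
  Lcal <- L
  for (r in seq_len(nrow(spec$bilateral))) {
    l <- spec$bilateral$left[r]
    rr <- spec$bilateral$right[r]
    L[l, ] <- pmax(L[l, ], spec$bilateral_rho * Lcal[rr, ])
    L[rr, ] <- pmax(L[rr, ], spec$bilateral_rho * Lcal[l, ])
  }

  # target-target couplings implied by shared loadings, floored
  Phi <- diag(nt)
  for (s in seq_len(nt - 1)) {
    for (t in (s + 1):nt) {
      Phi[s, t] <- Phi[t, s] <- max(max(L[, s] * L[, t]), 0.25)
    }
  }

  R <- matrix(0, nv, nv, dimnames = list(c(bn, tn), c(bn, tn)))
  diag(R) <- 1
  # predictor-predictor: factor-implied value, floored at fill_rho
  LPhi <- L %*% Phi
  for (i in seq_len(nb - 1)) {
    for (j in (i + 1):nb) {
      imp <- max(outer(L[i, ], L[j, ]) * Phi)
      R[i, j] <- R[j, i] <- max(spec$fill_rho, imp)
    }
  }
  for (r in seq_len(nrow(spec$bilateral))) {
    i <- spec$bilateral$left[r]
    j <- spec$bilateral$right[r]
    R[i, j] <- R[j, i] <- max(spec$bilateral_rho, R[i, j])
  }
  # biomarker-target: calibrated value, else factor-implied, floored
  for (t in seq_len(nt)) {
    for (i in seq_len(nb)) {
      v <- if (L[i, t] != 0) L[i, t] else max(spec$fill_rho, LPhi[i, t])
      R[i, nb + t] <- R[nb + t, i] <- v
    }
  }
  R[nb + seq_len(nt), nb + seq_len(nt)] <- Phi

  ev <- min(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
  if (ev < 1e-10) {
    R <- as.matrix(Matrix::nearPD(R, corr = TRUE, conv.tol = 1e-11)$mat)
    dimnames(R) <- list(c(bn, tn), c(bn, tn))
  }
  R
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec>\n")
  cat("  group sizes:",
      paste(sprintf("%s=%d", names(x$group_sizes), x$group_sizes),
            collapse = ", "), "\n")
  cat("  biomarkers:", nrow(x$biomarkers),
      " targets:", paste(x$targets$name, collapse = ", "), "\n")
  cat("  calibrated correlations:", nrow(x$target_correlations),
      " bilateral pairs:", nrow(x$bilateral), "\n")
  invisible(x)
}

#' Write / read a cohort specification as YAML
#'
#' @param spec A `cohort_spec`.
#' @param path File path.
#' @return `write_cohort_spec()` returns `path` invisibly;
#'   `read_cohort_spec()` returns a `cohort_spec`.
#' @export
write_cohort_spec <- function(spec, path) {
  lst <- list(
    group_sizes = as.list(spec$group_sizes),
    biomarkers = lapply(seq_len(nrow(spec$biomarkers)), function(i) {
      as.list(spec$biomarkers[i, ])
    }),
    targets = lapply(seq_len(nrow(spec$targets)), function(i) {
      as.list(spec$targets[i, ])
    }),
    target_correlations = lapply(
      seq_len(nrow(spec$target_correlations)),
      function(i) as.list(spec$target_correlations[i, ])
    ),
    bilateral = lapply(seq_len(nrow(spec$bilateral)), function(i) {
      as.list(spec$bilateral[i, ])
    }),
    bilateral_rho = spec$bilateral_rho,
    fill_rho = spec$fill_rho,
    marginal_shapes = as.list(spec$marginal_shapes),
    lognormal_sigma = as.list(spec$lognormal_sigma)
  )
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_cohort_spec
#' @export
read_cohort_spec <- function(path) {
  lst <- yaml::read_yaml(path)
  sig <- vapply(lst$lognormal_sigma, function(v) {
    if (is.null(v) || is.na(suppressWarnings(as.numeric(v)))) NA_real_
    else as.numeric(v)
  }, numeric(1))
  cohort_spec(
    group_sizes = unlist(lst$group_sizes),
    biomarkers = dplyr::bind_rows(lapply(lst$biomarkers, tibble::as_tibble)),
    targets = dplyr::bind_rows(lapply(lst$targets, tibble::as_tibble)),
    target_correlations = dplyr::bind_rows(
      lapply(lst$target_correlations, tibble::as_tibble)
    ),
    bilateral = dplyr::bind_rows(lapply(lst$bilateral, tibble::as_tibble)),
    bilateral_rho = lst$bilateral_rho,
    fill_rho = lst$fill_rho,
    marginal_shapes = unlist(lst$marginal_shapes),
    lognormal_sigma = sig
  )
}
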