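test_that("default spec matches the calibrated study structure", {
  spec <- default_cohort_spec()
  expect_equal(spec$group_sizes, c(male = 245L, female = 270L))
  expect_length(biomarker_names(), 44)
  expect_setequal(spec$biomarkers$name, biomarker_names())
  alm <- spec$targets[spec$targets$name == "ALM", ]
  expect_equal(alm$male_mean, 21.88)
  expect_equal(alm$male_sd, 7.95)
  expect_equal(alm$female_mean, 15.77)
  bfp <- spec$targets[spec$targets$name == "BFP", ]
  expect_equal(bfp$female_mean, 34.71)
  expect_equal(bfp$female_sd, 7.37)
  bmd <- spec$targets[spec$targets$name == "BMD", ]
  expect_equal(bmd$male_mean, 1.07)
  expect_equal(bmd$male_sd, 0.19)
})

test_that("assembled correlation matrices are valid and repairable", {
  spec <- default_cohort_spec()
  for (sx in c("male", "female")) {
    R <- spec_correlation_matrix(spec, sx)
    expect_true(isSymmetric(R, tol = 1e-12))
    expect_true(all(diag(R) == 1))
    expect_true(all(abs(R) <= 1 + 1e-12))
    ev <- min(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
    expect_gte(ev, -1e-8)
    # calibrated entries survive the PSD repair almost unchanged
    tc <- reference_correlations(dataset = sx)
    shift <- vapply(seq_len(nrow(tc)), function(i) {
      R[tc$biomarker[i], tc$target[i]] - tc$rho[i]
    }, numeric(1))
    expect_lt(max(abs(shift)), 0.03)
  }
})

test_that("generation is deterministic and has the right shape", {
  c1 <- generate_cohort(seed = 7)
  c2 <- generate_cohort(seed = 7)
  expect_identical(c1, c2)
  expect_equal(nrow(c1), 515)
  expect_equal(sum(c1$sex == "male"), 245)
  expect_equal(sum(c1$sex == "female"), 270)
  expect_true(all(biomarker_names() %in% names(c1)))
  expect_true(all(c1$BFP > 0 & c1$BFP < 100))
  c3 <- generate_cohort(seed = 8)
  expect_false(identical(c1[, "ALM"], c3[, "ALM"]))
})

test_that("moments are recovered at large n", {
  spec <- default_cohort_spec()
  spec$group_sizes <- c(male = 10000L, female = 10000L)
  st <- stratify_by_sex(generate_cohort(spec, seed = 11))
  for (sx in c("male", "female")) {
    d <- st[[sx]]
    mo <- dplyr::bind_rows(
      stats::setNames(
        spec$targets[, c("name", paste0(sx, "_mean"), paste0(sx, "_sd"))],
        c("name", "mean", "sd")
      ),
      stats::setNames(
        spec$biomarkers[, c("name", paste0(sx, "_mean"), paste0(sx, "_sd"))],
        c("name", "mean", "sd")
      )
    )
    for (i in seq_len(nrow(mo))) {
      v <- d[[mo$name[i]]]
      expect_lt(abs(mean(v) - mo$mean[i]) / mo$mean[i], 0.01,
                label = paste(sx, mo$name[i], "mean"))
      # the strongly right-skewed age marginal has excess kurtosis ~ 1e2,
      # so its sample SD fluctuates an order of magnitude more than the
      # near-normal variables at this n; give it a matching wider band
      sd_tol <- if (mo$name[i] == "age") 0.10 else 0.03
      expect_lt(abs(sd(v) - mo$sd[i]) / mo$sd[i], sd_tol,
                label = paste(sx, mo$name[i], "sd"))
    }
  }
})

test_that("calibrated feature-target correlations are recovered", {
  spec <- default_cohort_spec()
  spec$group_sizes <- c(male = 10000L, female = 10000L)
  st <- stratify_by_sex(generate_cohort(spec, seed = 42))
  for (sx in c("male", "female")) {
    d <- st[[sx]]
    tc <- reference_correlations(dataset = sx)
    errs <- vapply(seq_len(nrow(tc)), function(i) {
      cor(d[[tc$biomarker[i]]], d[[tc$target[i]]]) - tc$rho[i]
    }, numeric(1))
    expect_lt(max(abs(errs)), 0.05)
  }
})

test_that("right-skewed marginals are actually right-skewed", {
  spec <- default_cohort_spec()
  spec$group_sizes <- c(male = 5000L, female = 5000L)
  st <- stratify_by_sex(generate_cohort(spec, seed = 5))
  skew <- function(x) mean(((x - mean(x)) / sd(x))^3)
  expect_gt(skew(st$male$ALM), 0.2)
  expect_gt(skew(st$male$age), 1)
  expect_lt(median(st$male$age), mean(st$male$age))
})

test_that("combined target means are the size-weighted stratum means", {
  # with 245 males (ALM 21.88) and 270 females (15.77) the combined mean
  # is (245*21.88 + 270*15.77)/515 ~ 18.68; check on pooled generations
  spec <- default_cohort_spec()
  vals <- vapply(1:6, function(s) mean(generate_cohort(spec, s)$ALM),
                 numeric(1))
  pooled <- mean(vals)
  expected <- (245 * 21.88 + 270 * 15.77) / 515
  se <- 6.98 / sqrt(6 * 515)
  expect_lt(abs(pooled - expected), 4 * se)
})

test_that("missingness injection damages exactly the requested rows", {
  co <- generate_cohort(seed = 1)
  out <- inject_missingness(co, 100, seed = 2)
  incomplete <- !stats::complete.cases(out[, biomarker_names()])
  expect_equal(sum(incomplete), 100)
  untouched <- stats::complete.cases(out[, biomarker_names()])
  expect_identical(out[untouched, ], co[untouched, ])

  expect_identical(inject_missingness(co, 0, seed = 3), co)

  small <- co[1:5, ]
  all_hit <- inject_missingness(small, 5, seed = 4)
  expect_true(all(!stats::complete.cases(all_hit[, biomarker_names()])))

  expect_error(inject_missingness(small, 6, seed = 1), "between 0")
})

test_that("spec validation rejects inconsistent settings", {
  spec <- default_cohort_spec()
  bad <- spec
  bad$group_sizes <- c(male = 0L, female = 270L)
  expect_error(validate_cohort_spec(bad), "group sizes")
  bad <- spec
  bad$targets$male_sd[1] <- -1
  expect_error(validate_cohort_spec(bad), "SD")
  bad <- spec
  bad$target_correlations$rho[1] <- 1.2
  expect_error(validate_cohort_spec(bad), "rho|correlation")
})

test_that("cohort CSV and spec YAML round-trip", {
  co <- generate_cohort(seed = 2)[1:20, ]
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(co, path)
  back <- read_cohort_csv(path)
  expect_equal(as.data.frame(back), as.data.frame(co), tolerance = 1e-12)

  spec <- default_cohort_spec()
  ypath <- withr::local_tempfile(fileext = ".yaml")
  write_cohort_spec(spec, ypath)
  spec2 <- read_cohort_spec(ypath)
  expect_equal(spec2$group_sizes, spec$group_sizes)
  expect_equal(spec2$targets, spec$targets, tolerance = 1e-9)
  expect_identical(
    generate_cohort(spec2, seed = 3), generate_cohort(spec, seed = 3)
  )
})
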