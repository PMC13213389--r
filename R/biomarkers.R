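#' The 44 digital anthropometric biomarkers
#'
#' Canonical (snake_case) names of the 44 biomarkers extracted from a
#' segmented 3D body avatar: circumferences, lengths, surface areas and
#' volumes of body segments, plus height, weight and age. Column order of
#' every cohort produced by [generate_cohort()] follows this vector.
#'
#' @return Character vector of length 44.
#' @export
#' @examples
#' length(biomarker_names())
biomarker_names <- function() {
  c(
    "height", "weight", "abdomen_circumference",
    "ankle_circumference_left", "arm_length_left", "arm_volume_left",
    "bicep_circumference_left", "calf_circumference_left", "chest",
    "collar_circumference", "forearm_circumference_left",
    "head_circumference", "hip_circumference", "horizontal_waist",
    "inseam_left", "leg_volume_left", "midthigh_circumference_left",
    "narrow_waist", "outside_leg_length_left", "seat_circumference",
    "surface_area_arm_left", "surface_area_leg_left", "surface_area_torso",
    "surface_area_total", "thigh_circumference_left", "torso_volume",
    "upper_arm_circumference_left", "volume", "waist_circumference",
    "ankle_circumference_right", "arm_length_right", "arm_volume_right",
    "bicep_circumference_right", "calf_circumference_right",
    "forearm_circumference_right", "inseam_right", "leg_volume_right",
    "midthigh_circumference_right", "outside_leg_length_right",
    "surface_area_arm_right", "surface_area_leg_right",
    "thigh_circumference_right", "upper_arm_circumference_right", "age"
  )
}

#' Left/right biomarker pairs
#'
#' Bilateral measurements (left and right limb versions of the same
#' quantity). Human anatomy makes these pairs almost perfectly correlated,
#' which the cohort generator reproduces.
#'
#' @return Tibble with columns `left` and `right`.
#' @export
bilateral_pairs <- function() {
  base <- c(
    "ankle_circumference", "arm_length", "arm_volume",
    "bicep_circumference", "calf_circumference", "forearm_circumference",
    "inseam", "leg_volume", "midthigh_circumference", "outside_leg_length",
    "surface_area_arm", "surface_area_leg", "thigh_circumference",
    "upper_arm_circumference"
  )
  tibble::tibble(left = paste0(base, "_left"), right = paste0(base, "_right"))
}

#' Reference top-correlated biomarkers per target and cohort
#'
#' The ten biomarkers most correlated with each target variable (`ALM`,
#' `BFP`, `BMD`) in the reference cohort the generator is calibrated to,
#' with their Pearson correlation coefficients, for the male, female and
#' combined strata. These values calibrate the copula generator and drive
#' the fixed-list feature mode of the ten-feature graph variant.
#'
#' @param target One of `"ALM"`, `"BFP"`, `"BMD"`, or `NULL` for all.
#' @param dataset One of `"male"`, `"female"`, `"combined"`, or `NULL` for all.
#' @return Tibble with columns `target`, `dataset`, `biomarker`, `rho`,
#'   ordered by descending `rho` within each (target, dataset) block.
#' @export
#' @examples
#' reference_correlations("ALM", "male")
reference_correlations <- function(target = NULL, dataset = NULL) {
  tab <- reference_correlation_table()
  if (!is.null(target)) {
    target <- match.arg(target, c("ALM", "BFP", "BMD"))
    tab <- dplyr::filter(tab, .data$target == !!target)
  }
  if (!is.null(dataset)) {
    dataset <- match.arg(dataset, c("male", "female", "combined"))
    tab <- dplyr::filter(tab, .data$dataset == !!dataset)
  }
  tab
}

reference_correlation_table <- function() {
  rows <- list(
    list("ALM", "male", c(
      surface_area_total = 0.964, surface_area_leg_right = 0.956,
      surface_area_leg_left = 0.953, surface_area_arm_left = 0.947,
      leg_volume_left = 0.944, leg_volume_right = 0.943,
      surface_area_arm_right = 0.939, weight = 0.934, volume = 0.922,
      surface_area_torso = 0.916
    )),
    list("ALM", "female", c(
      surface_area_total = 0.907, leg_volume_left = 0.899,
      surface_area_leg_right = 0.898, surface_area_leg_left = 0.897,
      leg_volume_right = 0.894, weight = 0.891, volume = 0.868,
      calf_circumference_left = 0.865, thigh_circumference_left = 0.862,
      thigh_circumference_right = 0.861
    )),
    list("ALM", "combined", c(
      surface_area_total = 0.910, surface_area_arm_left = 0.904,
      surface_area_arm_right = 0.902, weight = 0.888,
      surface_area_torso = 0.875, forearm_circumference_right = 0.872,
      surface_area_leg_right = 0.869, volume = 0.865,
      surface_area_leg_left = 0.865, arm_volume_left = 0.861
    )),
    list("BFP", "male", c(
      horizontal_waist = 0.577, narrow_waist = 0.552,
      waist_circumference = 0.526, abdomen_circumference = 0.512,
      seat_circumference = 0.444, hip_circumference = 0.442,
      bicep_circumference_left = 0.438, torso_volume = 0.436,
      chest = 0.416, upper_arm_circumference_left = 0.409
    )),
    list("BFP", "female", c(
      horizontal_waist = 0.754, waist_circumference = 0.742,
      narrow_waist = 0.741, abdomen_circumference = 0.741,
      bicep_circumference_left = 0.720, chest = 0.697,
      upper_arm_circumference_right = 0.691,
      upper_arm_circumference_left = 0.690,
      bicep_circumference_right = 0.688, torso_volume = 0.665
    )),
    list("BFP", "combined", c(
      waist_circumference = 0.577, horizontal_waist = 0.566,
      abdomen_circumference = 0.559, seat_circumference = 0.510,
      hip_circumference = 0.505, thigh_circumference_left = 0.479,
      thigh_circumference_right = 0.475,
      midthigh_circumference_left = 0.459,
      midthigh_circumference_right = 0.448, narrow_waist = 0.442
    )),
    list("BMD", "male", c(
      surface_area_arm_right = 0.862, surface_area_arm_left = 0.861,
      surface_area_total = 0.851, arm_volume_right = 0.834, height = 0.834,
      forearm_circumference_right = 0.832, arm_volume_left = 0.831,
      surface_area_leg_left = 0.829, surface_area_leg_right = 0.821,
      surface_area_torso = 0.816
    )),
    list("BMD", "female", c(
      height = 0.733, surface_area_total = 0.711,
      surface_area_leg_left = 0.709, surface_area_leg_right = 0.696,
      outside_leg_length_left = 0.675, outside_leg_length_right = 0.662,
      arm_length_left = 0.659, surface_area_torso = 0.658,
      surface_area_arm_left = 0.654, hip_circumference = 0.652
    )),
    list("BMD", "combined", c(
      surface_area_total = 0.806, height = 0.804,
      surface_area_arm_left = 0.795, surface_area_arm_right = 0.794,
      surface_area_leg_left = 0.782, surface_area_leg_right = 0.773,
      surface_area_torso = 0.767, arm_volume_right = 0.765,
      arm_volume_left = 0.758, arm_length_left = 0.749
    ))
  )
  purrr::map_dfr(rows, function(r) {
    tibble::tibble(
      target = r[[1]], dataset = r[[2]],
      biomarker = names(r[[3]]), rho = unname(r[[3]])
    )
  })
}

# Default marginal moments for biomarkers without reference descriptive
# statistics. Plausible anthropometric values for a mixed child/adult cohort;
# SDs are wide to reflect the cohort's young median age and large adult tail.
default_biomarker_marginals <- function() {
  m <- function(name, mm, msd, fm, fsd) {
    tibble::tibble(
      name = name, male_mean = mm, male_sd = msd,
      female_mean = fm, female_sd = fsd
    )
  }
  dplyr::bind_rows(
    # reference descriptive statistics (height, weight, age)
    m("height", 164.33, 17.80, 156.68, 12.47),
    m("weight", 68.24, 25.88, 60.00, 18.22),
    m("age", 27.33, 19.59, 27.88, 20.25),
    # config defaults, units cm / cm^2 / cm^3
    m("abdomen_circumference", 85, 15, 82, 16),
    m("ankle_circumference_left", 22, 3, 21, 3),
    m("ankle_circumference_right", 22, 3, 21, 3),
    m("arm_length_left", 55, 7, 51, 6),
    m("arm_length_right", 55, 7, 51, 6),
    m("arm_volume_left", 2400, 800, 2000, 700),
    m("arm_volume_right", 2400, 800, 2000, 700),
    m("bicep_circumference_left", 29, 5, 27, 5),
    m("bicep_circumference_right", 29, 5, 27, 5),
    m("calf_circumference_left", 36, 5, 35, 5),
    m("calf_circumference_right", 36, 5, 35, 5),
    m("chest", 95, 14, 88, 13),
    m("collar_circumference", 38, 5, 33, 4),
    m("forearm_circumference_left", 26, 4, 23, 3),
    m("forearm_circumference_right", 26, 4, 23, 3),
    m("head_circumference", 56, 3, 55, 3),
    m("hip_circumference", 98, 13, 100, 15),
    m("horizontal_waist", 84, 16, 80, 16),
    m("inseam_left", 76, 9, 72, 8),
    m("inseam_right", 76, 9, 72, 8),
    m("leg_volume_left", 8500, 2800, 7800, 2600),
    m("leg_volume_right", 8500, 2800, 7800, 2600),
    m("midthigh_circumference_left", 50, 8, 49, 8),
    m("midthigh_circumference_right", 50, 8, 49, 8),
    m("narrow_waist", 82, 15, 75, 14),
    m("outside_leg_length_left", 98, 12, 94, 10),
    m("outside_leg_length_right", 98, 12, 94, 10),
    m("seat_circumference", 99, 13, 101, 15),
    m("surface_area_arm_left", 2100, 500, 1800, 450),
    m("surface_area_arm_right", 2100, 500, 1800, 450),
    m("surface_area_leg_left", 5300, 1300, 4900, 1200),
    m("surface_area_leg_right", 5300, 1300, 4900, 1200),
    m("surface_area_torso", 7200, 1800, 6400, 1600),
    m("surface_area_total", 18500, 4200, 16500, 3800),
    m("thigh_circumference_left", 55, 9, 56, 9),
    m("thigh_circumference_right", 55, 9, 56, 9),
    m("torso_volume", 33000, 12000, 29000, 11000),
    m("upper_arm_circumference_left", 30, 5, 28, 5),
    m("upper_arm_circumference_right", 30, 5, 28, 5),
    m("volume", 66000, 22000, 58000, 19000),
    m("waist_circumference", 83, 15, 78, 15)
  )
}
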