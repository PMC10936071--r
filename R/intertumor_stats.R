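# Cross-lesion statistics: 13 statistics per conventional measurement,
# 8 x 13 = 104 conventional inter-tumor heterogeneity metrics per patient.

#' Names of the thirteen cross-lesion statistics, in canonical order
#' @return Character vector of length 13.
#' @export
statistic_names <- function() {
  c("Mean", "Median", "Mode", "R", "Std_dev", "SM", "Variance", "Range",
    "CV", "CSS", "USS", "Kurtosis", "Skewness")
}

#' Cross-lesion statistics of one measurement
#'
#' Summarises one conventional measurement across a patient's lesions with 13
#' statistics: mean, median, mode, quartile deviation (R), standard deviation,
#' standard error of the mean (SM), variance, range, coefficient of variation
#' (CV), corrected sum of squares (CSS), uncorrected sum of squares (USS),
#' kurtosis and skewness.
#'
#' Conventions: variance/SD/SM use the n-1 divisor; skewness and excess
#' kurtosis use population central moments (defined 0 when the second moment
#' vanishes); mode rounds to 4 significant digits, takes the most frequent
#' value and breaks ties toward the smallest; R is the semi-interquartile
#' range with linear-interpolation quantiles; CV divides by |mean| and is 0
#' when the mean is 0.
#'
#' @param values Numeric vector, one entry per lesion; length >= 2.
#' @return Named list of the 13 statistics (names per [statistic_names()]).
#' @export
cross_lesion_stats <- function(values) {
  x <- as.numeric(values)
  n <- length(x)
  stop_if_not(n >= 2, "inter-tumor statistics need at least 2 lesions")
  stop_if_not(all(is.finite(x)), "values must be finite")
  m <- mean(x)
  dev <- x - m
  v <- sum(dev^2) / (n - 1)
  sdv <- sqrt(v)
  q <- stats::quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
  rounded <- signif(x, 4)
  tab <- table(rounded)
  modes <- as.numeric(names(tab)[tab == max(tab)])
  m2 <- sum(dev^2) / n
  m3 <- sum(dev^3) / n
  m4 <- sum(dev^4) / n
  list(
    Mean = m,
    Median = stats::median(x),
    Mode = min(modes),
    R = (q[2] - q[1]) / 2,
    Std_dev = sdv,
    SM = sdv / sqrt(n),
    Variance = v,
    Range = max(x) - min(x),
    CV = if (m == 0) 0 else sdv / abs(m),
    CSS = sum(dev^2),
    USS = sum(x^2),
    Kurtosis = if (m2 < 1e-300) 0 else m4 / m2^2 - 3,
    Skewness = if (m2 < 1e-300) 0 else m3 / m2^1.5
  )
}

#' Names of the 104 conventional heterogeneity metrics, in canonical order
#'
#' Measurements in the order of [measurement_names()], statistics in the
#' order of [statistic_names()]; names are `<Measurement>_<Statistic>`.
#' @return Character vector of length 104.
#' @export
conventional_metric_names <- function() {
  as.vector(t(outer(measurement_names(), statistic_names(), paste, sep = "_")))
}

#' Conventional inter-tumor heterogeneity block for one patient
#'
#' Applies [cross_lesion_stats()] to each of the 8 measurement columns of a
#' per-lesion measurement table, yielding the 104 named conventional metrics.
#'
#' @param measurements data.frame from [measure_patient()] (or any table with
#'   the 8 measurement columns), >= 2 rows.
#' @return Named numeric vector of length 104, ordered per
#'   [conventional_metric_names()].
#' @export
conventional_heterogeneity <- function(measurements) {
  stop_if_not(nrow(measurements) >= 2,
              "inter-tumor metrics need at least 2 lesions")
  out <- unlist(lapply(measurement_names(), function(mn) {
    stop_if_not(mn %in% names(measurements),
                paste0("missing measurement column: ", mn))
    s <- cross_lesion_stats(measurements[[mn]])
    stats::setNames(unlist(s), paste0(mn, "_", names(s)))
  }))
  out[conventional_metric_names()]
}

#' Full 107-metric heterogeneity vector for one patient
#'
#' The 104 conventional metrics plus the 3 CT-texture metrics (cSE, cluDev,
#' cluDiss).
#'
#' @param patient An `ith_patient`.
#' @param k Number of voxel subregions per lesion for the texture clustering.
#' @param seed Integer seed (texture subregion clustering).
#' @return Named numeric vector of length 107.
#' @export
heterogeneity_vector <- function(patient, k = 3, seed = 1) {
  meas <- measure_patient(patient)
  conv <- conventional_heterogeneity(meas)
  tex <- texture_heterogeneity(patient, k = k, seed = seed)
  c(conv, tex)
}

#' Heterogeneity metric table for a cohort
#'
#' @param cohort An `ith_cohort` (or plain list of `ith_patient`).
#' @param k,seed Passed to [heterogeneity_vector()].
#' @return data.frame, one row per patient: `patient_id` + 107 metric columns.
#' @export
heterogeneity_table <- function(cohort, k = 3, seed = 1) {
  patients <- if (inherits(cohort, "ith_cohort")) cohort$patients else cohort
  rows <- t(vapply(patients, heterogeneity_vector, numeric(107),
                   k = k, seed = seed))
  data.frame(patient_id = vapply(patients, `[[`, character(1), "patient_id"),
             rows, check.names = FALSE)
}
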