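# Synthetic phantom cohort: multi-lesion PET/CT patients with known ground
# truth, used to validate every downstream stage of the heterogeneity
# pipeline. Lesions are ellipsoids carrying Gaussian-correlated noise texture;
# covariates follow the category frequencies of an advanced serous ovarian
# cancer cohort; survival arises from an exponential-baseline Cox model on a
# planted linear predictor.

#' Anatomical region codes
#'
#' The nine abdominopelvic zones used to place metastatic implants, plus the
#' code reserved for the primary lesion.
#' @return Character vector of the 9 implant region codes.
#' @export
ar_regions <- function() paste0("AR-", 0:8)

#' Construct a voxel grid
#'
#' @param values 3-D numeric array (HU for CT, SUV for PET).
#' @param spacing Numeric length-3, voxel spacing in mm; all entries > 0.
#' @return A `voxel_grid` object.
#' @export
voxel_grid <- function(values, spacing) {
  stop_if_not(is.array(values) && length(dim(values)) == 3 && length(values) > 0,
              "values must be a non-empty 3-D array")
  spacing <- as.numeric(spacing)
  stop_if_not(length(spacing) == 3 && all(spacing > 0),
              "spacing must be three positive numbers (mm)")
  structure(list(values = values, spacing = spacing), class = "voxel_grid")
}

#' Construct a lesion volume of interest
#'
#' Bundles co-registered CT (HU) and PET (SUV) sub-volumes with a binary mask
#' and an anatomical region code.
#'
#' @param lesion_id Character identifier.
#' @param region One of `"primary"` or the codes in [ar_regions()].
#' @param ct,suv `voxel_grid` objects with identical shape and spacing.
#' @param mask 3-D logical/0-1 array, same shape, at least one voxel set.
#' @return A `lesion_voi` object.
#' @export
lesion_voi <- function(lesion_id, region, ct, suv, mask) {
  stop_if_not(region %in% c("primary", ar_regions()),
              "region must be 'primary' or one of AR-0..AR-8")
  stop_if_not(identical(dim(ct$values), dim(suv$values)) &&
              identical(dim(ct$values), dim(mask)),
              "ct, suv and mask must share one shape")
  stop_if_not(all(abs(ct$spacing - suv$spacing) < 1e-9),
              "ct and suv spacing differ")
  mask <- array(mask != 0, dim = dim(mask))
  stop_if_not(sum(mask) >= 1, "mask must contain at least one voxel")
  structure(list(lesion_id = lesion_id, region = region,
                 ct = ct, suv = suv, mask = mask),
            class = "lesion_voi")
}

#' Simulation configuration
#'
#' Defaults mirror the cohort the package emulates: 208 training and 84 test
#' patients, 1-9 metastatic implants per patient (median about 6), lesion
#' diameters 12-30 mm on a (1, 1, 3.8) mm grid, exponential-baseline survival
#' with median progression near 645 days and median survival near 1022 days,
#' and an H-score/risk-score Spearman target of 0.85.
#'
#' @param n_train,n_test Cohort sizes.
#' @param lesions_per_patient Integer range (min, max) of metastatic implants.
#' @param lesion_diameter Numeric range (min, max) lesion diameter in mm.
#' @param spacing Voxel spacing in mm.
#' @param hu_mean,hu_noise_sd Cohort-level mean lesion attenuation (HU) and
#'   within-lesion noise SD.
#' @param suv_mean Cohort geometric-mean lesion SUV.
#' @param texture_corr_mm Spatial correlation scale of within-lesion texture.
#' @param lesion_dispersion Multiplier on between-lesion dispersion of
#'   intensity/texture parameters (1 = calibrated default; 0 = clone lesions).
#' @param heterogeneity_effect Named numeric: planted log-hazard coefficients
#'   on ground-truth conventional heterogeneity metrics (names follow the
#'   `<Measurement>_<Statistic>` metric naming).
#' @param dispersion_effect Log-hazard coefficient on the patient's latent
#'   (standardised log) between-lesion dispersion, which drives the texture
#'   heterogeneity metrics.
#' @param clinical_effect Named numeric: log-hazard coefficients on the
#'   standardised FIGO stage (`figo`), the R2 resection flag (`sur_r2`) and
#'   standardised log CA125 (`log_ca125`).
#' @param baseline_rate_pfs,baseline_rate_os Exponential baseline hazards
#'   (events/day).
#' @param censor_admin Administrative censoring horizon in days.
#' @param dropout_max Upper bound of the uniform dropout-censoring draw (days).
#' @param rho_target Target Spearman correlation between simulated H-scores
#'   and the true risk score.
#' @param stain_prob Fraction of patients with immunohistochemistry data.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_train = 208, n_test = 84,
                       lesions_per_patient = c(1, 9),
                       lesion_diameter = c(12, 30),
                       spacing = c(1, 1, 3.8),
                       hu_mean = 45, hu_noise_sd = 10,
                       suv_mean = 6,
                       texture_corr_mm = 2.5,
                       lesion_dispersion = 1,
                       heterogeneity_effect = c(SUVmean_CV = 0.8,
                                                HU_SM = 0.5,
                                                TLG_USS = 0.5),
                       dispersion_effect = 0.7,
                       clinical_effect = c(figo = 0.25, sur_r2 = 0.3,
                                           log_ca125 = 0.2),
                       baseline_rate_pfs = log(2) / 645,
                       baseline_rate_os = log(2) / 1022,
                       censor_admin = 2500,
                       dropout_max = 3300,
                       rho_target = 0.85,
                       stain_prob = 0.30) {
  stop_if_not(n_train >= 1 && n_test >= 0, "cohort sizes must be >= 1")
  stop_if_not(baseline_rate_pfs > 0 && baseline_rate_os > 0,
              "baseline rates must be > 0")
  stop_if_not(rho_target >= -1 && rho_target <= 1, "rho_target must be in [-1, 1]")
  stop_if_not(lesions_per_patient[1] >= 1 && lesions_per_patient[2] <= 9,
              "implant count range must lie in [1, 9]")
  structure(as.list(environment()), class = "sim_config")
}

#' Generate one ellipsoidal lesion phantom
#'
#' Fills an ellipsoidal mask of the requested diameter with spatially
#' correlated Gaussian noise around the requested mean HU and SUV. With zero
#' noise SD every masked voxel equals the mean exactly; the same seed
#' reproduces the volumes bit for bit.
#'
#' @param region Region code (see [lesion_voi()]).
#' @param diameter_mm Lesion diameter (mm), > 0.
#' @param intensity List with `hu_mean`, `suv_mean`, `hu_sd`, `suv_sd`, and
#'   optionally `core_frac` / `core_offset_hu`: a concentric core of that
#'   relative radius whose CT attenuation is shifted by the offset, emulating
#'   the hypo-/hyperdense cores of partly necrotic or fibrotic implants.
#' @param texture List with `corr_mm`, the Gaussian correlation scale (mm).
#' @param spacing Voxel spacing (mm).
#' @param seed Integer seed.
#' @param lesion_id Identifier stored on the result.
#' @return A `lesion_voi`.
#' @export
generate_lesion_phantom <- function(region, diameter_mm,
                                    intensity = list(hu_mean = 45, suv_mean = 6,
                                                     hu_sd = 10, suv_sd = 1.5),
                                    texture = list(corr_mm = 2.5),
                                    spacing = c(1, 1, 3.8),
                                    seed = 1, lesion_id = "lesion") {
  stop_if_not(diameter_mm > 0, "diameter_mm must be > 0")
  spacing <- as.numeric(spacing)
  r <- diameter_mm / 2
  margin <- 2L
  half <- ceiling(r / spacing) + margin
  dims <- 2L * half + 1L
  ctr <- half + 1L
  ax <- lapply(1:3, function(a) ((seq_len(dims[a]) - ctr[a]) * spacing[a]) / r)
  dist2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, `+`), ax[[3]]^2, `+`)
  mask <- array(dist2 <= 1, dim = dims)
  corr_vox <- pmax(texture$corr_mm / spacing, 1e-8)

  # centred and scaled over the masked voxels so the lesion's noise mean/SD
  # match the request exactly regardless of smoothing edge effects
  field <- function(sd_target) {
    if (sd_target <= 0) return(array(0, dim = dims))
    raw <- array(stats::rnorm(prod(dims)), dim = dims)
    sm <- gaussian_smooth3d(raw, corr_vox)
    mu <- mean(sm[mask]); s <- stats::sd(sm[mask])
    if (!is.finite(s) || s < 1e-12) return(array(0, dim = dims))
    (sm - mu) / s * sd_target
  }
  core_frac <- if (is.null(intensity$core_frac)) 0 else intensity$core_frac
  core_off <- if (is.null(intensity$core_offset_hu)) 0 else intensity$core_offset_hu
  with_seed(seed, {
    ct_vals <- intensity$hu_mean + field(intensity$hu_sd)
    if (core_frac > 0 && core_off != 0) {
      ct_vals <- ct_vals + core_off * (dist2 <= core_frac^2)
    }
    suv_vals <- pmax(intensity$suv_mean + field(intensity$suv_sd), 0)
  })
  lesion_voi(lesion_id, region,
             voxel_grid(ct_vals, spacing),
             voxel_grid(suv_vals, spacing),
             mask)
}

# Category frequencies used for covariate draws (training-set marginals of
# the emulated cohort).
covariate_tables <- function() {
  list(
    figo = c(IIB = 0.0144, IIIA = 0.0288, IIIB = 0.0962, IIIC = 0.5721,
             IVA = 0.1587, IVB = 0.1298),
    sur_status = c(R0 = 0.5721, R1 = 0.2019, R2 = 0.2260),
    ascites_character = c(none = 0.0433, bloody = 0.3029, `non-bloody` = 0.6538),
    lnm = c(pelvic = 0.3558, middle_abdominal = 0.3029,
            upper_abdominal = 0.2933, distant = 0.1250),
    invasion = c(`0` = 0.1106, `1` = 0.2019, `2` = 0.2452, `3` = 0.2500,
                 `4` = 0.1923),
    region_freq = c(`AR-0` = 0.4567, `AR-1` = 0.6779, `AR-2` = 0.4183,
                    `AR-3` = 0.6202, `AR-4` = 0.4231, `AR-5` = 0.6827,
                    `AR-6` = 0.8317, `AR-7` = 0.6298, `AR-8` = 0.7067),
    n_implants_prob = stats::dbinom(0:8, 8, 0.68)
  )
}

draw_covariates <- function(k_implants, implant_regions) {
  tb <- covariate_tables()
  draw <- function(p) names(p)[sample.int(length(p), 1, prob = p)]
  loc <- as.integer(ar_regions() %in% implant_regions)
  names(loc) <- ar_regions()
  ac <- draw(tb$ascites_character)
  list(
    age = round(min(max(stats::rnorm(1, 54, 9.4), 25), 88), 1),
    ca125 = round(stats::rlnorm(1, log(867), 0.9), 1),
    figo_stage = draw(tb$figo),
    sur_status = draw(tb$sur_status),
    ascites_character = ac,
    ascites_volume = if (ac == "none") 0 else round(stats::rlnorm(1, log(1500), 1.7)),
    lnm = stats::rbinom(4, 1, tb$lnm) == 1,
    n_implants = k_implants,
    implant_locations = loc,
    invasion_pattern = as.integer(draw(tb$invasion)),
    solid_ratio = stats::rbeta(1, 6, 2.5)
  )
}

#' Generate one phantom patient
#'
#' Draws an implant count, places one primary plus that many implants in
#' distinct regions, generates each lesion's image phantom, and draws clinical
#' covariates from the documented category frequencies. Survival outcomes and
#' H-scores are attached at cohort level by [simulate_cohort()] because the
#' planted linear predictor is standardised across the cohort.
#'
#' @param config A [sim_config()].
#' @param patient_index Integer, used for the id and the RNG substream.
#' @param seed Master seed.
#' @return An `ith_patient` with lesions, covariates and ground-truth
#'   per-lesion parameters (`$truth`).
#' @export
generate_patient <- function(config, patient_index, seed = 1) {
  tb <- covariate_tables()
  ps <- substream_seed(seed, 101, patient_index)
  with_seed(ps, {
    kr <- config$lesions_per_patient
    kk <- seq.int(kr[1], kr[2])
    k <- kk[sample.int(length(kk), 1,
                       prob = tb$n_implants_prob[kk])]
    regions <- sample(ar_regions(), k, prob = tb$region_freq)
    cov <- draw_covariates(k, regions)
    disp <- exp(stats::rnorm(1, 0, 0.5)) * config$lesion_dispersion
    pat_hu <- stats::rnorm(1, config$hu_mean, 6)
    pat_suv <- config$suv_mean * exp(stats::rnorm(1, 0, 0.4))
    n_les <- k + 1L
    les_par <- data.frame(
      region = c("primary", regions),
      diameter = stats::runif(n_les, config$lesion_diameter[1],
                              config$lesion_diameter[2]),
      hu_mean = pat_hu + stats::rnorm(n_les, 0, 8 * disp),
      suv_mean = pat_suv * exp(stats::rnorm(n_les, 0, 0.30 * disp)),
      hu_sd = config$hu_noise_sd * exp(stats::rnorm(n_les, 0, 0.20 * disp)),
      suv_sd = 1.5 * exp(stats::rnorm(n_les, 0, 0.20 * disp)),
      corr_mm = config$texture_corr_mm * exp(stats::rnorm(n_les, 0, 0.25 * disp)),
      core_frac = stats::runif(n_les, 0.3, 0.6),
      core_offset = stats::rnorm(n_les, 0, 12 * disp)
    )
    # primary is the largest lesion more often than not
    les_par$diameter[1] <- max(les_par$diameter[1],
                               stats::runif(1, mean(config$lesion_diameter),
                                            config$lesion_diameter[2]))
  })
  pid <- sprintf("P%04d", patient_index)
  lesions <- vector("list", nrow(les_par))
  for (i in seq_len(nrow(les_par))) {
    lesions[[i]] <- generate_lesion_phantom(
      region = les_par$region[i],
      diameter_mm = les_par$diameter[i],
      intensity = list(hu_mean = les_par$hu_mean[i], suv_mean = les_par$suv_mean[i],
                       hu_sd = les_par$hu_sd[i], suv_sd = les_par$suv_sd[i],
                       core_frac = les_par$core_frac[i],
                       core_offset_hu = les_par$core_offset[i]),
      texture = list(corr_mm = les_par$corr_mm[i]),
      spacing = config$spacing,
      seed = substream_seed(seed, 211, patient_index, i),
      lesion_id = sprintf("%s_L%d", pid, i))
  }
  les_par$pixel_number <- vapply(lesions, function(l) sum(l$mask), numeric(1))
  structure(list(patient_id = pid, lesions = lesions, covariates = cov,
                 pfs = NULL, os = NULL, stain_fractions = NULL,
                 truth = list(lesion_params = les_par, dispersion = disp)),
            class = "ith_patient")
}

# Ground-truth conventional heterogeneity vector from the noiseless lesion
# parameters (no image involved) -- the basis of the planted linear predictor.
true_conventional_vector <- function(patient, spacing) {
  p <- patient$truth$lesion_params
  vol_ml <- p$pixel_number * prod(spacing) / 1000
  meas <- data.frame(
    Pixel_number = p$pixel_number,
    Maj = p$diameter, Min = p$diameter,
    HU = p$hu_mean + p$core_offset * p$core_frac^3,
    SUVmax = p$suv_mean + 2.5 * p$suv_sd,
    SUVmean = p$suv_mean,
    SUVpeak = p$suv_mean + p$suv_sd,
    TLG = p$suv_mean * vol_ml)
  unlist(lapply(names(meas), function(m) {
    s <- cross_lesion_stats(meas[[m]])
    stats::setNames(unlist(s), paste0(m, "_", names(s)))
  }))
}

#' Simulate exponential-baseline survival
#'
#' Event times are exponential with rate `baseline_rate * exp(lp)`; censoring
#' is the minimum of a uniform dropout draw on `[0, dropout_max]` and the
#' administrative horizon.
#'
#' @param linear_predictor Numeric vector of log relative hazards.
#' @param baseline_rate Baseline hazard (events/day), > 0.
#' @param censor_admin Administrative censoring time (days).
#' @param dropout_max Upper bound of uniform dropout (days).
#' @param seed Integer seed.
#' @return data.frame with `time` (days) and `event` (0/1).
#' @export
simulate_survival <- function(linear_predictor, baseline_rate,
                              censor_admin, dropout_max = 3 * censor_admin,
                              seed = 1) {
  stop_if_not(baseline_rate > 0, "baseline_rate must be > 0")
  n <- length(linear_predictor)
  with_seed(seed, {
    t_event <- stats::rexp(n, rate = baseline_rate * exp(linear_predictor))
    t_cens <- pmin(stats::runif(n, 0, max(dropout_max, 0)), censor_admin)
  })
  data.frame(time = pmin(t_event, t_cens),
             event = as.integer(t_event <= t_cens))
}

#' Simulate immunohistochemistry stain fractions tied to a risk score
#'
#' Gaussian-copula construction: the risk ranks are mapped to normal scores,
#' a correlated normal is drawn with Pearson correlation `2*sin(pi*rho/6)`
#' (so the Spearman correlation converges to `rho_target`), mapped through
#' the normal CDF to an H-score in \[0, 300\], and decomposed into
#' weak/moderate/strong percentages with weak + moderate + strong <= 100.
#'
#' @param risk_scores Numeric vector.
#' @param rho_target Target Spearman correlation in \[-1, 1\].
#' @param seed Integer seed.
#' @return data.frame with `weak_pct`, `moderate_pct`, `strong_pct`.
#' @export
simulate_h_scores <- function(risk_scores, rho_target, seed = 1) {
  stop_if_not(rho_target >= -1 && rho_target <= 1, "rho_target must be in [-1, 1]")
  n <- length(risk_scores)
  r_p <- 2 * sin(pi * rho_target / 6)
  z_risk <- stats::qnorm((rank(risk_scores, ties.method = "average") - 0.5) / n)
  z_h <- with_seed(seed, {
    if (abs(r_p) >= 1) sign(r_p) * z_risk
    else r_p * z_risk + sqrt(1 - r_p^2) * stats::rnorm(n)
  })
  h <- 300 * stats::pnorm(z_h)
  decompose_h_score(h)
}

# Deterministic monotone decomposition of an H-score into a stain triple.
decompose_h_score <- function(h) {
  weak <- ifelse(h <= 100, h, ifelse(h <= 200, 200 - h, 0))
  moderate <- ifelse(h <= 100, 0, ifelse(h <= 200, h - 100, 300 - h))
  strong <- ifelse(h <= 200, 0, h - 200)
  data.frame(weak_pct = weak, moderate_pct = moderate, strong_pct = strong)
}

#' Simulate a phantom cohort
#'
#' Generates `n_train + n_test` patients, computes each patient's ground-truth
#' conventional heterogeneity vector, standardises those metrics across the
#' cohort, builds the planted linear predictor (clinical effects +
#' heterogeneity-metric effects + latent-dispersion effect), draws PFS and OS
#' outcomes, and attaches copula-simulated p53/Ki-67 stain fractions to a
#' random subset of patients.
#'
#' @param config A [sim_config()].
#' @param seed Master seed; every substream derives from it.
#' @return An `ith_cohort`: list with `patients`, `split` ("train"/"test"),
#'   `truth` (linear predictors, dispersion, true metric matrix) and `config`.
#' @export
simulate_cohort <- function(config = sim_config(), seed = 1) {
  n <- config$n_train + config$n_test
  patients <- lapply(seq_len(n), function(i) generate_patient(config, i, seed))
  tm <- t(vapply(patients, true_conventional_vector, numeric(104),
                 spacing = config$spacing))
  rownames(tm) <- vapply(patients, `[[`, character(1), "patient_id")

  zscale <- function(x) {
    s <- stats::sd(x)
    if (!is.finite(s) || s < 1e-12) rep(0, length(x)) else (x - mean(x)) / s
  }
  lp <- rep(0, n)
  he <- config$heterogeneity_effect
  for (nm in names(he)) {
    stop_if_not(nm %in% colnames(tm),
                paste0("unknown metric in heterogeneity_effect: ", nm))
    lp <- lp + he[[nm]] * zscale(tm[, nm])
  }
  disp <- vapply(patients, function(p) p$truth$dispersion, numeric(1))
  lp <- lp + config$dispersion_effect * zscale(log(disp))
  ce <- config$clinical_effect
  figo_ord <- match(vapply(patients, function(p) p$covariates$figo_stage,
                           character(1)),
                    c("IIB", "IIIA", "IIIB", "IIIC", "IVA", "IVB"))
  sur_r2 <- as.numeric(vapply(patients, function(p) p$covariates$sur_status,
                              character(1)) == "R2")
  lca <- log(vapply(patients, function(p) p$covariates$ca125, numeric(1)))
  lp <- lp + ce[["figo"]] * zscale(figo_ord) + ce[["sur_r2"]] * sur_r2 +
    ce[["log_ca125"]] * zscale(lca)

  pfs <- simulate_survival(lp, config$baseline_rate_pfs, config$censor_admin,
                           config$dropout_max, seed = substream_seed(seed, 301))
  os <- simulate_survival(lp, config$baseline_rate_os, config$censor_admin,
                          config$dropout_max, seed = substream_seed(seed, 302))
  os$time <- pmax(os$time, pfs$time)  # death cannot precede progression follow-up
  p53 <- simulate_h_scores(lp, config$rho_target, seed = substream_seed(seed, 303))
  ki67 <- simulate_h_scores(lp, config$rho_target, seed = substream_seed(seed, 304))
  stained <- with_seed(substream_seed(seed, 305),
                       stats::runif(n) < config$stain_prob)
  for (i in seq_len(n)) {
    patients[[i]]$pfs <- pfs[i, ]
    patients[[i]]$os <- os[i, ]
    if (stained[i]) {
      patients[[i]]$stain_fractions <- list(p53 = p53[i, ], ki67 = ki67[i, ])
    }
  }
  structure(list(
    patients = patients,
    split = rep(c("train", "test"), c(config$n_train, config$n_test)),
    truth = list(lp = lp, dispersion = disp, true_metrics = tm),
    config = config), class = "ith_cohort")
}

#' @export
print.ith_cohort <- function(x, ...) {
  nl <- vapply(x$patients, function(p) length(p$lesions), numeric(1))
  cat(sprintf("Synthetic multi-lesion cohort: %d patients (%d train / %d test)\n",
              length(x$patients), sum(x$split == "train"), sum(x$split == "test")))
  cat(sprintf("Lesions per patient: median %g (range %d-%d)\n",
              stats::median(nl), min(nl), max(nl)))
  invisible(x)
}

#' Perturb a segmentation mask
#'
#' Emulates a repeat delineation: a smooth random field decides, per boundary
#' voxel, whether the contour is locally pushed outward (dilation) or pulled
#' inward (erosion), one voxel layer per step up to the requested physical
#' magnitude. Only axes whose spacing does not exceed the magnitude are moved.
#' Magnitude 0 returns the input unchanged; the result is never empty.
#'
#' @param mask 3-D binary array.
#' @param magnitude_mm Maximum boundary displacement (mm), >= 0.
#' @param spacing Voxel spacing (mm).
#' @param seed Integer seed.
#' @return Perturbed binary mask, same shape.
#' @export
perturb_segmentation <- function(mask, magnitude_mm, spacing = c(1, 1, 3.8),
                                 seed = 1) {
  stop_if_not(magnitude_mm >= 0, "magnitude_mm must be >= 0")
  mask <- array(mask != 0, dim = dim(mask))
  if (magnitude_mm == 0) return(mask)
  axes <- which(spacing <= magnitude_mm + 1e-9)
  if (length(axes) == 0) return(mask)
  steps <- max(floor(magnitude_mm / spacing[axes]))
  offs <- do.call(rbind, lapply(axes, function(a) {
    o <- matrix(0L, 2, 3); o[1, a] <- 1L; o[2, a] <- -1L; o
  }))
  with_seed(seed, {
    field <- gaussian_smooth3d(array(stats::rnorm(length(mask)), dim = dim(mask)),
                               c(2, 2, 2) / (spacing / min(spacing)))
    for (s in seq_len(steps)) {
      m_num <- array(as.numeric(mask), dim = dim(mask))
      nb <- neighbourhood_sum(m_num, offs)
      add <- !mask & nb > 0 & field > 0
      drop_ <- mask & nb < nrow(offs) & field < 0
      new_mask <- (mask | add) & !drop_
      if (sum(new_mask) == 0) {
        warning("perturbation would empty the mask; magnitude reduced")
        break
      }
      mask <- new_mask
    }
  })
  mask
}

#' Apply segmentation perturbation to every lesion of a cohort
#'
#' Returns a copy of the cohort in which each lesion's mask has been passed
#' through [perturb_segmentation()] (images untouched), emulating a repeat
#' delineation session for test-retest reproducibility screens.
#'
#' @param cohort An `ith_cohort`.
#' @param magnitude_mm Boundary displacement magnitude (mm).
#' @param seed Master seed; one substream per lesion.
#' @return The perturbed `ith_cohort`.
#' @export
perturb_cohort <- function(cohort, magnitude_mm = 1, seed = 1) {
  for (i in seq_along(cohort$patients)) {
    for (j in seq_along(cohort$patients[[i]]$lesions)) {
      l <- cohort$patients[[i]]$lesions[[j]]
      l$mask <- perturb_segmentation(l$mask, magnitude_mm,
                                     spacing = l$ct$spacing,
                                     seed = substream_seed(seed, 601, i, j))
      cohort$patients[[i]]$lesions[[j]] <- l
    }
  }
  cohort
}

#' Dice overlap of two masks
#' @param a,b Binary arrays of one shape.
#' @return Dice coefficient in \[0, 1\].
#' @export
dice_coefficient <- function(a, b) {
  a <- a != 0; b <- b != 0
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}
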