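#' Configuration of the synthetic phantom cohort
#'
#' Defaults emulate the cohort structure the analysis assumes: a liver
#' reference of SUV 2.0 +/- 0.3 (implying a PERCIST threshold of 3.6), a low
#' background, 1-3 FDG-avid lesions per patient whose intensity median and
#' skewness are the patient-level latent traits, a logistic link from those
#' traits to non-response with a ~25% base rate, Weibull
#' proportional-hazards progression-free survival, and TPS group
#' frequencies 21:13:10.
#'
#' @param n_patients cohort size.
#' @param lesions_per_patient integer range `c(min, max)`.
#' @param grid_shape voxels per axis.
#' @param spacing_mm voxel size in mm per axis.
#' @param liver_mean_suv,liver_sd_suv liver reference SUV distribution.
#' @param background_suv soft-tissue background SUV.
#' @param lesion_median_range SUV interval the per-patient median target is
#'   drawn from (must sit above the implied PERCIST threshold).
#' @param lesion_skew_range interval for the per-patient skewness target.
#' @param beta0,beta_skew,beta_median logistic coefficients for
#'   P(non-response) on the raw trait scale.
#' @param weibull_shape,base_scale Weibull baseline for PFS (months).
#' @param gamma_skew,gamma_median log-hazard coefficients (higher skewness
#'   raises, higher median lowers, the progression hazard by default).
#' @param censor_horizon_months administrative censoring time.
#' @param reader2_perturb_iters morphological dilate/erode iterations used
#'   to derive the second reader's mask.
#' @param tps_probs probabilities of TPS >= 50%, 1-49%, < 1%.
#' @param seed integer master seed; patient k uses substream `seed + k`.
#' @return a validated `SyntheticConfig` list.
#' @export
syntheticConfig <- function(n_patients = 44L,
                            lesions_per_patient = c(1L, 3L),
                            grid_shape = c(64L, 64L, 48L),
                            spacing_mm = c(4, 4, 4),
                            liver_mean_suv = 2.0,
                            liver_sd_suv = 0.3,
                            background_suv = 0.5,
                            lesion_median_range = c(5.5, 12),
                            lesion_skew_range = c(0.3, 2.2),
                            beta0 = -5.4,
                            beta_skew = 3.0,
                            beta_median = 0,
                            weibull_shape = 1.3,
                            base_scale = 1.8,
                            gamma_skew = 0.6,
                            gamma_median = -0.35,
                            censor_horizon_months = 30,
                            reader2_perturb_iters = 1L,
                            tps_probs = c(21, 13, 10) / 44,
                            seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients),
              lesions_per_patient = as.integer(lesions_per_patient),
              grid_shape = as.integer(grid_shape),
              spacing_mm = as.numeric(spacing_mm),
              liver_mean_suv = liver_mean_suv, liver_sd_suv = liver_sd_suv,
              background_suv = background_suv,
              lesion_median_range = lesion_median_range,
              lesion_skew_range = lesion_skew_range,
              beta0 = beta0, beta_skew = beta_skew, beta_median = beta_median,
              weibull_shape = weibull_shape, base_scale = base_scale,
              gamma_skew = gamma_skew, gamma_median = gamma_median,
              censor_horizon_months = censor_horizon_months,
              reader2_perturb_iters = as.integer(reader2_perturb_iters),
              tps_probs = tps_probs, seed = as.integer(seed))
  validateSyntheticConfig(cfg)
  class(cfg) <- "SyntheticConfig"
  cfg
}

validateSyntheticConfig <- function(cfg) {
  if (cfg$n_patients < 4L)
    petradStop("petrad_unsupported_parameter", "n_patients must be >= 4")
  if (abs(sum(cfg$tps_probs) - 1) > 1e-8 || any(cfg$tps_probs < 0))
    petradStop("petrad_unsupported_parameter", "tps_probs must sum to 1")
  if (any(c(cfg$liver_mean_suv, cfg$liver_sd_suv, cfg$background_suv) < 0) ||
      cfg$liver_mean_suv <= 0)
    petradStop("petrad_unsupported_parameter", "SUV parameters must be positive")
  thr <- 1.5 * cfg$liver_mean_suv + 2 * cfg$liver_sd_suv
  if (cfg$lesion_median_range[1] <= thr)
    petradStop("petrad_unsupported_parameter", sprintf(
      "lesion_median_range must lie above the implied PERCIST threshold %.2f",
      thr))
  invisible(TRUE)
}

#' Sample lesion voxel intensities with a target median and skewness
#'
#' Draws from a shifted-gamma family in which the skewness fixes the gamma
#' shape (`k = (2/skew)^2`, closed-form skewness `2/sqrt(k)`) and the shift
#' then fixes the median exactly in distribution. Negative skewness targets
#' use the mirrored gamma; targets within 0.01 of zero use the normal
#' limit. An optional `floor` clamps the support from below (used by the
#' phantom generator to keep lesions above the PERCIST threshold).
#'
#' @param median_target target median (SUV).
#' @param skew_target target skewness (dimensionless).
#' @param n number of draws (>= 10).
#' @param spread approximate standard deviation of the draws (SUV).
#' @param floor optional lower clamp (SUV).
#' @return numeric vector of length `n`.
#' @export
sampleLesionIntensities <- function(median_target, skew_target, n,
                                    spread = 1.0, floor = NULL) {
  if (n < 10L)
    petradStop("petrad_unsupported_parameter", "need n >= 10 draws")
  if (!is.finite(skew_target) || !is.finite(median_target))
    petradStop("petrad_unsupported_parameter",
               "median and skewness targets must be finite")
  s <- abs(skew_target)
  if (s < 0.01) {
    x <- stats::rnorm(n, mean = median_target, sd = spread)
  } else {
    k <- (2 / s)^2
    theta <- spread / sqrt(k)
    if (!is.null(floor) && skew_target > 0) {
      # cap the scale so the support minimum stays above the floor
      margin <- median_target - floor
      if (margin <= 0)
        petradStop("petrad_unsupported_parameter",
                   "median target at or below the floor")
      qmed <- stats::qgamma(0.5, shape = k)
      theta <- min(theta, 0.95 * margin / qmed)
    }
    g <- stats::rgamma(n, shape = k, scale = theta)
    shift <- median_target - stats::qgamma(0.5, shape = k, scale = theta)
    x <- shift + g
    if (skew_target < 0) x <- 2 * median_target - x
  }
  if (!is.null(floor)) x <- pmax(x, floor + 0.01)
  x
}

# internal: logical ellipsoid on a grid (voxel-index semi-axes)
ellipsoidMask <- function(grid_shape, center, semi_axes) {
  d <- grid_shape
  x <- ((seq_len(d[1]) - center[1]) / semi_axes[1])^2
  y <- ((seq_len(d[2]) - center[2]) / semi_axes[2])^2
  z <- ((seq_len(d[3]) - center[3]) / semi_axes[3])^2
  outer(outer(x, y, `+`), z, `+`) <= 1
}

# internal: 6-connected binary dilation / erosion via shifted arrays
shiftArr <- function(a, axis, by, fill) {
  d <- dim(a)
  idx <- lapply(d, seq_len)
  src <- idx
  n <- d[axis]
  if (by == 1L) src[[axis]] <- c(1L, seq_len(n - 1L))
  else src[[axis]] <- c(seq_len(n - 1L) + 1L, n)
  out <- a[src[[1]], src[[2]], src[[3]], drop = FALSE]
  # edge plane takes the fill value
  edge <- idx
  edge[[axis]] <- if (by == 1L) 1L else n
  out[edge[[1]], edge[[2]], edge[[3]]] <- fill
  out
}

morph6 <- function(mask, op = c("dilate", "erode")) {
  op <- match.arg(op)
  fill <- op == "erode"
  acc <- mask
  for (axis in 1:3) for (by in c(1L, -1L)) {
    s <- shiftArr(mask, axis, by, fill)
    acc <- if (op == "dilate") acc | s else acc & s
  }
  acc
}

# internal: separable 3-point box smoothing, it iterations
boxSmooth3d <- function(a, iters = 2L) {
  for (i in seq_len(iters)) for (axis in 1:3)
    a <- (shiftArr(a, axis, 1L, 0) + a + shiftArr(a, axis, -1L, 0)) / 3
  a
}

#' Generate one synthetic PET-CT phantom patient
#'
#' Builds a PET volume with a noisy ellipsoidal liver (Normal around the
#' configured reference), a flat low background with mild noise, and 1-3
#' ellipsoidal lesions filled by [sampleLesionIntensities()] from
#' patient-level median/skewness targets; a CT volume with smoothed HU
#' texture carrying no outcome signal; a liver mask; and two reader tumour
#' masks, reader 2 derived from reader 1 by random dilate/erode iterations.
#' Outcomes (response, PFS, TPS) are drawn from the configured links.
#'
#' @param config a `SyntheticConfig`.
#' @param patient_index 1-based patient number; the RNG substream is
#'   `config$seed + patient_index`, so cohorts are extensible.
#' @return a `SyntheticPatient` list (volumes, masks, latent traits,
#'   `outcome_row` one-row data.frame).
#' @export
generatePhantom <- function(config, patient_index) {
  cfg <- config
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(cfg$seed + patient_index)
  d <- cfg$grid_shape
  sp <- cfg$spacing_mm
  thr_implied <- 1.5 * cfg$liver_mean_suv + 2 * cfg$liver_sd_suv

  liver <- ellipsoidMask(d, center = c(0.28, 0.35, 0.40) * d,
                         semi_axes = c(0.16, 0.13, 0.15) * d)
  pet <- array(stats::rnorm(prod(d), cfg$background_suv, 0.05), dim = d)
  pet[liver] <- stats::rnorm(sum(liver), cfg$liver_mean_suv, cfg$liver_sd_suv)

  med_t <- stats::runif(1, cfg$lesion_median_range[1], cfg$lesion_median_range[2])
  skw_t <- stats::runif(1, cfg$lesion_skew_range[1], cfg$lesion_skew_range[2])
  n_les <- sample(seq(cfg$lesions_per_patient[1], cfg$lesions_per_patient[2]), 1)
  tumor <- array(FALSE, dim = d)
  liver_guard <- morph6(liver, "dilate")
  placed <- 0L
  tries <- 0L
  while (placed < n_les) {
    tries <- tries + 1L
    if (tries > 50L)
      petradStop("petrad_placement_failed",
                 "could not place lesions clear of the liver")
    ctr <- c(stats::runif(1, 9, d[1] - 8), stats::runif(1, 9, d[2] - 8),
             stats::runif(1, 9, d[3] - 8))
    ax <- stats::runif(3, 3.0, 6.0)
    les <- ellipsoidMask(d, ctr, ax)
    if (sum(les) < 50L || any(les & liver_guard)) next
    tumor <- tumor | les
    placed <- placed + 1L
  }
  vox <- which(tumor)
  pet[vox] <- sampleLesionIntensities(med_t, skw_t, length(vox),
                                      spread = 1.0, floor = thr_implied + 0.05)

  ct <- 40 + 30 * boxSmooth3d(array(stats::rnorm(prod(d)), dim = d), 2L) * 3
  ct[tumor] <- ct[tumor] + 15
  ct[liver] <- ct[liver] + 20

  # reader 2: stochastic boundary dilate/erode inside the FDG-positive
  # voxel universe. PERCIST masks are threshold-defined and manual edits
  # remove (or restore) boundary uptake, so reader differences live within
  # the above-threshold voxels: erode drops a random subset of the inner
  # boundary, dilate restores a random subset of previously removed voxels.
  r2 <- tumor
  if (cfg$reader2_perturb_iters > 0L) {
    for (i in seq_len(cfg$reader2_perturb_iters)) {
      op <- if (stats::runif(1) < 0.5) "dilate" else "erode"
      if (op == "dilate") {
        layer <- which(morph6(r2, "dilate") & !r2 & tumor)
      } else {
        layer <- which(r2 & !morph6(r2, "erode"))
      }
      if (length(layer) == 0L) next
      flip <- layer[stats::runif(length(layer)) < 0.3]
      cand <- r2
      cand[flip] <- op == "dilate"
      if (sum(cand & tumor) > 0L && sum(cand) >= 2L) r2 <- cand
    }
  }

  # outcomes
  p_nr <- stats::plogis(cfg$beta0 + cfg$beta_skew * skw_t +
                        cfg$beta_median * med_t)
  nonresp <- stats::runif(1) < p_nr
  recist <- if (nonresp) "PD" else
    sample(c("CR", "PR", "SD"), 1, prob = c(1, 17, 15) / 33)
  lp <- cfg$gamma_skew * skw_t + cfg$gamma_median * med_t
  t_event <- cfg$base_scale *
    (-log(stats::runif(1)) / exp(lp))^(1 / cfg$weibull_shape)
  # administrative censoring: staggered accrual gives each patient a
  # follow-up horizon uniform on [6, censor_horizon]
  cens <- stats::runif(1, min(6, cfg$censor_horizon_months),
                       cfg$censor_horizon_months)
  event <- as.integer(t_event <= cens)
  pfs <- min(t_event, cens)
  tps <- sample(c("TPS>=50", "TPS1-49", "TPS<1"), 1, prob = cfg$tps_probs)

  pid <- sprintf("P%03d", patient_index)
  list(patient_id = pid,
       pet = voxelGrid(pet, sp),
       ct = voxelGrid(ct, sp),
       liver_mask = roiMask(liver, sp, reader = "none", role = "liver"),
       tumor_mask_reader1 = roiMask(tumor, sp, reader = "reader1", role = "tumor"),
       tumor_mask_reader2 = roiMask(r2, sp, reader = "reader2", role = "tumor"),
       true_median = med_t,
       true_skewness = skw_t,
       outcome_row = data.frame(
         patient_id = pid, recist = recist,
         responder = as.integer(!nonresp),
         overall_progression = event,
         pfs_months = pfs, event = event, tps_group = tps,
         stringsAsFactors = FALSE))
}

#' Generate a full synthetic cohort
#'
#' @param config a `SyntheticConfig`.
#' @return list with `patients` (list of phantoms) and `cohort`
#'   (per-patient outcome data.frame with columns patient_id, recist,
#'   responder, overall_progression, pfs_months, event, tps_group).
#' @export
generateCohort <- function(config) {
  patients <- lapply(seq_len(config$n_patients),
                     function(k) generatePhantom(config, k))
  cohort <- do.call(rbind, lapply(patients, `[[`, "outcome_row"))
  rownames(cohort) <- NULL
  list(patients = patients, cohort = cohort)
}

#' Draw outcome rows only (no imaging) for calibration studies
#'
#' Uses the same trait and outcome links as [generatePhantom()] but skips
#' volume synthesis, which makes large-n calibration checks of the logistic
#' and survival links cheap.
#'
#' @param config a `SyntheticConfig`.
#' @return data.frame with latent traits and outcome columns.
#' @export
generateOutcomesOnly <- function(config) {
  cfg <- config
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(cfg$seed)
  n <- cfg$n_patients
  med <- stats::runif(n, cfg$lesion_median_range[1], cfg$lesion_median_range[2])
  skw <- stats::runif(n, cfg$lesion_skew_range[1], cfg$lesion_skew_range[2])
  p_nr <- stats::plogis(cfg$beta0 + cfg$beta_skew * skw + cfg$beta_median * med)
  nonresp <- stats::runif(n) < p_nr
  lp <- cfg$gamma_skew * skw + cfg$gamma_median * med
  t_event <- cfg$base_scale *
    (-log(stats::runif(n)) / exp(lp))^(1 / cfg$weibull_shape)
  cens <- stats::runif(n, min(6, cfg$censor_horizon_months),
                       cfg$censor_horizon_months)
  event <- as.integer(t_event <= cens)
  tps <- sample(c("TPS>=50", "TPS1-49", "TPS<1"), n, replace = TRUE,
                prob = cfg$tps_probs)
  data.frame(patient_id = sprintf("P%03d", seq_len(n)),
             true_median = med, true_skewness = skw,
             responder = as.integer(!nonresp),
             overall_progression = event,
             pfs_months = pmin(t_event, cens),
             event = event, tps_group = tps, stringsAsFactors = FALSE)
}
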