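#' Catalog of the 84 radiomic feature names (one modality)
#'
#' 12 shape + 24 first-order + 48 GLCM names, in extraction order and
#' without the modality prefix.
#'
#' @return character vector of length 84.
#' @export
featureCatalog <- function() {
  shape <- c("VoxelCount", "VolumeMl", "SurfaceArea", "SurfaceToVolumeRatio",
             "Compactness1", "Compactness2", "SphericalDisproportion",
             "Sphericity", "Maximum3DDiameter", "MajorAxisLength",
             "MinorAxisLength", "LeastAxisLength")
  fo <- c("Mean", "Median", "Minimum", "Maximum", "Range", "Variance",
          "StandardDeviation", "Skewness", "Kurtosis", "Energy",
          "TotalEnergy", "Entropy", "Uniformity", "RootMeanSquare",
          "MeanAbsoluteDeviation", "RobustMeanAbsoluteDeviation",
          "MedianAbsoluteDeviation", "InterquartileRange",
          "P10", "P25", "P75", "P90", "CoefficientOfVariation",
          "QuartileCoefficientOfDispersion")
  glcm_stats <- c("Autocorrelation", "JointAverage", "ClusterProminence",
                  "ClusterShade", "ClusterTendency", "Contrast",
                  "Correlation", "DifferenceAverage", "DifferenceEntropy",
                  "DifferenceVariance", "JointEnergy", "JointEntropy",
                  "Imc1", "Imc2", "InverseDifference",
                  "InverseDifferenceNormalized", "InverseDifferenceMoment",
                  "InverseDifferenceMomentNormalized", "InverseVariance",
                  "MaximumProbability", "SumAverage", "SumEntropy",
                  "SumOfSquares", "Dissimilarity")
  c(shape, fo,
    sprintf("GLCM-%s-d1", glcm_stats), sprintf("GLCM-%s-d2", glcm_stats))
}

# internal: 84 features for one modality (no prefix)
extractOneModality <- function(volume, mask, bin_count, distances) {
  out <- c(shapeFeatures(mask),
           firstOrderFeatures(volume, mask, bin_count),
           glcmFeatures(volume, mask, bin_count, distances))
  stopifnot(identical(names(out), featureCatalog()))
  out
}

#' Extract the dual-modality radiomic signature of one patient
#'
#' Computes the full 84-feature catalog on the PET and on the CT volume
#' using one reader's tumour mask (the total tumour burden, i.e. the union
#' of all lesions). Feature names are prefixed `PET-` / `CT-`, so
#' `PET-Skewness` and `PET-Median` exist by name. The shape block depends
#' only on the mask and is therefore identical between modalities.
#'
#' @param pet,ct [VoxelGrid-class] volumes on the same grid as `tumor_mask`
#'   (the mask is transferred with [transferLabelmap()] if the CT geometry
#'   differs).
#' @param tumor_mask an [RoiMask-class].
#' @param reader_id reader label recorded with the result.
#' @param bin_count grey levels for discretization (default 64).
#' @param distances GLCM offset distances in voxels.
#' @return named list with `pet` and `ct` numeric vectors (84 each) and
#'   `reader`.
#' @export
extractPatient <- function(pet, ct, tumor_mask, reader_id = readerId(tumor_mask),
                           bin_count = 64L, distances = c(1L, 2L)) {
  pet_f <- extractOneModality(pet, tumor_mask, bin_count, distances)
  ct_mask <- transferLabelmap(tumor_mask, ct)
  ct_f <- extractOneModality(ct, ct_mask, bin_count, distances)
  names(pet_f) <- paste0("PET-", names(pet_f))
  names(ct_f) <- paste0("CT-", names(ct_f))
  list(pet = pet_f, ct = ct_f, reader = reader_id)
}

#' Extract per-reader feature tables for a whole cohort
#'
#' Runs PERCIST segmentation and dual-modality feature extraction for every
#' patient and both readers; reader 1 uses the threshold segmentation of the
#' PET volume directly, reader 2 uses the (perturbed) reader-2 mask.
#'
#' @param patients list of `SyntheticPatient` objects from
#'   [generateCohort()] (or equivalently structured lists).
#' @param bin_count,distances passed to [extractPatient()].
#' @return list with `reader1` and `reader2`: numeric matrices
#'   (patients x 168 features, PET block then CT block), and `mtv_ml`,
#'   `threshold_suv` per patient.
#' @export
extractCohortFeatures <- function(patients, bin_count = 64L,
                                  distances = c(1L, 2L)) {
  nms <- c(paste0("PET-", featureCatalog()), paste0("CT-", featureCatalog()))
  n <- length(patients)
  r1 <- matrix(NA_real_, n, length(nms), dimnames = list(NULL, nms))
  r2 <- r1
  mtv <- thr <- numeric(n)
  ids <- character(n)
  for (k in seq_len(n)) {
    p <- patients[[k]]
    ids[k] <- p$patient_id
    ls <- liverReferenceStats(p$pet, p$liver_mask)
    t_k <- percistThreshold(ls)
    seg <- segmentLesions(p$pet, t_k,
                          exclusion_masks = list(p$liver_mask),
                          min_voxels = 2L, reader = "reader1")
    thr[k] <- t_k
    mtv[k] <- totalMtvMl(seg)
    f1 <- extractPatient(p$pet, p$ct, tumorMask(seg), "reader1",
                         bin_count, distances)
    f2 <- extractPatient(p$pet, p$ct, p$tumor_mask_reader2, "reader2",
                         bin_count, distances)
    r1[k, ] <- c(f1$pet, f1$ct)
    r2[k, ] <- c(f2$pet, f2$ct)
  }
  rownames(r1) <- rownames(r2) <- ids
  list(reader1 = r1, reader2 = r2, mtv_ml = mtv, threshold_suv = thr)
}
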