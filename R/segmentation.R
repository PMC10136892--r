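#' Liver reference statistics for PERCIST thresholding
#'
#' Summarises the SUV distribution inside a liver reference region. The
#' standard deviation uses the sample (n - 1) convention.
#'
#' @param pet a [VoxelGrid-class] with SUV values.
#' @param liver_mask an [RoiMask-class] aligned to `pet`.
#' @return list with `mean_suv`, `sd_suv`, `n_voxels`.
#' @export
liverReferenceStats <- function(pet, liver_mask) {
  checkAligned(pet, liver_mask)
  v <- gridData(pet)[maskArray(liver_mask)]
  if (length(v) == 0L)
    petradStop("petrad_invalid_reference", "liver reference mask is empty")
  list(mean_suv = mean(v),
       sd_suv = if (length(v) > 1L) stats::sd(v) else 0,
       n_voxels = length(v))
}

#' PERCIST-style SUV threshold
#'
#' The FDG-positivity threshold is 1.5 x mean liver SUV + 2 x liver SUV
#' standard deviation. The formula is affine; no floor is applied.
#'
#' @param stats list as returned by [liverReferenceStats()].
#' @return threshold in SUV units.
#' @examples
#' percistThreshold(list(mean_suv = 2, sd_suv = 0.25)) # 3.5
#' @export
percistThreshold <- function(stats) {
  1.5 * stats$mean_suv + 2 * stats$sd_suv
}

# internal: 26-connected component labelling on a logical 3-D array.
# Returns an integer array (0 = background) plus component sizes.
labelComponents <- function(mask) {
  d <- dim(mask)
  labels <- array(0L, dim = d)
  idx <- which(mask)
  if (length(idx) == 0L)
    return(list(labels = labels, sizes = integer()))
  # linear-index offsets of the 26 neighbours
  nb <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nb <- nb[rowSums(abs(nb)) > 0, , drop = FALSE]
  coord <- arrayInd(idx, d)
  inMask <- array(FALSE, dim = d)
  inMask[idx] <- TRUE
  sizes <- integer()
  lab <- 0L
  for (s in idx) {
    if (labels[s] != 0L) next
    lab <- lab + 1L
    queue <- s
    labels[s] <- lab
    size <- 0L
    while (length(queue)) {
      cur <- queue
      queue <- integer()
      size <- size + length(cur)
      cc <- arrayInd(cur, d)
      for (k in seq_len(nrow(nb))) {
        nx <- cc[, 1] + nb[k, 1]; ny <- cc[, 2] + nb[k, 2]
        nz <- cc[, 3] + nb[k, 3]
        ok <- nx >= 1L & nx <= d[1] & ny >= 1L & ny <= d[2] &
              nz >= 1L & nz <= d[3]
        if (!any(ok)) next
        lin <- nx[ok] + (ny[ok] - 1L) * d[1] + (nz[ok] - 1L) * d[1] * d[2]
        lin <- lin[inMask[lin] & labels[lin] == 0L]
        if (length(lin)) {
          labels[lin] <- lab
          queue <- c(queue, lin)
        }
      }
      queue <- unique(queue)
    }
    sizes[lab] <- size
  }
  list(labels = labels, sizes = sizes)
}

#' Segment FDG-positive tumour volume
#'
#' Thresholds the PET volume at `threshold` SUV (closed rule: voxels with
#' SUV >= threshold are included), removes voxels covered by any exclusion
#' mask (the stand-in for manual removal of physiological uptake such as
#' liver, heart and bladder), then drops 26-connected components smaller
#' than `min_voxels`.
#'
#' @param pet a [VoxelGrid-class] with SUV values.
#' @param threshold SUV threshold, typically from [percistThreshold()].
#' @param exclusion_masks list of [RoiMask-class] to subtract (may be empty).
#' @param min_voxels minimum component size kept (default 2 drops
#'   single-voxel noise).
#' @param reader reader identity recorded on the output mask.
#' @return A [SegmentationResult-class].
#' @export
segmentLesions <- function(pet, threshold, exclusion_masks = list(),
                           min_voxels = 2L, reader = "none") {
  if (!is.finite(threshold) || threshold <= 0)
    petradStop("petrad_invalid_reference", "threshold must be positive")
  m <- gridData(pet) >= threshold
  for (ex in exclusion_masks) {
    checkAligned(pet, ex)
    m <- m & !maskArray(ex)
  }
  comp <- labelComponents(m)
  keep <- which(comp$sizes >= min_voxels)
  m <- array(comp$labels %in% keep, dim = dim(m))
  if (!any(m))
    petradStop("petrad_no_tumor_found",
               sprintf("no FDG-positive component of >= %d voxels above SUV %.3f",
                       min_voxels, threshold))
  mtv_ml <- sum(m) * prod(spacing(pet)) / 1000
  new("SegmentationResult",
      threshold_suv = threshold,
      tumor_mask = roiMask(m, spacing = spacing(pet), reader = reader,
                           role = "tumor"),
      n_components = length(keep),
      total_mtv_ml = mtv_ml)
}

#' Transfer a tumour label map onto another grid
#'
#' With identical geometry the mask is passed through; otherwise it is
#' resampled by nearest neighbour, assuming both grids share the physical
#' origin at the corner of voxel (1,1,1).
#'
#' @param tumor_mask an [RoiMask-class].
#' @param target a [VoxelGrid-class] defining the output geometry.
#' @return An [RoiMask-class] aligned to `target`.
#' @export
transferLabelmap <- function(tumor_mask, target) {
  sdim <- dim(maskArray(tumor_mask)); tdim <- dim(gridData(target))
  ssp <- spacing(tumor_mask); tsp <- spacing(target)
  if (identical(sdim, tdim) && max(abs(ssp - tsp)) < 1e-6)
    return(roiMask(maskArray(tumor_mask), spacing = tsp,
                   reader = readerId(tumor_mask), role = tumor_mask@role))
  # physical extents must agree for an origin-aligned resample
  if (max(abs(sdim * ssp - tdim * tsp)) > max(ssp, tsp))
    petradStop("petrad_geometry_mismatch",
               "grids cover different physical extents; supply a transform")
  near <- function(n_t, sp_t, sp_s, n_s) {
    centers <- (seq_len(n_t) - 0.5) * sp_t        # mm from origin
    i <- pmin(pmax(ceiling(centers / sp_s), 1L), n_s)
    as.integer(i)
  }
  xi <- near(tdim[1], tsp[1], ssp[1], sdim[1])
  yi <- near(tdim[2], tsp[2], ssp[2], sdim[2])
  zi <- near(tdim[3], tsp[3], ssp[3], sdim[3])
  out <- maskArray(tumor_mask)[xi, yi, zi]
  roiMask(out, spacing = tsp, reader = readerId(tumor_mask),
          role = tumor_mask@role)
}
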