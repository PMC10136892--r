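#' Equal-width intensity discretization
#'
#' Maps values onto integer grey levels 1..`bin_count` with equal-width bins
#' spanning `[min, max]` of the input. The maximum value falls in bin
#' `bin_count`; constant input maps entirely to level 1.
#'
#' @param values numeric vector (typically the masked voxel values).
#' @param bin_count number of grey levels (>= 2).
#' @return integer vector of levels in `[1, bin_count]`.
#' @export
discretize <- function(values, bin_count = 64L) {
  stopifnot(length(values) > 0L, bin_count >= 2L)
  rng <- range(values)
  if (rng[2] <= rng[1]) return(rep(1L, length(values)))
  lev <- floor((values - rng[1]) / (rng[2] - rng[1]) * bin_count) + 1L
  as.integer(pmin(lev, bin_count))
}

# internal: first-order statistics from a plain value vector.
# Moments are population moments (n denominators, no bias correction);
# percentiles interpolate linearly between order statistics (type 7).
firstOrderFromValues <- function(v, bin_count = 64L, voxel_volume_mm3 = 1) {
  n <- length(v)
  if (n < 2L)
    petradStop("petrad_degenerate_region",
               "first-order moments need at least 2 voxels")
  mu <- mean(v)
  m2 <- mean((v - mu)^2)
  m3 <- mean((v - mu)^3)
  m4 <- mean((v - mu)^4)
  sdv <- sqrt(m2)
  q <- stats::quantile(v, c(0.10, 0.25, 0.50, 0.75, 0.90),
                       names = FALSE, type = 7)
  med <- q[3]
  lev <- discretize(v, bin_count)
  p <- tabulate(lev, nbins = bin_count) / n
  pnz <- p[p > 0]
  core <- v[v >= q[1] & v <= q[5]]
  c(Mean = mu,
    Median = med,
    Minimum = min(v),
    Maximum = max(v),
    Range = max(v) - min(v),
    Variance = m2,
    StandardDeviation = sdv,
    Skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    Kurtosis = if (m2 > 0) m4 / m2^2 else 0,
    Energy = sum(v^2),
    TotalEnergy = voxel_volume_mm3 * sum(v^2),
    Entropy = -sum(pnz * log2(pnz)),
    Uniformity = sum(p^2),
    RootMeanSquare = sqrt(mean(v^2)),
    MeanAbsoluteDeviation = mean(abs(v - mu)),
    RobustMeanAbsoluteDeviation =
      if (length(core)) mean(abs(core - mean(core))) else 0,
    MedianAbsoluteDeviation = mean(abs(v - med)),
    InterquartileRange = q[4] - q[2],
    P10 = q[1], P25 = q[2], P75 = q[4], P90 = q[5],
    CoefficientOfVariation = if (mu != 0) sdv / mu else 0,
    QuartileCoefficientOfDispersion =
      if ((q[4] + q[2]) != 0) (q[4] - q[2]) / (q[4] + q[2]) else 0)
}

#' First-order (histogram) features of a masked volume
#'
#' 24 intensity statistics of the voxel values inside the mask. Skewness is
#' the Fisher-Pearson population moment ratio and kurtosis is non-excess;
#' entropy and uniformity are computed on the equal-width discretized
#' histogram ([discretize()]).
#'
#' @param volume a [VoxelGrid-class].
#' @param mask an [RoiMask-class] aligned to `volume`.
#' @param bin_count grey levels for the entropy/uniformity histogram.
#' @return named numeric vector of 24 features.
#' @export
firstOrderFeatures <- function(volume, mask, bin_count = 64L) {
  checkAligned(volume, mask)
  v <- gridData(volume)[maskArray(mask)]
  if (length(v) == 0L)
    petradStop("petrad_degenerate_region", "empty mask")
  firstOrderFromValues(v, bin_count, prod(spacing(volume)))
}

#' Shape and size features of a mask
#'
#' 12 morphological descriptors. Surface area comes from the boundary-face
#' mesh: every voxel face exposed to background contributes its physical
#' face area. Axis lengths are 4 x sqrt(eigenvalue) of the physical
#' voxel-coordinate covariance (population convention).
#'
#' @param mask an [RoiMask-class].
#' @param spacing_mm optional spacing override (defaults to the mask's).
#' @return named numeric vector of 12 features.
#' @export
shapeFeatures <- function(mask, spacing_mm = spacing(mask)) {
  m <- maskArray(mask)
  n <- sum(m)
  if (n == 0L)
    petradStop("petrad_degenerate_region", "empty mask")
  sp <- spacing_mm
  d <- dim(m)
  vol_mm3 <- n * prod(sp)

  # exposed faces along each axis: voxel in-mask with out-of-mask (or
  # out-of-grid) neighbour; face area is the product of the other spacings
  pad <- array(FALSE, dim = d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- m
  faces <- 0
  areas <- c(sp[2] * sp[3], sp[1] * sp[3], sp[1] * sp[2])
  shifts <- list(c(1, 0, 0), c(2, 0, 0), c(0, 1, 0), c(0, 2, 0),
                 c(0, 0, 1), c(0, 0, 2))
  for (k in seq_along(shifts)) {
    s <- shifts[[k]]
    off <- c(if (s[1] == 1) 0L else if (s[1] == 2) 2L else 1L,
             if (s[2] == 1) 0L else if (s[2] == 2) 2L else 1L,
             if (s[3] == 1) 0L else if (s[3] == 2) 2L else 1L)
    nbr <- pad[off[1] + (1:d[1]), off[2] + (1:d[2]), off[3] + (1:d[3])]
    faces <- faces + sum(m & !nbr) * areas[ceiling(k / 2)]
  }
  A <- faces

  coord <- arrayInd(which(m), d)
  phys <- sweep(coord, 2, sp, `*`)
  # max 3-D diameter over boundary voxels (centres); boundary = any exposed face
  bnd <- m
  inner <- pad[1:d[1] + 1L, 1:d[2] + 1L, 1:d[3] + 1L]
  for (s in shifts) {
    off <- c(if (s[1] == 1) 0L else if (s[1] == 2) 2L else 1L,
             if (s[2] == 1) 0L else if (s[2] == 2) 2L else 1L,
             if (s[3] == 1) 0L else if (s[3] == 2) 2L else 1L)
    inner <- inner & pad[off[1] + (1:d[1]), off[2] + (1:d[2]), off[3] + (1:d[3])]
  }
  surf <- which(m & !inner)
  if (length(surf) == 0L) surf <- which(m)
  sc <- sweep(arrayInd(surf, d), 2, sp, `*`)
  maxdiam <- if (nrow(sc) == 1L) 0 else {
    dd <- as.matrix(stats::dist(sc))
    max(dd)
  }
  if (n >= 2L) {
    cv <- stats::cov(phys) * (n - 1) / n
    ev <- sort(eigen(cv, symmetric = TRUE, only.values = TRUE)$values,
               decreasing = TRUE)
    ev[ev < 0] <- 0
    axes <- 4 * sqrt(ev)
  } else axes <- c(0, 0, 0)

  R <- (3 * vol_mm3 / (4 * pi))^(1 / 3)
  c(VoxelCount = as.numeric(n),
    VolumeMl = vol_mm3 / 1000,
    SurfaceArea = A,
    SurfaceToVolumeRatio = A / vol_mm3,
    Compactness1 = vol_mm3 / (sqrt(pi) * A^1.5),
    Compactness2 = 36 * pi * vol_mm3^2 / A^3,
    SphericalDisproportion = A / (4 * pi * R^2),
    Sphericity = pi^(1 / 3) * (6 * vol_mm3)^(2 / 3) / A,
    Maximum3DDiameter = maxdiam,
    MajorAxisLength = axes[1],
    MinorAxisLength = axes[2],
    LeastAxisLength = axes[3])
}
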