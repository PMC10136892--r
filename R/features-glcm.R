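# The 13 unique 3-D direction vectors (one per axis/diagonal pair); the
# opposite directions are covered by symmetrization.
glcmDirections <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  # keep the lexicographically positive half
  keep <- g[, 3] > 0 | (g[, 3] == 0 & g[, 2] > 0) |
          (g[, 3] == 0 & g[, 2] == 0 & g[, 1] > 0)
  unname(g[keep, , drop = FALSE])
}

#' Grey-level co-occurrence matrix at one offset
#'
#' Counts co-occurring grey-level pairs `(i, j)` for voxel pairs
#' `(x, x + offset)` with both voxels inside the mask, symmetrizes (each
#' pair counted in both directions) and normalizes to sum 1.
#'
#' @param levels integer 3-D array of grey levels (NA outside the mask is
#'   allowed), e.g. from [discretize()] reshaped onto the grid.
#' @param mask an [RoiMask-class]; only within-mask pairs are counted.
#' @param offset integer length-3 displacement in voxels (nonzero).
#' @param n_levels size of the matrix (defaults to max level present).
#' @return list with `matrix` (`n_levels x n_levels`, sums to 1), `levels`,
#'   `offset` and `n_pairs` (directed pair count before symmetrization).
#' @export
glcmMatrix <- function(levels, mask, offset, n_levels = NULL) {
  stopifnot(length(offset) == 3L, any(offset != 0))
  m <- maskArray(mask)
  d <- dim(m)
  lev <- levels
  lev[!m] <- NA_integer_
  if (is.null(n_levels)) n_levels <- max(lev, na.rm = TRUE)
  o <- as.integer(offset)
  lo <- pmax(1L, 1L - o)
  hi <- pmin(d, d - o)
  if (any(hi < lo))
    petradStop("petrad_degenerate_region", "offset exceeds grid extent")
  xr <- lo[1]:hi[1]; yr <- lo[2]:hi[2]; zr <- lo[3]:hi[3]
  a <- lev[xr, yr, zr, drop = FALSE]
  b <- lev[xr + o[1], yr + o[2], zr + o[3], drop = FALSE]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok))
    petradStop("petrad_degenerate_region",
               "no within-mask voxel pairs at this offset")
  ai <- a[ok]; bi <- b[ok]
  counts <- matrix(tabulate(ai + (bi - 1L) * n_levels,
                            nbins = n_levels * n_levels),
                   n_levels, n_levels)
  sym <- counts + t(counts)
  list(matrix = sym / sum(sym), levels = n_levels, offset = o,
       n_pairs = sum(ok))
}

# internal: 24 texture statistics from one normalized symmetric GLCM.
# Degenerate conventions: correlation, IMC1 and IMC2 are 0 when the
# marginal distribution is concentrated on a single level.
glcmStatsFromMatrix <- function(P) {
  L <- nrow(P)
  i <- matrix(seq_len(L), L, L)
  j <- t(i)
  px <- rowSums(P)
  mu <- sum(i[, 1] * px)
  sig2 <- sum((i[, 1] - mu)^2 * px)
  # diagonal / cross-diagonal marginals
  k_diff <- 0:(L - 1)
  p_diff <- sapply(k_diff, function(k) sum(P[abs(i - j) == k]))
  k_sum <- 2:(2 * L)
  p_sum <- sapply(k_sum, function(k) sum(P[(i + j) == k]))
  DA <- sum(k_diff * p_diff)
  nzP <- P[P > 0]
  HXY <- -sum(nzP * log2(nzP))
  pxy <- outer(px, px)
  okm <- P > 0 & pxy > 0
  HXY1 <- -sum(P[okm] * log2(pxy[okm]))
  nzm <- pxy[pxy > 0]
  HXY2 <- -sum(nzm * log2(nzm))
  HX <- { nz <- px[px > 0]; -sum(nz * log2(nz)) }
  imc1 <- if (HX > 0) (HXY - HXY1) / HX else 0
  imc2 <- if (HXY2 >= HXY) sqrt(1 - exp(-2 * (HXY2 - HXY))) else 0
  if (HX == 0) imc2 <- 0
  nzd <- p_diff[p_diff > 0]
  nzs <- p_sum[p_sum > 0]
  offdiag <- abs(i - j) > 0
  c(Autocorrelation = sum(i * j * P),
    JointAverage = mu,
    ClusterProminence = sum((i + j - 2 * mu)^4 * P),
    ClusterShade = sum((i + j - 2 * mu)^3 * P),
    ClusterTendency = sum((i + j - 2 * mu)^2 * P),
    Contrast = sum((i - j)^2 * P),
    Correlation = if (sig2 > 0) (sum(i * j * P) - mu^2) / sig2 else 0,
    DifferenceAverage = DA,
    DifferenceEntropy = -sum(nzd * log2(nzd)),
    DifferenceVariance = sum((k_diff - DA)^2 * p_diff),
    JointEnergy = sum(P^2),
    JointEntropy = HXY,
    Imc1 = imc1,
    Imc2 = imc2,
    InverseDifference = sum(P / (1 + abs(i - j))),
    InverseDifferenceNormalized = sum(P / (1 + abs(i - j) / L)),
    InverseDifferenceMoment = sum(P / (1 + (i - j)^2)),
    InverseDifferenceMomentNormalized = sum(P / (1 + (i - j)^2 / L^2)),
    InverseVariance = sum(P[offdiag] / (i - j)[offdiag]^2),
    MaximumProbability = max(P),
    SumAverage = sum(k_sum * p_sum),
    SumEntropy = -sum(nzs * log2(nzs)),
    SumOfSquares = sig2,
    Dissimilarity = sum(abs(i - j) * P))
}

#' GLCM texture features
#'
#' For each offset distance the normalized symmetric co-occurrence matrices
#' over the 13 unique 3-D directions are averaged into one matrix, from
#' which 24 texture statistics are computed; with the default distances
#' `c(1, 2)` this yields the 48-feature GLCM block. Grey levels are
#' rediscretized over the masked intensity range ([discretize()]).
#'
#' @param volume a [VoxelGrid-class].
#' @param mask an [RoiMask-class] aligned to `volume`.
#' @param bin_count grey levels used for discretization.
#' @param distances integer offsets (in voxels) along each direction.
#' @return named numeric vector, `24 * length(distances)` features named
#'   `GLCM-<Statistic>-d<distance>`.
#' @export
glcmFeatures <- function(volume, mask, bin_count = 64L, distances = c(1L, 2L)) {
  checkAligned(volume, mask)
  m <- maskArray(mask)
  v <- gridData(volume)[m]
  if (length(v) < 2L)
    petradStop("petrad_degenerate_region", "mask too small for texture")
  lev <- array(NA_integer_, dim = dim(m))
  lev[m] <- discretize(v, bin_count)
  Ng <- max(lev, na.rm = TRUE)
  dirs <- glcmDirections()
  out <- numeric(0)
  for (dist in distances) {
    acc <- matrix(0, Ng, Ng)
    used <- 0L
    for (r in seq_len(nrow(dirs))) {
      off <- dirs[r, ] * dist
      g <- tryCatch(glcmMatrix(lev, mask, off, n_levels = Ng),
                    petrad_degenerate_region = function(e) NULL)
      if (is.null(g)) next
      acc <- acc + g$matrix
      used <- used + 1L
    }
    if (used == 0L)
      petradStop("petrad_degenerate_region",
                 sprintf("no voxel pairs at distance %d", dist))
    stats <- glcmStatsFromMatrix(acc / used)
    names(stats) <- sprintf("GLCM-%s-d%d", names(stats), dist)
    out <- c(out, stats)
  }
  out
}
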