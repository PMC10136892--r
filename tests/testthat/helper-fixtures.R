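# Programmatic fixtures, built once per test run and memoised.

.fixture_env <- new.env(parent = emptyenv())

# a small default-parameter phantom (one patient), reused across files
fixturePhantom <- function() {
  if (is.null(.fixture_env$phantom)) {
    cfg <- syntheticConfig(n_patients = 4, seed = 101)
    .fixture_env$phantom <- generatePhantom(cfg, 1)
  }
  .fixture_env$phantom
}

# a compact sphere-in-background PET grid for segmentation tests
fixtureSpherePet <- function(suv_sphere = 6, suv_bg = 1, r = 4,
                             dim3 = c(24, 24, 24), spacing = c(4, 4, 4)) {
  a <- array(suv_bg, dim = dim3)
  ctr <- dim3 / 2
  for (x in seq_len(dim3[1])) for (y in seq_len(dim3[2]))
    for (z in seq_len(dim3[3]))
      if (sum((c(x, y, z) - ctr)^2) <= r^2) a[x, y, z] <- suv_sphere
  voxelGrid(a, spacing)
}

# small random masked volume for oracle cross-checks (<= 8^3)
fixtureRandomMaskedVolume <- function(seed, dim3 = c(8, 8, 8),
                                      p_mask = 0.7) {
  set.seed(seed)
  vals <- array(stats::runif(prod(dim3), 1, 10), dim = dim3)
  m <- array(stats::runif(prod(dim3)) < p_mask, dim = dim3)
  if (sum(m) < 10) m[seq_len(10)] <- TRUE
  list(volume = voxelGrid(vals, c(2, 2, 2)),
       mask = roiMask(m, c(2, 2, 2)))
}

# digital ball mask of radius r voxels (isotropic spacing)
fixtureBallMask <- function(r, spacing = c(1, 1, 1)) {
  n <- 2L * ceiling(r) + 3L
  ctr <- (n + 1) / 2
  a <- array(FALSE, dim = c(n, n, n))
  for (x in seq_len(n)) for (y in seq_len(n)) for (z in seq_len(n))
    if (sum((c(x, y, z) - ctr)^2) <= r^2) a[x, y, z] <- TRUE
  roiMask(a, spacing)
}
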