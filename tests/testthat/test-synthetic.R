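test_that("shifted-gamma sampler hits its median and skewness targets", {
  set.seed(1)
  # gamma shape k = 4 has closed-form skewness 2/sqrt(4) = 1
  x <- sampleLesionIntensities(6, 2 / sqrt(4), 1e5)
  sk <- function(v) { m <- mean(v); mean((v - m)^3) / mean((v - m)^2)^1.5 }
  expect_equal(sk(x), 1.0, tolerance = 0.1)
  expect_equal(median(x), 6.0, tolerance = 0.1)
  # near-zero skew target falls back to the symmetric (normal) limit
  y <- sampleLesionIntensities(6, 0, 1e5)
  expect_lt(abs(sk(y)), 0.05)
  expect_equal(median(y), 6.0, tolerance = 0.1)
  # mirrored family handles negative targets
  z <- sampleLesionIntensities(6, -1, 1e5)
  expect_equal(sk(z), -1.0, tolerance = 0.1)
  expect_error(sampleLesionIntensities(6, NA, 100),
               class = "petrad_unsupported_parameter")
  expect_error(sampleLesionIntensities(6, 1, 5),
               class = "petrad_unsupported_parameter")
})

test_that("phantom generation is seed-deterministic and honours the
           reader-perturbation contract", {
  cfg <- syntheticConfig(n_patients = 4, seed = 33)
  a <- generatePhantom(cfg, 2)
  b <- generatePhantom(cfg, 2)
  expect_identical(gridData(a$pet), gridData(b$pet))
  expect_identical(maskArray(a$tumor_mask_reader2),
                   maskArray(b$tumor_mask_reader2))
  expect_identical(a$outcome_row, b$outcome_row)

  cfg0 <- syntheticConfig(n_patients = 4, seed = 33,
                          reader2_perturb_iters = 0L)
  p0 <- generatePhantom(cfg0, 1)
  expect_identical(maskArray(p0$tumor_mask_reader1),
                   maskArray(p0$tumor_mask_reader2))

  # structural invariants
  ph <- fixturePhantom()
  expect_gt(maskVoxelCount(ph$tumor_mask_reader1), 0)
  expect_gt(maskVoxelCount(ph$tumor_mask_reader2), 0)
  expect_equal(sum(maskArray(ph$liver_mask) &
                   maskArray(ph$tumor_mask_reader1)), 0)
  expect_equal(sum(maskArray(ph$liver_mask) &
                   maskArray(ph$tumor_mask_reader2)), 0)
  expect_gt(diceCoefficient(ph$tumor_mask_reader1, ph$tumor_mask_reader2), 0)
})

test_that("a near-symmetric lesion target yields a near-symmetric voxel
           histogram after segmentation", {
  cfg <- syntheticConfig(n_patients = 4, seed = 57,
                         lesions_per_patient = c(1L, 1L),
                         lesion_median_range = c(9, 9.0001),
                         lesion_skew_range = c(0, 1e-6))
  p <- generatePhantom(cfg, 1)
  ls <- liverReferenceStats(p$pet, p$liver_mask)
  seg <- segmentLesions(p$pet, percistThreshold(ls),
                        exclusion_masks = list(p$liver_mask))
  v <- gridData(p$pet)[maskArray(tumorMask(seg))]
  m <- mean(v)
  expect_lt(abs(mean((v - m)^3) / mean((v - m)^2)^1.5), 0.25)
})

test_that("reader agreement decreases with perturbation iterations", {
  iters <- c(0L, 1L, 3L, 6L)
  mean_dice <- sapply(iters, function(it) {
    cfg <- syntheticConfig(n_patients = 30, seed = 71,
                           reader2_perturb_iters = it)
    mean(sapply(seq_len(30), function(k) {
      p <- generatePhantom(cfg, k)
      diceCoefficient(p$tumor_mask_reader1, p$tumor_mask_reader2)
    }))
  })
  expect_equal(mean_dice[1], 1)
  expect_true(all(diff(mean_dice) < 0))
})

test_that("outcome links reproduce their configured rates and directions", {
  # flat link: non-responder fraction equals plogis(beta0)
  cfg <- syntheticConfig(n_patients = 2000, seed = 5,
                         beta0 = qlogis(0.25), beta_skew = 0,
                         beta_median = 0)
  d <- generateOutcomesOnly(cfg)
  expect_equal(mean(1 - d$responder), 0.25, tolerance = 0.03)
  # TPS frequencies follow the configured multinomial
  tab <- table(d$tps_group) / nrow(d)
  expect_lt(abs(tab[["TPS>=50"]] - 21 / 44), 0.04)
  expect_lt(abs(tab[["TPS1-49"]] - 13 / 44), 0.04)
  expect_lt(abs(tab[["TPS<1"]] - 10 / 44), 0.04)

  # raising beta_skew raises the non-response rate among high-skew patients
  rates <- sapply(c(1, 3), function(bs) {
    cc <- syntheticConfig(n_patients = 2000, seed = 6, beta_skew = bs,
                          beta0 = -5.4)
    dd <- generateOutcomesOnly(cc)
    hi <- dd$true_skewness > median(dd$true_skewness)
    mean(1 - dd$responder[hi])
  })
  expect_gt(rates[2], rates[1])

  # config invariants
  expect_error(syntheticConfig(n_patients = 2),
               class = "petrad_unsupported_parameter")
  expect_error(syntheticConfig(tps_probs = c(0.5, 0.4, 0.2)),
               class = "petrad_unsupported_parameter")
  expect_error(syntheticConfig(lesion_median_range = c(2, 4)),
               class = "petrad_unsupported_parameter")
})
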