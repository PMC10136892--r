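test_that("Kaplan-Meier estimates match hand-computed product limits", {
  k <- kmEstimate(c(5, 10, 15), c(1, 1, 1))
  expect_equal(k$surv, c(2 / 3, 1 / 3, 0))
  # censoring at 10 removes a subject without an event
  k2 <- kmEstimate(c(5, 10, 15), c(1, 0, 1))
  expect_equal(survivalAt(k2, 5), 2 / 3)
  expect_equal(survivalAt(k2, 15), 0)
  k3 <- kmEstimate(c(5, 10, 15), c(0, 0, 0))
  expect_true(all(k3$surv == 1))
  expect_error(kmEstimate(c(-1, 3), c(1, 1)), class = "petrad_invalid_time")
})

test_that("KM with no censoring equals the empirical survival function", {
  set.seed(3)
  t <- rexp(40, 0.1)
  k <- kmEstimate(t, rep(1, 40))
  for (q in c(2, 5, 10, 20))
    expect_equal(survivalAt(k, q), mean(t > q), tolerance = 1e-12)
})

test_that("survivalAt is a right-continuous step lookup", {
  k <- kmEstimate(c(5, 10, 15), c(1, 1, 1))
  expect_equal(survivalAt(k, 4.99), 1)
  expect_equal(survivalAt(k, 5), 2 / 3)   # post-jump value at the event
  expect_equal(survivalAt(k, 99), 0)      # carried beyond the last time
})

test_that("the log-rank test is symmetric and degenerate-safe", {
  t <- c(3, 6, 9, 12, 15, 18)
  e <- c(1, 1, 0, 1, 1, 0)
  same <- logrankTest(c(t, t), c(e, e), rep(c("a", "b"), each = 6))
  expect_equal(same$chisq, 0, tolerance = 1e-12)
  expect_equal(same$p, 1, tolerance = 1e-12)
  flip1 <- logrankTest(c(t, t * 2), c(e, e), rep(c("a", "b"), each = 6))
  flip2 <- logrankTest(c(t, t * 2), c(e, e), rep(c("b", "a"), each = 6))
  expect_equal(flip1$chisq, flip2$chisq, tolerance = 1e-12)
  expect_error(logrankTest(t, rep(0, 6), rep(c("a", "b"), 3)),
               class = "petrad_no_events")
})

test_that("Cox fits are replication invariant and sign-consistent with
           the log-rank direction", {
  set.seed(13)
  n <- 60
  x <- rbinom(n, 1, 0.5)
  t <- rexp(n, 0.1 * exp(0.8 * x))
  e <- rep(1, n)
  # jitter kills ties so Efron/Breslow coincide and replication is exact
  t <- t + seq_len(n) * 1e-9
  f1 <- coxFit(t, e, x)
  f2 <- coxFit(rep(t, 2), rep(e, 2), rep(x, 2))
  # duplication introduces ties, so Efron handling shifts beta slightly
  expect_equal(f1$beta, f2$beta, tolerance = 0.05)
  expect_true(f1$ci_lower < f1$hr && f1$hr < f1$ci_upper)
  # sign of beta-hat agrees with the log-rank O-E direction
  lr <- survival::survdiff(survival::Surv(t, e) ~ x)
  expect_equal(sign(f1$beta), sign(lr$obs[2] - lr$exp[2]))
  expect_error(coxFit(t, rep(0, n), x), class = "petrad_no_events")
  expect_error(coxFit(t, e, rep(1, n)), class = "petrad_degenerate_split")
})

test_that("a known Weibull proportional-hazards effect is recovered", {
  set.seed(17)
  n <- 300
  x <- rbinom(n, 1, 0.5)
  u <- runif(n)
  t <- 5 * (-log(u) / exp(log(0.2) * x))^(1 / 1.3)
  e <- as.integer(t <= 20); t <- pmin(t, 20)
  f <- coxFit(t, e, x)
  expect_gt(f$hr, 0.12)
  expect_lt(f$hr, 0.32)
  expect_lt(f$ci_upper, 1)
})

test_that("dichotomized PFS analysis guards degenerate splits and is
           consistent under subgroup restriction", {
  cfg <- syntheticConfig(n_patients = 120, seed = 3)
  d <- generateOutcomesOnly(cfg)
  co <- d[, c("pfs_months", "event", "tps_group")]
  fv <- d$true_skewness
  res <- dichotomizedPfsAnalysis(co, fv, median(fv), favourable = "low")
  expect_equal(res$n_low + res$n_high, 120)
  expect_true(res$cox$hr > 0)
  expect_true(res$six_month_low >= 0 && res$six_month_low <= 1)
  # gamma_skew > 0: the low-skewness group should progress less
  expect_lt(res$cox$hr, 1)
  expect_error(dichotomizedPfsAnalysis(co, fv, min(fv) - 1),
               class = "petrad_degenerate_split")
  # subgroup run equals the full code path applied to the subset
  sub <- dichotomizedPfsAnalysis(co, fv, median(fv), subgroup = "TPS>=50")
  manual <- dichotomizedPfsAnalysis(co[co$tps_group == "TPS>=50", ],
                                    fv[co$tps_group == "TPS>=50"],
                                    median(fv))
  expect_equal(sub$cox$hr, manual$cox$hr, tolerance = 1e-12)
  expect_equal(sub$logrank$chisq, manual$logrank$chisq, tolerance = 1e-12)
})
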