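test_that("logistic fitting recovers symmetry, truth, and flags
           separation", {
  # symmetric two-point design with balanced classes: intercept 0
  X <- matrix(rep(c(-1, 1), 4), ncol = 1)
  y <- c(0, 1, 1, 0, 0, 1, 1, 0)
  f <- fitLogistic(X, y)
  expect_lt(abs(f$coef[1]), 1e-8)

  set.seed(8)
  n <- 2000
  x <- rnorm(n)
  eta <- -0.5 + 1.2 * x
  yy <- rbinom(n, 1, plogis(eta))
  f2 <- fitLogistic(matrix(x, ncol = 1), yy)
  expect_equal(unname(f2$coef[2]), 1.2, tolerance = 0.15)
  expect_equal(unname(f2$coef[1]), -0.5, tolerance = 0.15)
  expect_false(f2$separation)

  # perfectly separated toy data: flagged, finite penalized coefficients
  xs <- c(-2, -1.5, -1, 1, 1.5, 2)
  ys <- c(0, 0, 0, 1, 1, 1)
  f3 <- fitLogistic(matrix(xs, ncol = 1), ys)
  expect_true(f3$separation)
  expect_true(all(is.finite(f3$coef)))
  expect_error(fitLogistic(matrix(xs, ncol = 1), rep(1, 6)),
               class = "petrad_degenerate_labels")
})

test_that("ROC endpoints behave: perfect, reversed and tied scores", {
  r <- rocAuc(c(0.1, 0.2, 0.3, 0.4), c(0, 0, 1, 1))
  expect_equal(r$auc, 1.0)
  expect_equal(rocAuc(c(0.4, 0.3, 0.2, 0.1), c(0, 0, 1, 1))$auc, 0.0)
  expect_equal(rocAuc(rep(0.5, 10), rep(0:1, 5))$auc, 0.5)
  expect_error(rocAuc(1:4, rep(1, 4)), class = "petrad_degenerate_labels")
})

test_that("AUC equals brute-force pair counting and flips with labels", {
  set.seed(23)
  for (i in 1:15) {
    n <- sample(10:200, 1)
    scores <- round(runif(n), 2)   # induces ties
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) next
    expect_equal(rocAuc(scores, labels)$auc, oracleAuc(scores, labels),
                 tolerance = 1e-12)
  }
  # label-flip symmetry under tie-free scores
  set.seed(24)
  s <- sample(seq(0.01, 0.99, by = 0.01), 40)
  l <- rbinom(40, 1, 0.5)
  if (length(unique(l)) == 2)
    expect_equal(rocAuc(s, l)$auc, 1 - rocAuc(s, 1 - l)$auc,
                 tolerance = 1e-12)
})

test_that("the Youden cutpoint matches the exhaustive scan with its
           tie-breaks", {
  r <- rocAuc(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))
  expect_equal(r$youden_J, 1)
  expect_equal(r$youden_threshold, 0.8)  # >= rule, lower threshold wins
  expect_equal(rocAuc(rep(0.3, 8), rep(0:1, 4))$youden_J, 0)
  set.seed(29)
  for (i in 1:15) {
    n <- sample(8:60, 1)
    scores <- round(runif(n), 1)
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    got <- rocAuc(scores, labels)
    want <- oracleYouden(scores, labels)
    expect_equal(got$youden_threshold, want$threshold)
    expect_equal(got$youden_J, want$J, tolerance = 1e-12)
  }
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(5)
  scores <- rnorm(80)
  labels <- rbinom(80, 1, plogis(scores))
  ours <- rocAuc(scores, labels)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-9)
})

test_that("signature evaluation reports feature-scale thresholds and a
           null cohort stays near chance", {
  set.seed(61)
  n <- 200
  X <- matrix(runif(2 * n), ncol = 2,
              dimnames = list(NULL, c("informative", "noise")))
  y <- rbinom(n, 1, plogis(-2 + 4 * X[, "informative"]))
  tr <- 1:140; te <- 141:200
  ev <- evaluateSignature(X[tr, ], X[te, ], y[tr], y[te],
                          signature = c("informative", "noise"))
  pf <- ev$per_feature
  expect_gt(pf$auc[pf$feature == "informative"], 0.65)
  expect_true(pf$threshold[pf$feature == "informative"] >= 0 &&
              pf$threshold[pf$feature == "informative"] <= 1)
  expect_equal(pf$direction[pf$feature == "informative"], "adverse-above")
  # null band: with no signal the test AUC hovers near 0.5
  y0 <- rbinom(n, 1, 0.4)
  ev0 <- evaluateSignature(X[tr, ], X[te, ], y0[tr], y0[te],
                           signature = "noise")
  expect_gt(ev0$per_feature$auc[1], 0.30)
  expect_lt(ev0$per_feature$auc[1], 0.70)
})
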