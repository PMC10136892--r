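test_that("normalization composes z-scoring with min-max onto [0, 1] and
           reapplies (not refits) on new data", {
  m <- cbind(a = c(2, 4, 6), b = c(1, 1, 2), flat = c(3, 3, 3))
  expect_warning(out <- normalizeFeatures(m), "constant")
  expect_equal(unname(out$table[, "a"]), c(0, 0.5, 1))
  expect_false("flat" %in% colnames(out$table))
  expect_true(all(apply(out$table, 2, min) == 0))
  expect_true(all(apply(out$table, 2, max) == 1))
  # reapplication uses the training parameters: an out-of-range test value
  # lands outside [0, 1] rather than being rescaled
  test <- cbind(a = c(8), b = c(1.5), flat = c(9))
  mapped <- applyNormalization(test, out$params)
  expect_equal(unname(mapped[, "a"]), 1.5)
  expect_error(normalizeFeatures(cbind(x = c(1, 1))),
               class = "petrad_empty_feature_space")
})

test_that("the stratified split reproduces the 33/11 -> 31/13 arithmetic
           and is seed-deterministic", {
  co <- data.frame(patient_id = sprintf("P%03d", 1:44),
                   responder = rep(c(1L, 0L), c(33, 11)))
  sp <- splitCohort(co, ratio = 0.7, seed = 9)
  expect_length(sp$train, 31)  # round(.7*33) + round(.7*11) = 23 + 8
  expect_length(sp$test, 13)
  expect_equal(sum(co$responder[co$patient_id %in% sp$train]), 23)
  expect_setequal(c(sp$train, sp$test), co$patient_id)
  expect_identical(splitCohort(co, ratio = 0.7, seed = 9), sp)
  expect_false(identical(splitCohort(co, ratio = 0.7, seed = 10)$train,
                         sp$train))
  expect_error(splitCohort(co, ratio = 1.0, seed = 1),
               class = "petrad_unsupported_parameter")
  co1 <- data.frame(patient_id = c("A", "B", "C"),
                    responder = c(1L, 1L, 0L))
  expect_error(splitCohort(co1, seed = 1),
               class = "petrad_unsplittable_stratum")
})

test_that("Boruta rejects pure noise, confirms a strong feature, and
           keeps duplicated informative columns (all-relevant)", {
  set.seed(15)
  n <- 200
  y <- rep(0:1, each = n / 2)
  noise <- matrix(rnorm(n * 10), n, 10,
                  dimnames = list(NULL, paste0("noise", 1:10)))
  X <- cbind(signal = y * 1.5 + rnorm(n), noise)
  res <- borutaSelect(X, y, n_trees = 300L, max_iter = 50L, seed = 21)
  expect_true("signal" %in% res$final)
  expect_lt(length(intersect(res$final, colnames(noise))), 3)

  X2 <- cbind(X[, c("signal", "noise1", "noise2", "noise3")],
              twin = X[, "signal"])
  res2 <- borutaSelect(X2, y, n_trees = 300L, max_iter = 50L, seed = 22)
  expect_true(all(c("signal", "twin") %in% res2$final))

  expect_error(borutaSelect(X, rep(1, n), seed = 1),
               class = "petrad_degenerate_labels")
  expect_error(borutaSelect(X[1:5, ], c(0, 1, 0, 1, 0), seed = 1),
               class = "petrad_unsupported_parameter")
})

test_that("correlation pruning follows the importance/tie-break rule and
           matches the greedy oracle on random instances", {
  set.seed(31)
  base <- rnorm(60)
  X <- cbind(a = base, b = base * 0.999 + rnorm(60, sd = 0.01),
             c = rnorm(60))
  imp <- c(a = 5, b = 3, c = 1)
  kept <- correlationPrune(X, c("a", "b", "c"), imp, r_max = 0.8)
  expect_true("a" %in% kept)
  expect_false("b" %in% kept)
  expect_true("c" %in% kept)
  # everything weakly correlated: no-op
  X3 <- matrix(rnorm(60 * 4), 60, 4, dimnames = list(NULL, letters[1:4]))
  expect_setequal(correlationPrune(X3, letters[1:4],
                                   setNames(4:1, letters[1:4]), 0.8),
                  letters[1:4])
  # exhaustive comparison against the independent greedy oracle
  for (seed in 1:10) {
    set.seed(seed)
    p <- 6
    M <- matrix(rnorm(40 * p), 40, p)
    M[, 2] <- M[, 1] + rnorm(40, sd = 0.1)
    M[, 4] <- M[, 3] * -1 + rnorm(40, sd = 0.2)
    colnames(M) <- paste0("v", 1:p)
    imp <- setNames(runif(p), colnames(M))
    expect_identical(
      correlationPrune(M, colnames(M), imp, 0.7),
      oracleGreedyPrune(M, colnames(M), imp, 0.7))
  }
})
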