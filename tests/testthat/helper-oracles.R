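# Independent brute-force oracles used to cross-check the implementation.
# These deliberately use naive loops / closed forms and never call the
# package code paths they verify.

# population-moment first-order statistics from a value vector
oracleFirstOrder <- function(v) {
  n <- length(v)
  mu <- sum(v) / n
  m2 <- sum((v - mu)^2) / n
  m3 <- sum((v - mu)^3) / n
  list(mean = mu,
       median = stats::median(v),
       skewness = m3 / m2^1.5,
       variance = m2)
}

# directed-pair enumeration GLCM (triple loop), symmetrized + normalized
oracleGlcm <- function(lev, mask, offset, n_levels) {
  d <- dim(mask)
  M <- matrix(0, n_levels, n_levels)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    if (!mask[x, y, z]) next
    xx <- x + offset[1]; yy <- y + offset[2]; zz <- z + offset[3]
    if (xx < 1 || xx > d[1] || yy < 1 || yy > d[2] || zz < 1 || zz > d[3])
      next
    if (!mask[xx, yy, zz]) next
    i <- lev[x, y, z]; j <- lev[xx, yy, zz]
    M[i, j] <- M[i, j] + 1
    M[j, i] <- M[j, i] + 1
  }
  if (sum(M) == 0) return(NULL)
  M / sum(M)
}

# Mann-Whitney AUC by explicit pair counting (ties count 1/2)
oracleAuc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# exhaustive Youden scan over unique scores with the >= decision rule
oracleYouden <- function(scores, labels) {
  thr <- sort(unique(scores), decreasing = TRUE)
  best <- NULL
  for (t in thr) {
    sens <- mean(scores[labels == 1] >= t)
    spec <- mean(scores[labels == 0] < t)
    J <- sens + spec - 1
    if (is.null(best) || J > best$J + 1e-12 ||
        (abs(J - best$J) <= 1e-12 &&
         (sens > best$sens || (sens == best$sens && t < best$threshold))))
      best <- list(threshold = t, J = J, sens = sens)
  }
  best
}

# greedy correlation pruning, written independently with explicit loops
oracleGreedyPrune <- function(X, confirmed, importance, r_max) {
  ord <- confirmed[order(-importance[confirmed], confirmed)]
  kept <- character(0)
  for (f in ord) {
    blocked <- FALSE
    for (g in kept)
      if (abs(stats::cor(X[, f], X[, g])) >= r_max) blocked <- TRUE
    if (!blocked) kept <- c(kept, f)
  }
  kept
}

diceCoefficient <- function(m1, m2) {
  a <- maskArray(m1); b <- maskArray(m2)
  2 * sum(a & b) / (sum(a) + sum(b))
}
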