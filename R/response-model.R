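#' Logistic regression with a ridge fallback for separation
#'
#' Maximum-likelihood fit via iteratively reweighted least squares
#' (`stats::glm`). If the fit does not converge or shows complete
#' separation (fitted probabilities collapsing to 0/1), a ridge-penalized
#' IRLS refit is used with escalating penalty until stable, and the
#' `separation` flag is raised.
#'
#' @param X numeric matrix (n x p) of predictors.
#' @param y binary 0/1 outcome.
#' @return list with `coef` (intercept first), `converged`, `separation`,
#'   `log_likelihood`, `n_iterations`.
#' @export
fitLogistic <- function(X, y) {
  X <- as.matrix(X)
  if (length(unique(y)) < 2L)
    petradStop("petrad_degenerate_labels", "y must contain both classes")
  if (nrow(X) < ncol(X) + 2L)
    petradStop("petrad_unsupported_parameter", "need n >= p + 2 samples")
  df <- data.frame(y = y, X)
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ ., data = df, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities|did not converge", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (!sep && fit$converged) {
    eta <- stats::predict(fit)
    ll <- sum(y * eta - log1p(exp(eta)))
    return(list(coef = stats::coef(fit), converged = TRUE,
                separation = FALSE, log_likelihood = ll,
                n_iterations = fit$iter))
  }
  # ridge IRLS (intercept unpenalized), escalating lambda until finite/stable
  Z <- cbind(`(Intercept)` = 1, X)
  lambda <- 1e-6
  repeat {
    b <- rep(0, ncol(Z))
    ok <- TRUE
    for (i in 1:100) {
      eta <- drop(Z %*% b)
      mu <- stats::plogis(eta)
      w <- pmax(mu * (1 - mu), 1e-10)
      pen <- diag(c(0, rep(lambda, ncol(Z) - 1L)))
      H <- crossprod(Z, Z * w) + pen
      g <- crossprod(Z, y - mu) - pen %*% b
      step <- tryCatch(solve(H, g), error = function(e) NULL)
      if (is.null(step)) { ok <- FALSE; break }
      b_new <- b + drop(step)
      if (any(!is.finite(b_new)) || max(abs(b_new)) > 1e4) { ok <- FALSE; break }
      done <- max(abs(b_new - b)) < 1e-8
      b <- b_new
      if (done) break
    }
    if (ok && all(is.finite(b))) break
    lambda <- lambda * 100
    if (lambda > 1e3)
      petradStop("petrad_unsupported_parameter",
                 "logistic fit failed even under heavy ridge penalty")
  }
  eta <- drop(Z %*% b)
  names(b) <- colnames(Z)
  list(coef = b, converged = TRUE, separation = TRUE,
       log_likelihood = sum(y * eta - log1p(exp(eta))),
       n_iterations = NA_integer_, ridge_lambda = lambda)
}

#' @rdname fitLogistic
#' @param fit result of [fitLogistic()].
#' @param newX matrix of predictors.
#' @return `predictLogistic`: predicted probabilities.
#' @export
predictLogistic <- function(fit, newX) {
  Z <- cbind(1, as.matrix(newX))
  stats::plogis(drop(Z %*% fit$coef))
}

#' ROC curve, AUC and Youden threshold
#'
#' The AUC is the rank-based (Mann-Whitney) estimator with tie correction;
#' the curve is evaluated at every unique score with the closed decision
#' rule score >= threshold => positive.
#'
#' @param scores numeric risk scores (higher = more likely positive).
#' @param labels binary 0/1; 1 is the positive class.
#' @return list with `auc`, `thresholds`, `sensitivity`, `specificity`,
#'   `youden_threshold`, `youden_J`, `sens_at_youden`, `spec_at_youden`.
#' @export
rocAuc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  if (length(unique(labels)) < 2L)
    petradStop("petrad_degenerate_labels", "need both classes for a ROC")
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- sort(unique(scores), decreasing = TRUE)
  sens <- vapply(thr, function(t) mean(scores[labels == 1] >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(scores[labels == 0] < t), numeric(1))
  J <- sens + spec - 1
  best_J <- max(J)
  cand <- which(J >= best_J - 1e-12)
  cand <- cand[order(-sens[cand], thr[cand])]   # higher sens, then lower thr
  best <- cand[1]
  list(auc = auc, thresholds = thr, sensitivity = sens, specificity = spec,
       youden_threshold = thr[best], youden_J = J[best],
       sens_at_youden = sens[best], spec_at_youden = spec[best])
}

#' @rdname rocAuc
#' @param roc a result of [rocAuc()].
#' @return `youdenThreshold`: list with `threshold` and `J`.
#' @export
youdenThreshold <- function(roc) {
  list(threshold = roc$youden_threshold, J = roc$youden_J)
}

#' Evaluate a radiomic signature for a binary target
#'
#' Fits per-feature univariate logistic models on the training rows
#' (the primary reported objects) plus one multivariate model on the full
#' signature, and evaluates all of them on the held-out test rows. The
#' positive class is the adverse outcome (non-responder / progression), so
#' a higher oriented score means a worse expected outcome. Per-feature
#' Youden cutpoints are mapped back through the monotone logistic link onto
#' the normalized feature scale, with the comparison direction recorded.
#'
#' @param X_train,X_test normalized feature matrices with the signature
#'   columns.
#' @param y_train,y_test binary adverse-outcome indicator (1 = adverse).
#' @param signature character vector of feature names; these feed the
#'   multivariate model and are evaluated per feature.
#' @param extra_features additional feature names evaluated per feature
#'   only (not part of the multivariate signature model).
#' @return list with `per_feature` (data.frame: feature, auc, youden_J,
#'   threshold in feature units, direction, sens, spec, coefficient) and
#'   `multivariate` (auc, J, threshold on the probability scale, coef;
#'   `NULL` when the signature is empty).
#' @export
evaluateSignature <- function(X_train, X_test, y_train, y_test, signature,
                              extra_features = character(0)) {
  eval_set <- unique(c(signature, extra_features))
  stopifnot(all(eval_set %in% colnames(X_train)), length(eval_set) > 0L)
  rows <- lapply(eval_set, function(f) {
    fit <- fitLogistic(X_train[, f, drop = FALSE], y_train)
    sc <- predictLogistic(fit, X_test[, f, drop = FALSE])
    roc <- rocAuc(sc, y_test)
    beta <- unname(fit$coef[2])
    # invert p >= t through the logistic link onto the feature scale
    t_prob <- roc$youden_threshold
    t_feat <- (stats::qlogis(pmin(pmax(t_prob, 1e-12), 1 - 1e-12)) -
                 fit$coef[1]) / beta
    data.frame(feature = f, auc = roc$auc, youden_J = roc$youden_J,
               threshold = unname(t_feat),
               direction = if (beta >= 0) "adverse-above" else "adverse-below",
               sensitivity = roc$sens_at_youden,
               specificity = roc$spec_at_youden,
               coefficient = beta, stringsAsFactors = FALSE)
  })
  per_feature <- do.call(rbind, rows)
  per_feature$in_signature <- per_feature$feature %in% signature
  multivariate <- NULL
  if (length(signature) > 0L) {
    multi_fit <- fitLogistic(X_train[, signature, drop = FALSE], y_train)
    multi_sc <- predictLogistic(multi_fit, X_test[, signature, drop = FALSE])
    multi_roc <- rocAuc(multi_sc, y_test)
    multivariate <- list(auc = multi_roc$auc, youden_J = multi_roc$youden_J,
                         threshold = multi_roc$youden_threshold,
                         coef = multi_fit$coef,
                         separation = multi_fit$separation)
  }
  list(per_feature = per_feature, multivariate = multivariate)
}
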