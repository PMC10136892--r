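#' Normalize features to [0, 1]
#'
#' Per feature: z-score standardize, then min-max rescale to `[0, 1]`.
#' Constant features are dropped with a warning. The fitted scaling
#' parameters are returned so they can be re-applied (not refit) to test
#' data with [applyNormalization()]; test values may therefore fall
#' slightly outside `[0, 1]`.
#'
#' @param table numeric matrix (patients x features), training rows only.
#' @return list with `table` (normalized), `params` (per-feature center,
#'   scale, min, max on the z scale) and `dropped` feature names.
#' @export
normalizeFeatures <- function(table) {
  stopifnot(nrow(table) >= 2L)
  mu <- colMeans(table)
  sdv <- apply(table, 2, stats::sd)
  keep <- is.finite(sdv) & sdv > 0
  if (!any(keep))
    petradStop("petrad_empty_feature_space", "all features are constant")
  if (any(!keep))
    warning(sprintf("dropping %d constant feature(s): %s", sum(!keep),
                    paste(utils::head(colnames(table)[!keep], 5),
                          collapse = ", ")))
  z <- sweep(sweep(table[, keep, drop = FALSE], 2, mu[keep]), 2,
             sdv[keep], `/`)
  zmin <- apply(z, 2, min)
  zmax <- apply(z, 2, max)
  out <- sweep(sweep(z, 2, zmin), 2, zmax - zmin, `/`)
  list(table = out,
       params = list(center = mu[keep], scale = sdv[keep],
                     zmin = zmin, zmax = zmax),
       dropped = colnames(table)[!keep])
}

#' @rdname normalizeFeatures
#' @param params the `params` element returned by [normalizeFeatures()].
#' @export
applyNormalization <- function(table, params) {
  nms <- names(params$center)
  z <- sweep(sweep(table[, nms, drop = FALSE], 2, params$center), 2,
             params$scale, `/`)
  sweep(sweep(z, 2, params$zmin), 2, params$zmax - params$zmin, `/`)
}

#' Outcome-stratified train/test split
#'
#' Shuffles within each outcome stratum (seeded) and cuts
#' `round(ratio * n_stratum)` members into the training set, so the class
#' balance is preserved ("balanced" split).
#'
#' @param cohort data.frame with `patient_id` and the stratification label.
#' @param ratio training fraction (default 0.7).
#' @param seed integer RNG seed.
#' @param stratify_by column name with the binary outcome label.
#' @return list with `train` and `test` patient-id vectors, plus the plan
#'   metadata.
#' @export
splitCohort <- function(cohort, ratio = 0.7, seed = 1L,
                        stratify_by = "responder") {
  if (ratio <= 0 || ratio >= 1)
    petradStop("petrad_unsupported_parameter", "ratio must be in (0, 1)")
  lab <- cohort[[stratify_by]]
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  train <- character(0)
  for (g in sort(unique(lab))) {
    ids <- cohort$patient_id[lab == g]
    if (length(ids) < 2L)
      petradStop("petrad_unsplittable_stratum",
                 sprintf("stratum '%s' has fewer than 2 members", g))
    ids <- sample(ids)
    n_tr <- round(ratio * length(ids))
    n_tr <- min(max(n_tr, 1L), length(ids) - 1L)
    train <- c(train, ids[seq_len(n_tr)])
  }
  test <- setdiff(cohort$patient_id, train)
  if (length(test) == 0L)
    petradStop("petrad_unsupported_parameter", "empty test set")
  list(train = sort(train), test = sort(test), ratio = ratio,
       stratify_by = stratify_by, seed = seed)
}

#' Boruta all-relevant feature selection
#'
#' At each iteration the design matrix is augmented with "shadow" features
#' (independently permuted copies of every not-yet-rejected feature), a
#' random-forest classifier is fitted (impurity importance via `ranger`),
#' and each undecided feature scores a "hit" when its importance exceeds
#' the maximum shadow importance. Two-sided binomial tests at level
#' `alpha`, Bonferroni-corrected across the undecided features, confirm
#' (significantly many hits) or reject (significantly few). Features still
#' undecided at `max_iter` are tentative and are resolved by comparing
#' their median importance history against the median of the max-shadow
#' history.
#'
#' @param X numeric matrix (training patients x features), normalized.
#' @param y binary outcome vector (0/1) of length `nrow(X)`.
#' @param n_trees random-forest size per iteration.
#' @param max_iter maximum Boruta iterations.
#' @param alpha significance level of the binomial decisions.
#' @param seed integer seed; iteration i uses `seed + i`.
#' @return list with `decision` (named factor confirmed/tentative/rejected,
#'   tentatives shown as resolved in `final`), `final` (confirmed feature
#'   names), `hits`, `iterations`, `median_importance`, and the parameters.
#' @export
borutaSelect <- function(X, y, n_trees = 500L, max_iter = 100L,
                         alpha = 0.01, seed = 1L) {
  stopifnot(nrow(X) == length(y), ncol(X) >= 1L)
  if (length(unique(y)) < 2L)
    petradStop("petrad_degenerate_labels", "y must contain both classes")
  if (nrow(X) < 8L)
    petradStop("petrad_unsupported_parameter", "need >= 8 training samples")
  p <- ncol(X)
  feat <- colnames(X)
  if (is.null(feat)) feat <- colnames(X) <- sprintf("f%03d", seq_len(p))
  status <- rep("undecided", p)
  names(status) <- feat
  hits <- stats::setNames(integer(p), feat)
  imp_hist <- matrix(NA_real_, max_iter, p, dimnames = list(NULL, feat))
  shadow_max_hist <- rep(NA_real_, max_iter)
  yf <- factor(y)
  it <- 0L
  while (any(status == "undecided") && it < max_iter) {
    it <- it + 1L
    active <- status != "rejected"
    Xa <- X[, active, drop = FALSE]
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    set.seed(seed + it)
    # shadows are fresh permutations of ALL original features, not just the
    # still-active ones: shrinking the shadow set lowers the max-shadow bar
    # late in the run and lets chance-correlated noise sneak past it
    sh <- apply(X, 2, sample)
    colnames(sh) <- paste0(".shadow.", colnames(X))
    df <- as.data.frame(cbind(Xa, sh))
    df$.y <- yf
    fit <- ranger::ranger(dependent.variable.name = ".y", data = df,
                          num.trees = n_trees, importance = "impurity",
                          seed = seed + it, num.threads = 1L,
                          respect.unordered.factors = TRUE)
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
    imp <- fit$variable.importance
    shadow_max <- max(imp[startsWith(names(imp), ".shadow.")])
    shadow_max_hist[it] <- shadow_max
    real_imp <- imp[colnames(Xa)]
    imp_hist[it, colnames(Xa)] <- real_imp
    und <- names(status)[status == "undecided"]
    hits[und] <- hits[und] + as.integer(real_imp[und] > shadow_max)
    m <- length(und)
    for (f in und) {
      p_hi <- stats::pbinom(hits[f] - 1L, it, 0.5, lower.tail = FALSE)
      p_lo <- stats::pbinom(hits[f], it, 0.5)
      if (p_hi <= alpha / (2 * m)) status[f] <- "confirmed"
      else if (p_lo <= alpha / (2 * m)) status[f] <- "rejected"
    }
  }
  med_imp <- apply(imp_hist[seq_len(it), , drop = FALSE], 2,
                   stats::median, na.rm = TRUE)
  med_shadow <- stats::median(shadow_max_hist[seq_len(it)], na.rm = TRUE)
  decision <- status
  decision[status == "undecided"] <- "tentative"
  resolved <- decision
  tent <- names(decision)[decision == "tentative"]
  resolved[tent] <- ifelse(!is.na(med_imp[tent]) & med_imp[tent] >= med_shadow,
                           "confirmed", "rejected")
  list(decision = factor(decision, c("confirmed", "tentative", "rejected")),
       final = names(resolved)[resolved == "confirmed"],
       hits = hits, iterations = it,
       median_importance = med_imp, median_shadow = med_shadow,
       params = list(n_trees = n_trees, max_iter = max_iter,
                     alpha = alpha, seed = seed))
}

#' Correlation pruning of a confirmed feature set
#'
#' Orders confirmed features by Boruta median importance (descending, name
#' ascending on ties) and greedily keeps a feature only if its absolute
#' Pearson correlation with every already-kept feature is below `r_max`.
#'
#' @param X numeric matrix with at least the confirmed feature columns.
#' @param confirmed character vector of confirmed feature names.
#' @param importance named numeric vector (e.g. `median_importance` from
#'   [borutaSelect()]).
#' @param r_max correlation threshold (default 0.8).
#' @return character vector: the final signature, in selection order.
#' @export
correlationPrune <- function(X, confirmed, importance, r_max = 0.8) {
  if (length(confirmed) == 0L)
    petradStop("petrad_empty_feature_space", "no confirmed features to prune")
  ord <- confirmed[order(-importance[confirmed], confirmed)]
  kept <- character(0)
  for (f in ord) {
    ok <- TRUE
    for (g in kept) {
      r <- stats::cor(X[, f], X[, g])
      if (is.finite(r) && abs(r) >= r_max) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, f)
  }
  kept
}
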