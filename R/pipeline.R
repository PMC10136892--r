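#' Map RECIST categories to the responder flag
#'
#' Disease control (CR, PR or SD at the second follow-up) counts as
#' response; progressive disease (PD) is non-response.
#'
#' @param recist_category character vector with values in CR/PR/SD/PD.
#' @return integer vector: 1 = responder, 0 = non-responder.
#' @examples
#' classifyResponse(c("CR", "PR", "SD", "PD")) # 1 1 1 0
#' @export
classifyResponse <- function(recist_category) {
  ok <- recist_category %in% c("CR", "PR", "SD", "PD")
  if (!all(ok))
    petradStop("petrad_invalid_category",
               sprintf("unknown RECIST category: %s",
                       paste(unique(recist_category[!ok]), collapse = ", ")))
  as.integer(recist_category != "PD")
}

#' Run the full radiomics analysis pipeline
#'
#' simulate -> segment -> extract -> reliability filter -> normalize/split
#' -> Boruta -> correlation pruning -> logistic/ROC/Youden -> PFS analyses,
#' executed for both endpoints (response at second follow-up and overall
#' progression). The whole run is reproducible from `config$seed`.
#'
#' @param config a `SyntheticConfig` from [syntheticConfig()] (or a list of
#'   pre-generated `patients` + `cohort` in `cohort_data`).
#' @param cohort_data optional output of [generateCohort()] to reuse.
#' @param targets which endpoints to analyse.
#' @param ratio train fraction of the stratified split.
#' @param ccc_cutoff Lin-CCC reliability cutoff.
#' @param alpha,n_trees,max_iter Boruta parameters.
#' @param r_max correlation-pruning threshold.
#' @param bin_count grey levels for feature discretization.
#' @param report_features named features that are always evaluated and
#'   carried through the survival analyses (in addition to the selected
#'   signature), mirroring per-feature reporting of the headline features;
#'   silently skipped when a name did not survive the reliability filter.
#' @return a `RunReport` list: config echo, stage record counts, CCC
#'   report, per-target selection + model + survival results.
#' @export
runPipeline <- function(config, cohort_data = NULL,
                        targets = c("response", "progression"),
                        ratio = 0.7, ccc_cutoff = 0.8, alpha = 0.01,
                        n_trees = 500L, max_iter = 100L, r_max = 0.8,
                        bin_count = 64L,
                        report_features = c("PET-Skewness", "PET-Median")) {
  targets <- match.arg(targets, several.ok = TRUE)
  if (is.null(cohort_data)) cohort_data <- generateCohort(config)
  patients <- cohort_data$patients
  cohort <- cohort_data$cohort
  # consistency of the stored responder flag with the RECIST rule
  stopifnot(identical(cohort$responder, classifyResponse(cohort$recist)))

  feats <- extractCohortFeatures(patients, bin_count = bin_count)
  rel <- reliabilityFilter(feats$reader1, feats$reader2, cutoff = ccc_cutoff)
  merged <- rel$merged

  per_target <- list()
  for (tg in targets) {
    adverse <- if (tg == "response") 1L - cohort$responder else
      cohort$overall_progression
    strat_col <- if (tg == "response") "responder" else "overall_progression"
    split <- splitCohort(cohort, ratio = ratio, seed = config$seed,
                         stratify_by = strat_col)
    tr <- match(split$train, cohort$patient_id)
    te <- match(split$test, cohort$patient_id)
    norm <- normalizeFeatures(merged[tr, , drop = FALSE])
    X_tr <- norm$table
    X_te <- applyNormalization(merged[te, , drop = FALSE], norm$params)
    X_all <- applyNormalization(merged, norm$params)
    bor <- borutaSelect(X_tr, adverse[tr], n_trees = n_trees,
                        max_iter = max_iter, alpha = alpha,
                        seed = config$seed + if (tg == "response") 1000L else 2000L)
    sig <- if (length(bor$final) == 0L) character(0) else
      correlationPrune(X_tr, bor$final, bor$median_importance, r_max = r_max)
    extra <- intersect(report_features, colnames(X_tr))
    if (length(sig) == 0L && length(extra) == 0L) {
      per_target[[tg]] <- list(split = split, boruta = bor,
                               signature = sig,
                               note = "no feature confirmed or reportable")
      next
    }
    ev <- evaluateSignature(X_tr, X_te, adverse[tr], adverse[te], sig,
                            extra_features = extra)
    surv <- list()
    for (i in seq_len(nrow(ev$per_feature))) {
      f <- ev$per_feature$feature[i]
      thr <- ev$per_feature$threshold[i]
      fav <- if (ev$per_feature$direction[i] == "adverse-above") "low" else "high"
      fv <- X_all[, f]
      runs <- list()
      for (sg in c(list(NULL), as.list(sort(unique(cohort$tps_group))))) {
        key <- if (is.null(sg)) "all" else sg
        runs[[key]] <- tryCatch(
          dichotomizedPfsAnalysis(cohort, fv, thr, subgroup = sg,
                                  favourable = fav),
          petrad_error = function(e) list(skipped = conditionMessage(e)))
      }
      surv[[f]] <- runs
    }
    per_target[[tg]] <- list(split = split, boruta = bor, signature = sig,
                             evaluation = ev, survival = surv,
                             normalization = norm$params,
                             feature_values_all =
                               X_all[, ev$per_feature$feature, drop = FALSE])
  }

  # TPS prognostic analysis: Cox per TPS level against the TPS<1 reference
  tps_cox <- list()
  for (lev in c("TPS>=50", "TPS1-49")) {
    sel <- cohort$tps_group %in% c(lev, "TPS<1")
    tps_cox[[lev]] <- tryCatch(
      coxFit(cohort$pfs_months[sel], cohort$event[sel],
             as.integer(cohort$tps_group[sel] == lev)),
      petrad_error = function(e) list(skipped = conditionMessage(e)))
  }

  km_all <- kmEstimate(cohort$pfs_months, cohort$event)
  structure(list(
    config = config,
    cohort = cohort,
    counts = list(n_patients = nrow(cohort),
                  n_responders = sum(cohort$responder),
                  n_non_responders = sum(1 - cohort$responder),
                  n_progression = sum(cohort$overall_progression),
                  n_features_extracted = ncol(feats$reader1),
                  n_features_reliable = ncol(merged),
                  tps_table = table(cohort$tps_group)),
    segmentation = list(threshold_suv = feats$threshold_suv,
                        mtv_ml = feats$mtv_ml),
    ccc_report = rel$report,
    targets = per_target,
    tps_cox = tps_cox,
    km_overall = km_all,
    median_pfs_months = kmMedian(km_all),
    seed = config$seed,
    version = as.character(utils::packageVersion("petrad"))),
    class = "petradRunReport")
}

#' @export
print.petradRunReport <- function(x, ...) {
  cat("petrad pipeline run (seed", x$seed, ")\n")
  cat(sprintf("  patients: %d (%d responders / %d non-responders)\n",
              x$counts$n_patients, x$counts$n_responders,
              x$counts$n_non_responders))
  cat(sprintf("  features: %d extracted, %d reliable (CCC filter)\n",
              x$counts$n_features_extracted, x$counts$n_features_reliable))
  cat(sprintf("  median PFS: %.1f months\n", x$median_pfs_months))
  for (tg in names(x$targets)) {
    sig <- x$targets[[tg]]$signature
    cat(sprintf("  [%s] signature: %s\n", tg,
                if (length(sig)) paste(sig, collapse = ", ") else "(none)"))
    ev <- x$targets[[tg]]$evaluation
    if (!is.null(ev))
      for (i in seq_len(nrow(ev$per_feature)))
        cat(sprintf("    %s: AUC %.3f, Youden threshold %.4f (%s)\n",
                    ev$per_feature$feature[i], ev$per_feature$auc[i],
                    ev$per_feature$threshold[i],
                    ev$per_feature$direction[i]))
  }
  invisible(x)
}
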