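#' Kaplan-Meier product-limit estimate
#'
#' Thin wrapper around [survival::survfit()] exposing the curve as plain
#' vectors; censored subjects leave the risk set after their time.
#'
#' @param times follow-up times in months (>= 0).
#' @param events 1 = progression/death observed, 0 = censored.
#' @return list with `time`, `surv`, `n_risk`, `n_event`, `n_censor`.
#' @export
kmEstimate <- function(times, events) {
  if (any(times < 0))
    petradStop("petrad_invalid_time", "negative follow-up time")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  list(time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
       n_event = fit$n.event, n_censor = fit$n.censor)
}

#' Survival probability at a time point
#'
#' Right-continuous step-function lookup on a Kaplan-Meier curve: at an
#' event time the post-jump value is returned; beyond the last observed
#' time the last value is carried forward.
#'
#' @param curve result of [kmEstimate()].
#' @param t time in months (>= 0).
#' @return survival probability in `[0, 1]`.
#' @export
survivalAt <- function(curve, t) {
  stopifnot(t >= 0)
  idx <- which(curve$time <= t)
  if (length(idx) == 0L) return(1)
  curve$surv[max(idx)]
}

#' Mantel-Cox log-rank test for two groups
#'
#' @param times,events follow-up and event indicators for all subjects.
#' @param group two-level grouping vector.
#' @return list with `chisq` (1 df), `p`.
#' @export
logrankTest <- function(times, events, group) {
  if (length(unique(group)) != 2L)
    petradStop("petrad_degenerate_split", "log-rank needs exactly two groups")
  if (sum(events) == 0L)
    petradStop("petrad_no_events", "no events in either group")
  sd <- survival::survdiff(survival::Surv(times, events) ~ group)
  chisq <- sd$chisq
  list(chisq = chisq, p = stats::pchisq(chisq, df = 1, lower.tail = FALSE))
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood fit via [survival::coxph()] with Efron handling of
#' tied event times and optional stratification. The Wald 95% CI is
#' `exp(beta +/- 1.96 se)`.
#'
#' @param times,events follow-up and event indicators.
#' @param covariate binary or continuous covariate.
#' @param strata optional stratification labels (per-stratum baseline
#'   hazards, per-stratum risk sets).
#' @return list with `beta`, `hr`, `ci_lower`, `ci_upper`, `se`, `p`
#'   (Wald), `n_events`, `converged`.
#' @export
coxFit <- function(times, events, covariate, strata = NULL) {
  if (sum(events) < 1L)
    petradStop("petrad_no_events", "need at least one event")
  if (length(unique(covariate)) < 2L)
    petradStop("petrad_degenerate_split", "covariate is constant")
  df <- data.frame(t = times, e = events, x = covariate)
  fml <- survival::Surv(t, e) ~ x
  if (!is.null(strata)) {
    df$s <- strata
    fml <- survival::Surv(t, e) ~ x + survival::strata(s)
  }
  converged <- TRUE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = df, ties = "efron"),
    warning = function(w) {
      if (grepl("infinite|converge|beta may be", conditionMessage(w)))
        converged <<- FALSE
      invokeRestart("muffleWarning")
    })
  beta <- unname(stats::coef(fit)[1])
  se <- sqrt(diag(fit$var))[1]
  if (!is.finite(beta) || abs(beta) > 15) converged <- FALSE
  list(beta = beta, hr = exp(beta),
       ci_lower = exp(beta - 1.96 * se), ci_upper = exp(beta + 1.96 * se),
       se = se, p = 2 * stats::pnorm(-abs(beta / se)),
       n_events = sum(events), converged = converged)
}

#' PFS analysis for a threshold-dichotomized feature
#'
#' Splits patients into low (<= threshold) and high (> threshold) groups on
#' the normalized feature scale, optionally restricted to one TPS subgroup,
#' and runs the Kaplan-Meier pair, the log-rank test, and a Cox fit with
#' the low group as the exposure (so HR < 1 means the low group progresses
#' less).
#'
#' @param cohort data.frame with `pfs_months`, `event` and `tps_group`.
#' @param feature_values numeric vector aligned with `cohort` rows.
#' @param threshold cutpoint on the feature scale (must be interior to the
#'   feature range).
#' @param subgroup optional TPS level to restrict to.
#' @param favourable which side of the threshold is the presumed low-risk
#'   group used as the Cox exposure: "low" (values <= threshold) or "high".
#' @return list with `km_low`, `km_high`, `logrank`, `cox`,
#'   `six_month_low`, `six_month_high`, `n_low`, `n_high`, `favourable`.
#' @export
dichotomizedPfsAnalysis <- function(cohort, feature_values, threshold,
                                    subgroup = NULL,
                                    favourable = c("low", "high")) {
  favourable <- match.arg(favourable)
  keep <- rep(TRUE, nrow(cohort))
  if (!is.null(subgroup)) keep <- cohort$tps_group == subgroup
  co <- cohort[keep, , drop = FALSE]
  fv <- feature_values[keep]
  low <- fv <= threshold
  if (!any(low) || all(low))
    petradStop("petrad_degenerate_split",
               "threshold leaves one group empty")
  km_low <- kmEstimate(co$pfs_months[low], co$event[low])
  km_high <- kmEstimate(co$pfs_months[!low], co$event[!low])
  lr <- logrankTest(co$pfs_months, co$event, ifelse(low, "low", "high"))
  expo <- if (favourable == "low") low else !low
  cx <- coxFit(co$pfs_months, co$event, as.integer(expo))
  list(km_low = km_low, km_high = km_high, logrank = lr, cox = cx,
       six_month_low = survivalAt(km_low, 6),
       six_month_high = survivalAt(km_high, 6),
       n_low = sum(low), n_high = sum(!low), favourable = favourable)
}

#' Median survival time from a Kaplan-Meier curve
#'
#' First time at which the survival estimate drops to 0.5 or below; `NA`
#' when the curve never reaches 0.5.
#'
#' @param curve result of [kmEstimate()].
#' @export
kmMedian <- function(curve) {
  idx <- which(curve$surv <= 0.5)
  if (length(idx) == 0L) return(NA_real_)
  curve$time[min(idx)]
}
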