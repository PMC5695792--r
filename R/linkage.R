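#' Correlation between predicted adherence and cholesterol lowering
#'
#' Pearson correlation between the predicted adherence probability and the
#' magnitude of cholesterol lowering (`-delta`, so positive r means higher
#' predicted adherence goes with more lowering), per analyte, on patients
#' with both a baseline and a follow-up value. The correlation with the raw
#' delta is also reported.
#'
#' @param predictedAdherence named numeric vector (names = patient ids).
#' @param lipids output of [lipidChange()].
#' @return data.table: `analyte`, `n`, `r`, `pValue`, `rRawDelta`. Analytes
#'   with fewer than 3 complete pairs get `NA`s.
#' @export
lipidCorrelation <- function(predictedAdherence, lipids) {
  lp <- as.data.table(lipids)
  stopifnot(!is.null(names(predictedAdherence)))
  rows <- lapply(unique(lp$analyte), function(an) {
    x <- lp[analyte == an]
    adh <- predictedAdherence[x$patientId]
    ok <- !is.na(adh) & !is.na(x$delta)
    n <- sum(ok)
    if (n < 3)
      return(data.table(analyte = an, n = n, r = NA_real_,
                        pValue = NA_real_, rRawDelta = NA_real_))
    ct <- cor.test(adh[ok], -x$delta[ok], method = "pearson")
    data.table(analyte = an, n = n, r = unname(ct$estimate),
               pValue = ct$p.value, rRawDelta = -unname(ct$estimate))
  })
  rbindlist(rows)
}

#' Cox proportional-hazards linkage of predicted adherence to events
#'
#' Per diagnosis group (and the composite), fits
#' `Surv(time, event) ~ predictedAdherence + predictedRisk + covariates`
#' and reports the hazard ratio per unit predicted adherence (the
#' out-of-fold probability on its natural 0-1 scale) and per unit
#' predicted disease risk, with Wald p-values. Groups with no events are
#' skipped with a message.
#'
#' @param predictedAdherence named numeric vector (names = patient ids).
#' @param eventOutcome long table from [eventOutcomes()].
#' @param covariates data.frame of patient/statin covariates aligned with
#'   `predictedAdherence` (missing numerics are median-imputed with
#'   indicators); may be `NULL` for an unadjusted fit.
#' @param diseaseRisk per-patient composite risk, aligned; `NULL` to omit.
#' @return data.table: `group`, `n`, `nEvents`, `hrAdherence`,
#'   `ciLowAdherence`, `ciHighAdherence`, `pAdherence`, `hrRisk`, `pRisk`.
#' @export
coxLinkage <- function(predictedAdherence, eventOutcome, covariates = NULL,
                       diseaseRisk = NULL) {
  ev <- as.data.table(eventOutcome)
  ids <- names(predictedAdherence)
  stopifnot(!is.null(ids))
  base <- data.frame(.adh = as.numeric(predictedAdherence))
  if (!is.null(diseaseRisk)) base$.risk <- as.numeric(diseaseRisk)
  if (!is.null(covariates)) {
    covs <- imputeByTrainingMedian(as.data.frame(covariates), seq_along(ids))
    for (nm in names(covs)) if (is.character(covs[[nm]]))
      covs[[nm]] <- factor(covs[[nm]])
    base <- data.frame(base, covs)
  }
  rows <- lapply(unique(ev$group), function(g) {
    x <- ev[group == g][match(ids, patientId)]
    if (anyNA(x$patientId)) stop("event outcomes missing for some patients")
    if (sum(x$event) == 0) {
      message("no events in group ", g, "; skipped")
      return(NULL)
    }
    df <- data.frame(.time = x$timeDays, .event = as.integer(x$event), base)
    fit <- coxph(Surv(.time, .event) ~ ., data = df, ties = "breslow")
    sm <- summary(fit)$coefficients
    ci <- summary(fit)$conf.int
    data.table(
      group = g, n = nrow(df), nEvents = sum(x$event),
      hrAdherence = unname(exp(coef(fit)[".adh"])),
      ciLowAdherence = unname(ci[".adh", "lower .95"]),
      ciHighAdherence = unname(ci[".adh", "upper .95"]),
      pAdherence = unname(sm[".adh", "Pr(>|z|)"]),
      hrRisk = if (".risk" %in% rownames(sm))
        unname(exp(coef(fit)[".risk"])) else NA_real_,
      pRisk = if (".risk" %in% rownames(sm))
        unname(sm[".risk", "Pr(>|z|)"]) else NA_real_
    )
  })
  rbindlist(rows)
}

#' Kaplan-Meier curves across predicted-adherence tertiles
#'
#' [tertileKm()] applied to predicted adherence, per diagnosis group.
#'
#' @param predictedAdherence named numeric vector (names = patient ids).
#' @param eventOutcome long table from [eventOutcomes()].
#' @param groups which groups to plot; default all present.
#' @return named list of [tertileKm()] results.
#' @export
adherenceTertileKm <- function(predictedAdherence, eventOutcome,
                               groups = NULL) {
  ev <- as.data.table(eventOutcome)
  ids <- names(predictedAdherence)
  if (is.null(groups)) groups <- unique(ev$group)
  out <- lapply(groups, function(g) {
    x <- ev[group == g][match(ids, patientId)]
    tertileKm(predictedAdherence, x$timeDays, x$event)
  })
  names(out) <- groups
  out
}
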