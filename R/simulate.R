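#' Statin code list used by the synthetic generator
#'
#' The cohort and feature modules take the statin definition as data (a set
#' of drug-code tokens, the role a national-drug-code dictionary plays for
#' real claims). These are the tokens the generator emits.
#' @return character vector of statin drug-code tokens.
#' @export
statinCodes <- function() {
  c("STATIN_ATORVA", "STATIN_SIMVA", "STATIN_PRAVA", "STATIN_ROSU", "STATIN_LOVA")
}

#' Hospitalization code-to-diagnosis-group map
#'
#' Maps hospitalization claim codes to the four diagnosis groups used for
#' disease-risk labels and cardiovascular outcomes: myocardial infarction,
#' stroke, coronary artery disease, kidney disease.
#' @return data.frame with columns `code`, `group`.
#' @export
hospitalizationCodeMap <- function() {
  data.frame(
    code  = c("HOSP_MI", "HOSP_STROKE", "HOSP_CAD", "HOSP_KIDNEY"),
    group = c("MI", "STROKE", "CAD", "KIDNEY"),
    stringsAsFactors = FALSE
  )
}

#' Configuration for the synthetic claims generator
#'
#' Defines one synthetic "study": cohort size, the latent-phenotype model
#' that generates correlated claim counts, the covariate-driven adherence
#' mechanism, the lipid response, and the event-hazard model. An identical
#' config (including `seed`) reproduces the identical dataset bit for bit.
#'
#' Months are the unit of time (all dates are month-truncated, as in
#' privacy-protected claims extracts); `monthsBaseline` months of
#' pre-threshold history and `monthsFollowup` months of follow-up are
#' emitted per patient.
#'
#' @param nPatients number of patients.
#' @param nLatentFactors number of latent patient phenotypes driving code
#'   co-occurrence (true nonnegative rank of the count matrix).
#' @param nCodeVars,nDrugVars,nLabVars number of diagnostic/procedure code,
#'   concomitant drug, and laboratory variables. The first six lab variables
#'   are the named lipid/renal/muscle analytes (LDL, total cholesterol, HDL,
#'   triglycerides, creatinine, creatine kinase).
#' @param monthsBaseline months of pre-threshold history emitted.
#' @param monthsFollowup months of follow-up after the threshold fill.
#' @param adherenceCoefficients named log-odds weights for the monthly refill
#'   propensity. Allowed names: `"(Intercept)"`, `"age"` (standardised),
#'   `"female"`, `"tobacco"`, and `"factor1"` ... `"factor<L>"`
#'   (standardised latent intensities).
#' @param eventCoefficients named log-hazard weights on standardised latent
#'   intensities, names are factor indices (`"1"`, `"2"`, ...).
#' @param adherenceEventCoefficient log-hazard weight of realized adherence
#'   on every diagnosis group's event hazard (negative = protective).
#' @param lipidEffect mean LDL drop, mg/dL, per unit realized adherence.
#' @param labNoiseSd within-patient lab measurement noise SD, mg/dL.
#' @param baselineLdlMean,baselineLdlSd population baseline LDL, mg/dL.
#' @param eventBaseHazard per-day baseline hazard for each diagnosis group.
#' @param meanEventsPerKind named vector (`code`, `drug`, `lab`): expected
#'   total pre-threshold events per patient of each kind; loading columns
#'   are scaled to meet it.
#' @param pDiscontinue probability that a patient discontinues after the
#'   first fill regardless of covariates (refilling at a residual 0.5%
#'   monthly rate). This is unobserved heterogeneity: baseline covariates
#'   cannot predict it, but realized early refill behaviour reveals it,
#'   which is exactly why a first-refill indicator adds predictive value
#'   beyond any baseline model. Default 0 (constant per-patient refill
#'   propensity); ~0.1-0.2 emulates the sizable never-refill group seen in
#'   real cohorts.
#' @param lipidPanels if TRUE (default), every patient receives a scheduled
#'   lipid panel (LDL + total cholesterol) at the threshold month and 3 and
#'   12 months after it, the draws that feed the cholesterol-change
#'   outcomes. Set FALSE for pure factor-recovery experiments, where the
#'   panel would add a constant (non-latent) component to the count matrix.
#' @param pPriorStatin fraction of patients given a statin fill in the year
#'   before threshold (excluded later as not treatment-naive).
#' @param pBadDaysSupply fraction of first fills with a non-standard days
#'   supply (excluded later).
#' @param ageRange uniform age range; spills past the 18-65 eligibility
#'   window so the age filter has work to do.
#' @param seed integer RNG seed.
#' @return a `SimConfig` (validated list).
#' @export
simConfig <- function(nPatients,
                      nLatentFactors = 10L,
                      nCodeVars = 150L,
                      nDrugVars = 100L,
                      nLabVars = 6L,
                      monthsBaseline = 24L,
                      monthsFollowup = 60L,
                      adherenceCoefficients = c(
                        "(Intercept)" = 0.4, age = 0.35, tobacco = -0.4,
                        factor1 = 0.4, factor2 = -0.4
                      ),
                      eventCoefficients = c("1" = 0.3, "2" = 0.2),
                      adherenceEventCoefficient = -0.3,
                      lipidEffect = 40,
                      labNoiseSd = 12,
                      baselineLdlMean = 150,
                      baselineLdlSd = 25,
                      eventBaseHazard = 2e-5,
                      meanEventsPerKind = c(code = 8, drug = 10, lab = 6),
                      pDiscontinue = 0,
                      lipidPanels = TRUE,
                      pPriorStatin = 0.01,
                      pBadDaysSupply = 0.01,
                      ageRange = c(25, 70),
                      seed = 1L) {
  cfg <- list(
    nPatients = as.integer(nPatients),
    nLatentFactors = as.integer(nLatentFactors),
    nCodeVars = as.integer(nCodeVars), nDrugVars = as.integer(nDrugVars),
    nLabVars = as.integer(nLabVars),
    monthsBaseline = as.integer(monthsBaseline),
    monthsFollowup = as.integer(monthsFollowup),
    adherenceCoefficients = adherenceCoefficients,
    eventCoefficients = eventCoefficients,
    adherenceEventCoefficient = adherenceEventCoefficient,
    lipidEffect = lipidEffect, labNoiseSd = labNoiseSd,
    baselineLdlMean = baselineLdlMean, baselineLdlSd = baselineLdlSd,
    eventBaseHazard = eventBaseHazard,
    meanEventsPerKind = meanEventsPerKind, pDiscontinue = pDiscontinue,
    lipidPanels = isTRUE(lipidPanels),
    pPriorStatin = pPriorStatin, pBadDaysSupply = pBadDaysSupply,
    ageRange = ageRange, seed = as.integer(seed)
  )
  counts <- c("nPatients", "nLatentFactors", "nCodeVars", "nDrugVars",
              "nLabVars", "monthsBaseline", "monthsFollowup")
  for (nm in counts) if (cfg[[nm]] <= 0L) stop(nm, " must be > 0")
  if (cfg$monthsFollowup < 12L) stop("monthsFollowup must be >= 12")
  if (cfg$nLabVars < 6L) stop("nLabVars must be >= 6 (the named analytes)")
  if (any(cfg$meanEventsPerKind < 0) || cfg$eventBaseHazard < 0 ||
      cfg$labNoiseSd < 0 || cfg$baselineLdlSd < 0 || cfg$lipidEffect < 0)
    stop("rate/scale parameters must be nonnegative")
  if (cfg$pPriorStatin < 0 || cfg$pPriorStatin > 1 ||
      cfg$pBadDaysSupply < 0 || cfg$pBadDaysSupply > 1 ||
      cfg$pDiscontinue < 0 || cfg$pDiscontinue > 1)
    stop("probabilities must lie in [0, 1]")
  if (!all(c("code", "drug", "lab") %in% names(cfg$meanEventsPerKind)))
    stop("meanEventsPerKind needs entries code, drug, lab")
  okNames <- c("(Intercept)", "age", "female", "tobacco",
               paste0("factor", seq_len(cfg$nLatentFactors)))
  bad <- setdiff(names(cfg$adherenceCoefficients), okNames)
  if (length(bad)) stop("unknown adherence covariates: ", paste(bad, collapse = ", "))
  evIdx <- suppressWarnings(as.integer(names(cfg$eventCoefficients)))
  if (length(cfg$eventCoefficients) &&
      (anyNA(evIdx) || any(evIdx < 1L) || any(evIdx > cfg$nLatentFactors)))
    stop("eventCoefficients names must be factor indices within 1..nLatentFactors")
  structure(cfg, class = "SimConfig")
}

labAnalytes_ <- function(nLabVars) {
  base <- c("LAB_LDL", "LAB_TC", "LAB_HDL", "LAB_TG", "LAB_CREAT", "LAB_CK")
  if (nLabVars > 6L) base <- c(base, sprintf("LAB_X%03d", seq_len(nLabVars - 6L)))
  base
}

# nonnegative loading matrix L x V with block structure: each variable has
# one primary latent factor (strong loading) plus weak background loadings,
# columns scaled so expected per-kind event totals match the config.
makeLoadings_ <- function(cfg) {
  V <- cfg$nCodeVars + cfg$nDrugVars + cfg$nLabVars
  L <- cfg$nLatentFactors
  vars <- c(sprintf("CODE%04d", seq_len(cfg$nCodeVars)),
            sprintf("DRUG%04d", seq_len(cfg$nDrugVars)),
            labAnalytes_(cfg$nLabVars))
  kind <- rep(c("code", "drug", "lab"),
              c(cfg$nCodeVars, cfg$nDrugVars, cfg$nLabVars))
  primary <- ((seq_len(V) - 1L) %% L) + 1L
  lam <- matrix(runif(L * V, 0, 0.03), L, V)
  lam[cbind(primary, seq_len(V))] <- runif(V, 0.5, 1.5)
  for (k in c("code", "drug", "lab")) {
    sel <- kind == k
    lam[, sel] <- lam[, sel] * (cfg$meanEventsPerKind[[k]] / sum(lam[, sel]))
  }
  dimnames(lam) <- list(paste0("factor", seq_len(L)), vars)
  list(lambda = lam, vars = vars, kind = kind)
}

labValue_ <- function(analyte, n, baseLdl, cfg) {
  noise <- rnorm(n, 0, cfg$labNoiseSd)
  switch(substr(analyte, 1, 7),
    LAB_LDL = baseLdl + noise,
    LAB_TC  = baseLdl + 80 + noise,
    LAB_HDL = rnorm(n, 50, 10),
    LAB_TG  = rnorm(n, 150, 40),
    LAB_CRE = rnorm(n, 1, 0.2),
    LAB_CK  = rnorm(n, 120, 40),
    rnorm(n, 100, 20)
  )
}

#' Generate a synthetic claims cohort with recorded ground truth
#'
#' Emits month-truncated claims (drug fills, lab results, diagnostic codes),
#' a demographics table, and the generating ground truth. The generative
#' model mirrors the assumptions of the downstream analysis:
#' \itemize{
#' \item pre-threshold counts are Poisson with rate `theta \%*\% lambda`
#'   (latent nonnegative patient intensities times nonnegative loadings), so
#'   the count matrix has true nonnegative rank at most `nLatentFactors`;
#' \item each patient's threshold month carries a first statin fill
#'   (days supply in 30/60/90/180, small configurable fraction non-standard)
#'   flagged as a new prescription;
#' \item after the threshold, a 30-day statin refill is emitted each month
#'   with probability equal to the patient's adherence propensity
#'   (logistic in the configured covariates);
#' \item a lipid panel (LDL + total cholesterol) is drawn at the threshold
#'   month and 3 and 12 months after it; post-threshold values drop by
#'   `lipidEffect` mg/dL per unit realized adherence, plus noise;
#' \item one exponential event clock per diagnosis group (MI, stroke, CAD,
#'   kidney) with hazard `eventBaseHazard * exp(eventCoefficients .
#'   scaledFactors + adherenceEventCoefficient * realizedAdherence)`,
#'   censored at the end of follow-up;
#' \item a wellness-visit code every 6 months of follow-up pins the
#'   follow-up window (last recorded element) for every patient.
#' }
#'
#' @param config a [simConfig()].
#' @return list with `claims` (data.table: `patientId`, `month`, `kind`,
#'   `code`, `value`, `daysSupply`, `strength`, `newRefillFlag`),
#'   `demographics`, `truth` (a `GroundTruth` list: `theta`, `trueLoadings`,
#'   `propensity`, `realizedAdherence`, `hazardMultiplier`, `eventTimeDays`,
#'   `baselineLdl`) and the `config`. The truth is never consumed by
#'   pipeline stages; it exists for parameter-recovery tests.
#' @export
simulateEhr <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  cfg <- config
  withr_seed(cfg$seed)
  n <- cfg$nPatients
  L <- cfg$nLatentFactors
  ids <- sprintf("P%06d", seq_len(n))

  demographics <- data.table(
    patientId = ids,
    age = round(runif(n, cfg$ageRange[1], cfg$ageRange[2])),
    female = rbinom(n, 1, 0.42),
    race = sample(c("white", "black", "other"), n, TRUE, c(0.74, 0.08, 0.18)),
    tobacco = rbinom(n, 1, 0.05),
    pharmacyProgram = sample(c("retail", "mail", "mtf"), n, TRUE, c(0.55, 0.15, 0.30))
  )

  threshold <- cfg$monthsBaseline + sample(0:11, n, TRUE)
  theta <- matrix(rgamma(n * L, shape = 1.2, rate = 1.2), n, L,
                  dimnames = list(ids, paste0("factor", seq_len(L))))
  load <- makeLoadings_(cfg)

  ## --- pre-threshold claim events from the latent Poisson model ----------
  rate <- theta %*% load$lambda
  counts <- matrix(rpois(length(rate), rate), n, ncol(rate))
  nz <- which(counts > 0L, arr.ind = TRUE)
  reps <- counts[nz]
  pIdx <- rep(nz[, 1], reps)
  vIdx <- rep(nz[, 2], reps)
  baseline <- data.table(
    patientId = ids[pIdx],
    month = threshold[pIdx] - sample.int(cfg$monthsBaseline, length(pIdx), TRUE) + 1L,
    kind = load$kind[vIdx],
    code = load$vars[vIdx],
    value = NA_real_, daysSupply = NA_integer_, strength = NA_real_,
    newRefillFlag = NA
  )
  baseLdl <- rnorm(n, cfg$baselineLdlMean, cfg$baselineLdlSd)
  isLab <- baseline$kind == "lab"
  if (any(isLab)) {
    labCodes <- unique(baseline$code[isLab])
    for (an in labCodes) {
      sel <- which(baseline$code == an)
      baseline$value[sel] <- labValue_(an, length(sel),
                                       baseLdl[match(baseline$patientId[sel], ids)], cfg)
    }
  }
  isDrug <- baseline$kind == "drug"
  baseline$daysSupply[isDrug] <- 30L
  drugStrength <- setNames(sample(c(10, 20, 40, 80), cfg$nDrugVars, TRUE),
                           load$vars[load$kind == "drug"])
  baseline$strength[isDrug] <- drugStrength[baseline$code[isDrug]]

  ## --- the threshold (first statin) fill ---------------------------------
  firstSupply <- sample(c(30L, 60L, 90L, 180L), n, TRUE, c(0.35, 0.25, 0.30, 0.10))
  bad <- runif(n) < cfg$pBadDaysSupply
  firstSupply[bad] <- 45L
  firstStatin <- data.table(
    patientId = ids, month = threshold, kind = "drug",
    code = sample(statinCodes(), n, TRUE,
                  c(0.35, 0.30, 0.15, 0.12, 0.08)),
    value = NA_real_, daysSupply = firstSupply,
    strength = sample(c(10, 20, 40, 80), n, TRUE, c(0.25, 0.40, 0.25, 0.10)),
    newRefillFlag = TRUE
  )

  ## prior statin exposure for a small fraction (later excluded)
  prior <- which(runif(n) < cfg$pPriorStatin)
  priorStatin <- if (length(prior)) data.table(
    patientId = ids[prior],
    month = threshold[prior] - sample.int(12L, length(prior), TRUE),
    kind = "drug", code = sample(statinCodes(), length(prior), TRUE),
    value = NA_real_, daysSupply = 30L, strength = 20,
    newRefillFlag = FALSE
  ) else NULL

  ## --- adherence mechanism ------------------------------------------------
  thetaStd <- scale(theta)
  covs <- cbind(`(Intercept)` = 1,
                age = as.numeric(scale(demographics$age)),
                female = demographics$female,
                tobacco = demographics$tobacco,
                thetaStd)
  beta <- cfg$adherenceCoefficients
  eta <- as.numeric(covs[, names(beta), drop = FALSE] %*% beta)
  propensity <- plogis(eta)
  if (cfg$pDiscontinue > 0) {
    ## covariate-independent discontinuation: unobserved heterogeneity
    quit <- runif(n) < cfg$pDiscontinue
    propensity[quit] <- 0.005
  }
  fills <- matrix(rbinom(n * cfg$monthsFollowup, 1, rep(propensity, cfg$monthsFollowup)),
                  n, cfg$monthsFollowup)
  realizedAdherence <- rowMeans(fills)
  fillIdx <- which(fills == 1L, arr.ind = TRUE)
  refills <- if (nrow(fillIdx)) data.table(
    patientId = ids[fillIdx[, 1]],
    month = threshold[fillIdx[, 1]] + fillIdx[, 2],
    kind = "drug", code = firstStatin$code[fillIdx[, 1]],
    value = NA_real_, daysSupply = 30L,
    strength = firstStatin$strength[fillIdx[, 1]],
    newRefillFlag = FALSE
  ) else NULL

  ## --- lipid panels -------------------------------------------------------
  panel <- function(atMonth, drop) data.table(
    patientId = rep(ids, 2L),
    month = rep(threshold + atMonth, 2L),
    kind = "lab",
    code = rep(c("LAB_LDL", "LAB_TC"), each = n),
    value = c(baseLdl - drop + rnorm(n, 0, cfg$labNoiseSd),
              baseLdl + 80 - drop + rnorm(n, 0, cfg$labNoiseSd)),
    daysSupply = NA_integer_, strength = NA_real_, newRefillFlag = NA
  )
  panels <- if (cfg$lipidPanels) rbindlist(list(
    panel(0L, 0),
    panel(3L, cfg$lipidEffect * realizedAdherence),
    panel(12L, cfg$lipidEffect * realizedAdherence)
  )) else NULL

  ## --- cardiovascular / renal events --------------------------------------
  groups <- c("MI", "STROKE", "CAD", "KIDNEY")
  evBeta <- numeric(L)
  evBeta[as.integer(names(cfg$eventCoefficients))] <- cfg$eventCoefficients
  logMult <- as.numeric(thetaStd %*% evBeta) +
    cfg$adherenceEventCoefficient * realizedAdherence
  hazardMultiplier <- exp(logMult)
  horizonDays <- cfg$monthsFollowup * DAYS_PER_MONTH
  eventTimeDays <- matrix(NA_real_, n, 4L, dimnames = list(ids, groups))
  evClaims <- vector("list", 4L)
  for (g in seq_along(groups)) {
    tg <- rexp(n, rate = cfg$eventBaseHazard * hazardMultiplier)
    eventTimeDays[, g] <- tg
    hit <- which(tg <= horizonDays)
    evClaims[[g]] <- if (length(hit)) data.table(
      patientId = ids[hit],
      month = threshold[hit] + pmax(1L, as.integer(ceiling(tg[hit] / DAYS_PER_MONTH))),
      kind = "code", code = paste0("HOSP_", groups[g]),
      value = NA_real_, daysSupply = NA_integer_, strength = NA_real_,
      newRefillFlag = NA
    ) else NULL
  }

  ## --- wellness visits pin the follow-up window ---------------------------
  visitMonths <- seq(6L, cfg$monthsFollowup, by = 6L)
  if (visitMonths[length(visitMonths)] != cfg$monthsFollowup)
    visitMonths <- c(visitMonths, cfg$monthsFollowup)
  visits <- data.table(
    patientId = rep(ids, each = length(visitMonths)),
    month = rep(threshold, each = length(visitMonths)) + visitMonths,
    kind = "code", code = "VISIT_WELLNESS",
    value = NA_real_, daysSupply = NA_integer_, strength = NA_real_,
    newRefillFlag = NA
  )

  claims <- rbindlist(c(list(baseline, firstStatin, priorStatin, refills,
                             panels, visits), evClaims))
  ## first fill of each non-statin prescription carries the new-fill flag
  isDrugAll <- claims$kind == "drug" & is.na(claims$newRefillFlag)
  if (any(isDrugAll)) {
    dd <- claims[isDrugAll, .(patientId, code, month)]
    dd[, idx := which(isDrugAll)]
    setorder(dd, patientId, code, month)
    firstRow <- dd[, .(idx = idx[1L]), by = .(patientId, code)]$idx
    claims$newRefillFlag[isDrugAll] <- FALSE
    claims$newRefillFlag[firstRow] <- TRUE
  }
  setorder(claims, patientId, month, kind, code)

  truth <- structure(list(
    theta = theta,
    trueLoadings = Matrix::t(load$lambda),  # variables x L
    propensity = setNames(propensity, ids),
    realizedAdherence = setNames(realizedAdherence, ids),
    hazardMultiplier = setNames(hazardMultiplier, ids),
    eventTimeDays = eventTimeDays,
    baselineLdl = setNames(baseLdl, ids),
    thresholdMonth = setNames(threshold, ids)
  ), class = "GroundTruth")

  list(claims = claims[], demographics = demographics[], truth = truth,
       config = cfg)
}

#' Closed-form lipid-effect calibration for a target adherence-LDL correlation
#'
#' Under the generator's lipid model the change in LDL is
#' `-lipidEffect * adherence + noise` with independent measurement noise on
#' both the baseline and follow-up value, so the population correlation
#' between adherence and lowering is
#' `r = b*s_a / sqrt(b^2 s_a^2 + 2 s_e^2)`. Inverting gives the `lipidEffect`
#' that produces a target correlation. The adherence SD is computed
#' analytically from the propensity distribution
#' (`var(p) + E[p(1-p)]/M` for `M` follow-up months), using a large
#' quasi-population draw of the linear predictor, not the realized data.
#'
#' @param targetR target Pearson correlation between adherence and lowering.
#' @param config a [simConfig()]; its coefficients and noise scales are used.
#' @return lipid effect in mg/dL per unit adherence.
#' @export
lipidEffectForCorrelation <- function(targetR, config) {
  stopifnot(targetR > 0, targetR < 1)
  beta <- config$adherenceCoefficients
  ## means and variances of the generator's covariates: standardised age
  ## and factor intensities are (0, 1); female and tobacco are Bernoulli
  moments <- function(nm) {
    if (nm == "female") c(0.42, 0.42 * 0.58)
    else if (nm == "tobacco") c(0.05, 0.05 * 0.95)
    else c(0, 1)
  }
  nms <- setdiff(names(beta), "(Intercept)")
  mu <- (beta[["(Intercept)"]] %||% 0) +
    sum(vapply(nms, function(nm) beta[[nm]] * moments(nm)[1], numeric(1)))
  sdLin <- sqrt(sum(vapply(nms, function(nm)
    beta[[nm]]^2 * moments(nm)[2], numeric(1))))
  z <- qnorm(seq(0.0005, 0.9995, by = 0.001))
  p <- plogis(mu + sdLin * z)
  varA <- var(p) + mean(p * (1 - p)) / config$monthsFollowup
  s2e <- 2 * config$labNoiseSd^2
  targetR * sqrt(s2e / (varA * (1 - targetR^2)))
}
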