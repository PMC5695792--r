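#' Assemble per-patient model features
#'
#' Joins the cohort covariates (demographics, first-statin characteristics,
#' follow-up length, interaction counts), wide baseline labs, and factor
#' scores into one data.frame keyed by the cohort's patient order.
#'
#' @param cohort cohort table.
#' @param factorScores patients x K matrix (rownames = patient ids), or
#'   `NULL`.
#' @param labs long table from [extractBaselineLabs()], or `NULL`.
#' @return data.frame, one row per cohort patient; `patientId` is kept as
#'   row names, not a column.
#' @export
assembleFeatures <- function(cohort, factorScores = NULL, labs = NULL) {
  co <- as.data.table(cohort)
  out <- data.frame(
    age = co$age, female = co$female, race = co$race,
    tobacco = co$tobacco, pharmacyProgram = co$pharmacyProgram,
    firstStatinStrength = co$firstStatinStrength,
    firstStatinDaysSupply = co$firstStatinDaysSupply,
    followupDays = co$followupDays,
    nLabs = co$nLabs, nDrugs = co$nDrugs, nCodes = co$nCodes,
    row.names = co$patientId
  )
  if (!is.null(labs) && nrow(labs)) {
    wide <- data.table::dcast(as.data.table(labs), patientId ~ analyte,
                              value.var = "value")
    m <- wide[match(co$patientId, patientId)]
    for (nm in setdiff(names(m), "patientId")) out[[nm]] <- m[[nm]]
  }
  if (!is.null(factorScores)) {
    s <- factorScores[match(co$patientId, rownames(factorScores)), , drop = FALSE]
    for (j in seq_len(ncol(s))) out[[colnames(factorScores)[j]]] <- s[, j]
  }
  out
}

#' Run the full adherence-modelling pipeline on a claims dataset
#'
#' Executes cohort construction, feature engineering, factorization,
#' outcome computation, disease-risk modelling, adherence modelling, and
#' outcome linkage, in order; any stage failure aborts naming the stage.
#'
#' @param claims,demographics raw input tables (see [simulateEhr()]).
#' @param statinCodes statin drug-code tokens.
#' @param codeMap hospitalization code-to-group map.
#' @param K number of factors, default 30.
#' @param nFolds cross-validation folds, default 30.
#' @param seed master seed; stage seeds are derived from it.
#' @param windowMonths count-matrix window.
#' @param minPatients variable prevalence filter for the count matrix.
#' @param window prescribing window for cohort entry.
#' @param includeFirstRefill also fit the first-refill adherence model
#'   (outcome recomputed on the post-first-supply window).
#' @param log1p pass-through to [fitNmf()].
#' @param numTrees forest size.
#' @param riskLambdaGrid pass-through to [fitDiseaseRisk()].
#' @param precomputedScores optional patients x K factor-score matrix; when
#'   given, NMF fitting is skipped and these scores are used (the situation
#'   where an analytical dataset ships its factor scores).
#' @return list of class `"ehrPipeline"`: per-stage artifacts (`cohort`,
#'   `tally`, `countMatrix`, `factorModel`, `features`, `outcomes`,
#'   `riskFit`, `adherenceFit`, `adherenceFirstRefillFit`, `linkage`) and
#'   `summary` (cohort sizes, variable counts, CV AUCs, correlations,
#'   hazard-ratio table, seeds).
#' @export
runPipeline <- function(claims, demographics,
                        statinCodes = ehrAdherence::statinCodes(),
                        codeMap = hospitalizationCodeMap(),
                        K = 30L, nFolds = 30L, seed = 1L,
                        windowMonths = 6L, minPatients = 100L,
                        window = c(-Inf, Inf),
                        includeFirstRefill = TRUE, log1p = FALSE,
                        numTrees = 500L,
                        riskLambdaGrid = c(0.5, 5, 50),
                        precomputedScores = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  cs <- stage("cohort", {
    res <- applyCohortFilters(claims, demographics, statinCodes, window)
    if (!nrow(res$cohort)) stop("no patients remain after filters")
    res
  })
  cohort <- cs$cohort

  feat <- stage("features", {
    list(
      countMatrix = buildCountMatrix(claims, cohort, windowMonths,
                                     minPatients, statinCodes),
      labs = extractBaselineLabs(claims, cohort),
      priorPdc = computePriorPdc(claims, cohort, statinCodes)
    )
  })

  fm <- NULL
  scores <- stage("factorize", {
    if (!is.null(precomputedScores)) {
      precomputedScores
    } else {
      fm <- fitNmf(feat$countMatrix, K = K, seed = seed + 1L, log1p = log1p)
      factorScores(fm)
    }
  })

  oc <- stage("outcomes", {
    list(
      adherence = computeAdherenceOutcomes(claims, cohort, statinCodes),
      lipids = lipidChange(claims, cohort),
      events = eventOutcomes(claims, cohort, codeMap)
    )
  })

  features <- assembleFeatures(cohort, scores, feat$labs)
  riskDesign <- features[, setdiff(names(features), "followupDays")]

  riskFit <- stage("risk", {
    evw <- data.table::dcast(as.data.table(oc$events)[group != "COMPOSITE"],
                             patientId ~ group, value.var = "eventWithin1yr")
    evw <- evw[match(cohort$patientId, patientId)]
    labels <- as.matrix(evw[, -1]) * 1
    fitDiseaseRisk(riskDesign, labels, nFolds = nFolds, seed = seed + 2L,
                   lambdaGrid = riskLambdaGrid)
  })

  adhFeatures <- cbind(features, diseaseRisk = riskFit$composite)
  adherent <- oc$adherence$adherent[match(cohort$patientId,
                                          oc$adherence$patientId)]
  adhFit <- stage("adherence", {
    fitAdherence(adhFeatures, adherent, nFolds = nFolds, seed = seed + 3L,
                 numTrees = numTrees)
  })

  adhFrFit <- NULL
  if (includeFirstRefill) {
    adhFrFit <- stage("adherence", {
      fr <- oc$adherence[match(cohort$patientId, patientId)]
      ok <- !is.na(fr$followupPdc)
      fitAdherence(cbind(adhFeatures, firstRefill = as.numeric(fr$firstRefill))[ok, ],
                   fr$followupPdc[ok] > 0.8,
                   nFolds = nFolds, seed = seed + 3L, numTrees = numTrees)
    })
  }

  link <- stage("linkage", {
    predAdh <- setNames(adhFit$oofProb, cohort$patientId)
    covs <- features[, setdiff(names(features),
                               colnames(scores) %||% character())]
    list(
      lipidCorrelation = lipidCorrelation(predAdh, oc$lipids),
      cox = coxLinkage(predAdh, oc$events, covs, riskFit$composite),
      km = adherenceTertileKm(predAdh, oc$events)
    )
  })

  kinds <- table(rowData(feat$countMatrix)$kind)
  summary <- list(
    nInput = nrow(as.data.table(demographics)),
    cohortSize = nrow(cohort),
    exclusionTally = cs$tally,
    nCountVariables = nrow(feat$countMatrix),
    countVariablesByKind = as.list(kinds),
    nLabVariables = length(unique(feat$labs$analyte)),
    nPriorPdcVariables = length(unique(feat$priorPdc$code)),
    K = K,
    adherentFraction = mean(adherent),
    riskCvAuc = as.list(riskFit$cvAuc),
    adherenceCvAuc = adhFit$cvAuc,
    adherenceFirstRefillCvAuc = if (!is.null(adhFrFit)) adhFrFit$cvAuc else NA,
    lipidCorrelation = as.data.frame(link$lipidCorrelation),
    hazardRatios = as.data.frame(link$cox),
    seed = seed
  )

  structure(list(
    cohort = cohort, tally = cs$tally, countMatrix = feat$countMatrix,
    labs = feat$labs, priorPdc = feat$priorPdc, factorModel = fm,
    factorScores = scores, features = features, outcomes = oc,
    riskFit = riskFit, adherenceFit = adhFit,
    adherenceFirstRefillFit = adhFrFit, linkage = link, summary = summary
  ), class = "ehrPipeline")
}

#' @export
print.ehrPipeline <- function(x, ...) {
  s <- x$summary
  cat("ehrAdherence pipeline run (seed ", s$seed, ")\n", sep = "")
  cat("  cohort: ", s$cohortSize, " of ", s$nInput, " patients; adherent ",
      sprintf("%.1f%%", 100 * s$adherentFraction), "\n", sep = "")
  cat("  predictors: ", s$nCountVariables, " count variables -> ",
      s$K, " factors\n", sep = "")
  cat("  CV c-statistic: risk-only ", sprintf("%.3f", s$adherenceCvAuc),
      if (!is.na(s$adherenceFirstRefillCvAuc))
        sprintf("; with first refill %.3f", s$adherenceFirstRefillCvAuc),
      "\n", sep = "")
  invisible(x)
}

## ---------------------------------------------------------------------------
## Analytical-dataset layout: one CSV per data role, tied together by a YAML
## manifest so column/file names are user-editable rather than hard-coded.

#' Write a synthetic dataset (claims, demographics, truth, config) to disk
#'
#' @param sim result of [simulateEhr()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeSyntheticEhr <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fwrite(sim$claims, file.path(dir, "claims.csv"))
  fwrite(sim$demographics, file.path(dir, "demographics.csv"))
  tdir <- file.path(dir, "truth")
  dir.create(tdir, showWarnings = FALSE)
  fwrite(data.table(patientId = rownames(sim$truth$theta), sim$truth$theta),
         file.path(tdir, "theta.csv"))
  fwrite(data.table(variable = rownames(sim$truth$trueLoadings),
                    as.matrix(sim$truth$trueLoadings)),
         file.path(tdir, "loadings.csv"))
  fwrite(data.table(
    patientId = names(sim$truth$propensity),
    propensity = sim$truth$propensity,
    realizedAdherence = sim$truth$realizedAdherence,
    hazardMultiplier = sim$truth$hazardMultiplier,
    baselineLdl = sim$truth$baselineLdl,
    thresholdMonth = sim$truth$thresholdMonth
  ), file.path(tdir, "patients.csv"))
  cfg <- sim$config
  class(cfg) <- NULL
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Read a synthetic dataset written by [writeSyntheticEhr()]
#' @param dir dataset directory.
#' @return list with `claims` and `demographics` tables.
#' @export
readSyntheticEhr <- function(dir) {
  list(
    claims = fread(file.path(dir, "claims.csv"),
                   colClasses = list(character = "patientId")),
    demographics = fread(file.path(dir, "demographics.csv"),
                         colClasses = list(character = "patientId"))
  )
}

#' Write a pipeline run as an analytical dataset (manifest + CSVs)
#'
#' One file per data role (baseline covariates, labs, prior PDC, count
#' matrix in triplet form plus its variable list, outcomes, factor scores),
#' tied together by `manifest.yaml`.
#'
#' @param result an `"ehrPipeline"` object.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
writeAnalyticalDataset <- function(result, dir) {
  stopifnot(inherits(result, "ehrPipeline"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    baseline = "baseline.csv", labs = "labs.csv", prior_pdc = "prior_pdc.csv",
    counts = "counts.csv", count_variables = "count_variables.csv",
    outcomes = "outcomes.csv", factor_scores = "factor_scores.csv"
  )
  fwrite(result$cohort, file.path(dir, manifest$baseline))
  fwrite(result$labs, file.path(dir, manifest$labs))
  fwrite(result$priorPdc, file.path(dir, manifest$prior_pdc))
  m <- assay(result$countMatrix, "counts")
  trip <- Matrix::summary(m)
  fwrite(data.table(variable = rownames(m)[trip$i],
                    patientId = colnames(m)[trip$j], count = trip$x),
         file.path(dir, manifest$counts))
  fwrite(data.table(variable = rownames(m),
                    kind = rowData(result$countMatrix)$kind),
         file.path(dir, manifest$count_variables))
  adh <- as.data.table(result$outcomes$adherence)
  fwrite(adh, file.path(dir, manifest$outcomes))
  fwrite(data.table(patientId = rownames(result$factorScores),
                    result$factorScores),
         file.path(dir, manifest$factor_scores))
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' Read an analytical dataset written by [writeAnalyticalDataset()]
#'
#' Validates the manifest (every role present), patient-id consistency
#' across files (duplicates and cross-file mismatches are named), and
#' count nonnegativity.
#'
#' @param dir dataset directory.
#' @param manifestFile manifest file name inside `dir`.
#' @return list of typed tables keyed by role (`baseline`, `labs`,
#'   `prior_pdc`, `counts` triplet, `count_variables`, `outcomes`,
#'   `factor_scores`).
#' @export
readAnalyticalDataset <- function(dir, manifestFile = "manifest.yaml") {
  mf <- file.path(dir, manifestFile)
  if (!file.exists(mf)) stop("manifest not found: ", mf)
  manifest <- yaml::read_yaml(mf)
  roles <- c("baseline", "labs", "prior_pdc", "counts", "count_variables",
             "outcomes", "factor_scores")
  missing <- setdiff(roles, names(manifest))
  if (length(missing)) stop("manifest missing roles: ",
                            paste(missing, collapse = ", "))
  out <- lapply(manifest[roles], function(f) {
    path <- file.path(dir, f)
    if (!file.exists(path)) stop("manifest file not found: ", f)
    fread(path)
  })
  names(out) <- roles
  dup <- out$baseline$patientId[duplicated(out$baseline$patientId)]
  if (length(dup)) stop("duplicated patient id in baseline: ",
                        paste(unique(dup), collapse = ", "))
  if (any(out$counts$count < 0)) stop("negative entries in count matrix")
  ids <- out$baseline$patientId
  for (role in c("outcomes", "factor_scores")) {
    extra <- setdiff(out[[role]]$patientId, ids)
    if (length(extra))
      stop("patient ids in ", role, " absent from baseline: ",
           paste(head(extra, 5), collapse = ", "))
  }
  out
}
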