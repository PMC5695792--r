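#' Identify each patient's first statin fill (threshold month)
#'
#' The threshold is the earliest drug claim whose code is in the statin list
#' and whose `newRefillFlag` is `TRUE` (the claims system's marker for the
#' first fill of a prescription, as opposed to a refill). Patients without
#' such a fill are absent from the result.
#'
#' @param claims claims table (see [simulateEhr()] for the layout).
#' @param statinCodes character vector of statin drug-code tokens.
#' @param window optional length-2 numeric: only fills with
#'   `window[1] <= month <= window[2]` qualify.
#' @return data.table with columns `patientId`, `thresholdMonth`.
#' @export
identifyFirstStatin <- function(claims, statinCodes, window = c(-Inf, Inf)) {
  cl <- as.data.table(claims)
  hits <- cl[kind == "drug" & code %in% statinCodes & newRefillFlag %in% TRUE &
               month >= window[1] & month <= window[2]]
  if (!nrow(hits))
    return(data.table(patientId = character(), thresholdMonth = integer()))
  out <- hits[, .(thresholdMonth = min(month)), by = patientId]
  setorder(out, patientId)
  out[]
}

#' Apply cohort inclusion/exclusion filters
#'
#' Retains patients who (in this order, with a per-rule exclusion tally):
#' have a flagged first statin fill; are statin-naive (no statin fill of any
#' kind in the 12 months before the threshold month, and none in the
#' preceding 6 months -- the 6-month rule is tallied separately even though
#' the 12-month rule subsumes it); have the first fill inside the
#' prescribing window; are aged 18-65 at threshold; received a standard
#' days supply (30/60/90/180); and have at least `minFollowupDays` of
#' follow-up, measured from the threshold month to the last recorded claim
#' of any kind (lab, drug or code) at 30 days per month.
#'
#' @param claims claims table.
#' @param demographics one row per patient: `patientId`, `age`, `female`,
#'   `race`, `tobacco`, `pharmacyProgram`. Must cover every patient in
#'   `claims`.
#' @param statinCodes statin drug-code tokens.
#' @param window prescribing window (month indices), default unbounded.
#' @param minFollowupDays minimum follow-up, default 365.
#' @param validSupplies permitted first-fill days supplies.
#' @return list with `cohort` (one row per retained patient: demographics,
#'   `thresholdMonth`, first-statin characteristics, `followupDays` and
#'   pre-threshold interaction counts `nLabs`/`nDrugs`/`nCodes`) and
#'   `tally` (named integer vector of exclusions per rule, in order).
#'   The tally plus the retained count always sums to the number of
#'   patients in `demographics`.
#' @export
applyCohortFilters <- function(claims, demographics, statinCodes,
                               window = c(-Inf, Inf), minFollowupDays = 365,
                               validSupplies = c(30L, 60L, 90L, 180L)) {
  cl <- as.data.table(claims)
  dem <- as.data.table(demographics)
  if (anyDuplicated(dem$patientId))
    stop("duplicated patient id in demographics: ",
         dem$patientId[anyDuplicated(dem$patientId)])
  missingDem <- setdiff(unique(cl$patientId), dem$patientId)
  if (length(missingDem))
    stop("claims contain patients absent from demographics: ",
         paste(head(missingDem, 5), collapse = ", "))

  tally <- c(noFirstStatin = 0L, priorStatin12mo = 0L, priorStatin6mo = 0L,
             outsideWindow = 0L, age = 0L, daysSupply = 0L, followup = 0L)

  thr <- identifyFirstStatin(cl, statinCodes)  # unwindowed: the window is its own filter
  tally["noFirstStatin"] <- nrow(dem) - nrow(thr)
  if (!nrow(thr)) return(list(cohort = emptyCohort_(), tally = tally))

  x <- merge(thr, dem, by = "patientId")
  statinFills <- cl[kind == "drug" & code %in% statinCodes,
                    .(patientId, month)][x, on = "patientId", nomatch = 0L]
  pre12 <- statinFills[month >= thresholdMonth - 12L & month < thresholdMonth,
                       unique(patientId)]
  tally["priorStatin12mo"] <- sum(x$patientId %in% pre12)
  x <- x[!patientId %in% pre12]
  if (nrow(x)) {
    pre6 <- statinFills[month >= thresholdMonth - 6L & month < thresholdMonth,
                        unique(patientId)]
    tally["priorStatin6mo"] <- sum(x$patientId %in% pre6)
    x <- x[!patientId %in% pre6]
  }
  out <- x$thresholdMonth < window[1] | x$thresholdMonth > window[2]
  tally["outsideWindow"] <- sum(out); x <- x[!out]
  bad <- x$age < 18 | x$age > 65
  tally["age"] <- sum(bad); x <- x[!bad]

  ## first-statin characteristics at the threshold month (earliest flagged
  ## fill; ties within the month broken by code order for determinism)
  firsts <- cl[kind == "drug" & code %in% statinCodes & newRefillFlag %in% TRUE]
  setorder(firsts, patientId, month, code)
  firsts <- firsts[, .SD[1L], by = patientId,
                   .SDcols = c("month", "code", "strength", "daysSupply")]
  x <- merge(x, firsts[, .(patientId, firstStatinCode = code,
                           firstStatinStrength = strength,
                           firstStatinDaysSupply = daysSupply)],
             by = "patientId")
  bad <- !x$firstStatinDaysSupply %in% validSupplies
  tally["daysSupply"] <- sum(bad); x <- x[!bad]

  lastMonth <- cl[, .(lastMonth = max(month)), by = patientId]
  x <- merge(x, lastMonth, by = "patientId")
  x[, followupDays := monthsToDays(lastMonth - thresholdMonth)]
  bad <- x$followupDays < minFollowupDays
  tally["followup"] <- sum(bad); x <- x[!bad]
  x[, lastMonth := NULL]

  if (!nrow(x)) return(list(cohort = emptyCohort_(), tally = tally))
  ic <- interactionCounts(cl, x[, .(patientId, thresholdMonth)])
  x <- merge(x, ic, by = "patientId")
  setorder(x, patientId)
  list(cohort = x[], tally = tally)
}

emptyCohort_ <- function() {
  data.table(patientId = character(), thresholdMonth = integer(),
             age = numeric(), female = integer(), race = character(),
             tobacco = integer(), pharmacyProgram = character(),
             firstStatinCode = character(), firstStatinStrength = numeric(),
             firstStatinDaysSupply = integer(), followupDays = numeric(),
             nLabs = integer(), nDrugs = integer(), nCodes = integer())
}

#' Stratified descriptive summary of a cohort
#'
#' Per-variable mean (continuous) or proportion (binary) by stratum, with a
#' two-sample test p-value: Welch t-test for continuous variables,
#' chi-square for binary. Missing values are counted per variable and
#' excluded from tests. A variable with all values missing, a constant
#' variable, or a stratum with fewer than 2 non-missing patients yields
#' `NA` for the p-value.
#'
#' @param cohort data.frame of per-patient variables.
#' @param stratum logical vector (one per row) defining the two groups.
#' @param variables columns to summarise; default: all numeric/logical
#'   columns except identifiers.
#' @param strataNames length-2 labels, `strataNames[1]` = `TRUE` stratum.
#' @return data.table: `variable`, `nMissing`, mean per stratum, `pValue`.
#' @export
cohortSummary <- function(cohort, stratum,
                          variables = NULL,
                          strataNames = c("group1", "group2")) {
  x <- as.data.table(cohort)
  stopifnot(length(stratum) == nrow(x), is.logical(stratum))
  if (is.null(variables)) {
    variables <- names(x)[vapply(x, function(v)
      is.numeric(v) || is.logical(v), logical(1))]
    variables <- setdiff(variables, c("patientId", "thresholdMonth"))
  }
  rows <- lapply(variables, function(nm) {
    v <- as.numeric(x[[nm]])
    nMissing <- sum(is.na(v))
    ok <- !is.na(v)
    g1 <- v[ok & stratum]; g2 <- v[ok & !stratum]
    m1 <- if (length(g1)) mean(g1) else NA_real_
    m2 <- if (length(g2)) mean(g2) else NA_real_
    binary <- all(v[ok] %in% c(0, 1))
    p <- NA_real_
    if (length(g1) >= 2 && length(g2) >= 2 && stats::sd(v[ok]) > 0) {
      p <- if (binary) {
        tab <- table(factor(stratum[ok], c(TRUE, FALSE)), factor(v[ok], c(0, 1)))
        if (all(dim(tab) == 2) && all(rowSums(tab) > 0))
          suppressWarnings(chisq.test(tab)$p.value) else NA_real_
      } else if (stats::sd(g1) > 0 || stats::sd(g2) > 0) {
        t.test(g1, g2)$p.value
      } else NA_real_
    }
    data.table(variable = nm, nMissing = nMissing, m1 = m1, m2 = m2, pValue = p)
  })
  out <- rbindlist(rows)
  setnames(out, c("m1", "m2"), strataNames)
  out[]
}
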