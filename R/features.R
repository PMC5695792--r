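#' Build the pre-threshold claim-count matrix
#'
#' Entry (v, p) counts claim events of variable `v` for patient `p` in the
#' `windowMonths` months up to and including the patient's threshold month.
#' Variables observed (count > 0) in fewer than `minPatients` patients are
#' dropped, and variables are ordered lexicographically so the matrix is
#' reproducible regardless of claim-file row order. Statin fills are
#' excluded (the cohort is treatment-naive, so the only in-window statin
#' claim is the threshold fill itself, whose characteristics enter the
#' models as separate covariates).
#'
#' @param claims claims table.
#' @param cohort cohort table with `patientId` and `thresholdMonth`.
#' @param windowMonths counting window, default 6.
#' @param minPatients minimum number of patients a variable must appear in,
#'   default 100.
#' @param excludeCodes claim codes left out of the matrix (default the
#'   statin list).
#' @return a [ClaimCountMatrix-class] (variables x patients).
#' @export
buildCountMatrix <- function(claims, cohort, windowMonths = 6L,
                             minPatients = 100L,
                             excludeCodes = statinCodes()) {
  if (windowMonths <= 0) stop("windowMonths must be positive")
  cl <- as.data.table(claims)
  co <- as.data.table(cohort)
  ev <- cl[co[, .(patientId, thresholdMonth)], on = "patientId", nomatch = 0L]
  ev <- ev[month >= thresholdMonth - windowMonths + 1L & month <= thresholdMonth &
             !code %in% excludeCodes]
  cnt <- ev[, .(n = .N), by = .(patientId, code, kind)]
  nPat <- cnt[, .(nPatients = .N), by = code]
  keep <- nPat[nPatients >= minPatients, code]
  cnt <- cnt[code %in% keep]
  vars <- sort(unique(cnt$code), method = "radix")
  pats <- sort(co$patientId, method = "radix")
  m <- sparseMatrix(
    i = match(cnt$code, vars), j = match(cnt$patientId, pats),
    x = cnt$n, dims = c(length(vars), length(pats)),
    dimnames = list(vars, pats)
  )
  kindMap <- unique(cnt[, .(code, kind)])
  se <- SummarizedExperiment(
    assays = list(counts = m),
    rowData = DataFrame(kind = kindMap$kind[match(vars, kindMap$code)],
                        row.names = vars),
    colData = DataFrame(row.names = pats)
  )
  metadata(se)$windowMonths <- as.integer(windowMonths)
  metadata(se)$minPatients <- as.integer(minPatients)
  methods::new("ClaimCountMatrix", se)
}

#' Most recent pre-threshold laboratory values
#'
#' For each patient and analyte, the most recent value measured at or before
#' the threshold month, looking back at most `lookbackMonths` months. Ties
#' within a month are broken by taking the last record in claim-file order.
#'
#' @param claims claims table.
#' @param cohort cohort table (`patientId`, `thresholdMonth`).
#' @param lookbackMonths lookback window, default 24 (the lab collection
#'   period).
#' @return data.table: `patientId`, `analyte`, `value`, `monthMeasured`.
#'   Absent analytes are simply missing rows.
#' @export
extractBaselineLabs <- function(claims, cohort, lookbackMonths = 24L) {
  cl <- as.data.table(claims)
  co <- as.data.table(cohort)
  labs <- cl[kind == "lab"][co[, .(patientId, thresholdMonth)],
                            on = "patientId", nomatch = 0L]
  labs[, fileOrder := .I]
  labs <- labs[month <= thresholdMonth & month >= thresholdMonth - lookbackMonths]
  if (!nrow(labs))
    return(data.table(patientId = character(), analyte = character(),
                      value = numeric(), monthMeasured = integer()))
  setorder(labs, patientId, code, month, fileOrder)
  out <- labs[, .SD[.N], by = .(patientId, code), .SDcols = c("month", "value")]
  setnames(out, c("code", "month"), c("analyte", "monthMeasured"))
  setcolorder(out, c("patientId", "analyte", "value", "monthMeasured"))
  setorder(out, patientId, analyte)
  out[]
}

#' Prior percent days covered for non-statin medications
#'
#' For each patient and each non-statin medication first filled at least
#' 2 months before the threshold, the prior PDC is the total days supplied
#' by fills strictly before the threshold month divided by the days from
#' the first fill to the threshold (30 days/month), capped at 1.
#' Medications with under 2 months of history are omitted (missing).
#'
#' @param claims claims table.
#' @param cohort cohort table (`patientId`, `thresholdMonth`).
#' @param statinCodes statin codes to exclude.
#' @return data.table: `patientId`, `code`, `priorPdc` in \[0, 1\].
#' @export
computePriorPdc <- function(claims, cohort, statinCodes) {
  cl <- as.data.table(claims)
  co <- as.data.table(cohort)
  fills <- cl[kind == "drug" & !code %in% statinCodes &
                !is.na(daysSupply)][co[, .(patientId, thresholdMonth)],
                                    on = "patientId", nomatch = 0L]
  fills <- fills[month < thresholdMonth]
  if (!nrow(fills))
    return(data.table(patientId = character(), code = character(),
                      priorPdc = numeric()))
  out <- fills[, .(
    firstMonth = min(month),
    supplied = sum(daysSupply),
    thresholdMonth = thresholdMonth[1L]
  ), by = .(patientId, code)]
  out <- out[thresholdMonth - firstMonth >= 2L]
  out[, priorPdc := pmin(1, supplied / monthsToDays(thresholdMonth - firstMonth))]
  setorder(out, patientId, code)
  out[, .(patientId, code, priorPdc)]
}

#' Pre-threshold health-system interaction counts
#'
#' Number of pre-threshold claim events per patient, broken down by kind,
#' each kind counted over its own collection window ending at the threshold
#' month (inclusive): labs 24 months, drugs 12, codes 12 by default. Statin
#' fills are not counted as drug interactions.
#'
#' @param claims claims table.
#' @param cohort cohort table (`patientId`, `thresholdMonth`).
#' @param windows named months per kind.
#' @param excludeCodes codes not counted (default statins).
#' @return data.table: `patientId`, `nLabs`, `nDrugs`, `nCodes` (zero for
#'   patients with no in-window events).
#' @export
interactionCounts <- function(claims, cohort,
                              windows = c(lab = 24L, drug = 12L, code = 12L),
                              excludeCodes = statinCodes()) {
  cl <- as.data.table(claims)
  co <- as.data.table(cohort)
  ev <- cl[!code %in% excludeCodes][co[, .(patientId, thresholdMonth)],
                                    on = "patientId", nomatch = 0L]
  ev <- ev[month <= thresholdMonth &
             month >= thresholdMonth - windows[kind] + 1L]
  cnt <- ev[, .(n = .N), by = .(patientId, kind)]
  wide <- data.table(patientId = co$patientId)
  for (k in c("lab", "drug", "code")) {
    col <- c(lab = "nLabs", drug = "nDrugs", code = "nCodes")[[k]]
    kk <- cnt[kind == k]
    wide[[col]] <- kk$n[match(wide$patientId, kk$patientId)]
    wide[[col]][is.na(wide[[col]])] <- 0L
  }
  setorder(wide, patientId)
  wide[]
}
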