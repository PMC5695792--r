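#' Percent days covered and adherence indicators for one fill schedule
#'
#' PDC is the ratio of total days of filled medication (of any type) to the
#' number of days of follow-up, capped at 1. This is the literal
#' supplied-days ratio: a patient who refills early banks the surplus
#' (equivalently, pills are stockpiled and consumed one per day), so
#' overlapping fills are not collapsed to a union of covered days.
#'
#' @param fills data.frame with columns `month` (integer, relative or
#'   absolute; the first row must be the threshold fill) and `daysSupply`.
#' @param followupDays follow-up length in days (threshold to last recorded
#'   claim of any kind).
#' @return one-row data.table: `pdc`, `adherent` (pdc > 0.8 exactly),
#'   `firstRefill` (any fill after the threshold fill), `followupPdc`
#'   (PDC over the window starting when the first prescription's supply
#'   ends, excluding the first fill's pills; `NA` if that window has
#'   nonpositive length), `followupDays`.
#' @export
computePdc <- function(fills, followupDays) {
  stopifnot(nrow(fills) >= 1, followupDays > 0)
  if (any(fills$daysSupply < 0)) stop("negative days supply")
  supplied <- sum(fills$daysSupply)
  pdc <- min(1, supplied / followupDays)
  firstSupply <- fills$daysSupply[1L]
  fupWindow <- followupDays - firstSupply
  followupPdc <- if (fupWindow > 0)
    min(1, sum(fills$daysSupply[-1L]) / fupWindow) else NA_real_
  data.table(
    pdc = pdc, adherent = pdc > 0.8,
    firstRefill = nrow(fills) > 1L,
    followupPdc = followupPdc,
    followupDays = followupDays
  )
}

#' Adherence outcomes for a whole cohort
#'
#' Applies [computePdc()] to each cohort patient's statin fills (any statin
#' code) at or after the threshold month.
#'
#' @param claims claims table.
#' @param cohort cohort table with `patientId`, `thresholdMonth`,
#'   `followupDays`.
#' @param statinCodes statin drug-code tokens.
#' @return data.table keyed by `patientId` with [computePdc()]'s columns.
#' @export
computeAdherenceOutcomes <- function(claims, cohort, statinCodes) {
  cl <- as.data.table(claims)
  co <- as.data.table(cohort)
  fills <- cl[kind == "drug" & code %in% statinCodes][
    co[, .(patientId, thresholdMonth, followupDays)],
    on = "patientId", nomatch = 0L]
  fills <- fills[month >= thresholdMonth]
  setorder(fills, patientId, month)
  out <- fills[, computePdc(.SD, followupDays[1L]),
               by = patientId, .SDcols = c("month", "daysSupply")]
  ## cohort patients are guaranteed a threshold fill, but keep the contract
  ## explicit if called on a broader table
  missing <- setdiff(co$patientId, out$patientId)
  if (length(missing)) stop("patients without a threshold fill: ",
                            paste(head(missing, 5), collapse = ", "))
  setorder(out, patientId)
  out[]
}

#' Cholesterol change around statin initiation
#'
#' Per patient and analyte: baseline = last value measured at or before the
#' threshold month; follow-up = first value measured at least 2 months after
#' it; `delta` = follow-up - baseline; `decreased` = (delta < 0), strict.
#' Patients missing either side get `NA`s.
#'
#' @param claims claims table.
#' @param cohort cohort table (`patientId`, `thresholdMonth`).
#' @param analytes lab codes to evaluate (default LDL and total
#'   cholesterol).
#' @return data.table: `patientId`, `analyte`, `baseline`, `followup`,
#'   `delta`, `decreased`.
#' @export
lipidChange <- function(claims, cohort, analytes = c("LAB_LDL", "LAB_TC")) {
  cl <- as.data.table(claims)
  co <- as.data.table(cohort)
  labs <- cl[kind == "lab" & code %in% analytes]
  labs[, fileOrder := .I]
  labs <- labs[co[, .(patientId, thresholdMonth)], on = "patientId", nomatch = 0L]
  base <- labs[month <= thresholdMonth]
  setorder(base, patientId, code, month, fileOrder)
  base <- base[, .(baseline = value[.N]), by = .(patientId, code)]
  fup <- labs[month >= thresholdMonth + 2L]
  setorder(fup, patientId, code, month, fileOrder)
  fup <- fup[, .(followup = value[1L]), by = .(patientId, code)]
  grid <- data.table(patientId = rep(co$patientId, each = length(analytes)),
                     code = rep(analytes, nrow(co)))
  out <- merge(merge(grid, base, by = c("patientId", "code"), all.x = TRUE),
               fup, by = c("patientId", "code"), all.x = TRUE)
  out[, delta := followup - baseline]
  out[, decreased := delta < 0]
  setnames(out, "code", "analyte")
  setorder(out, patientId, analyte)
  out[]
}

#' Time-to-event outcomes for hospitalization diagnosis groups
#'
#' For each patient and diagnosis group, the first in-group coded event
#' after the threshold month defines the event time (30 days/month);
#' otherwise the patient is censored at `followupDays`. A composite outcome
#' is the earliest event across `compositeGroups`.
#'
#' @param claims claims table.
#' @param cohort cohort table (`patientId`, `thresholdMonth`,
#'   `followupDays`).
#' @param codeMap data.frame mapping `code` to `group`; each code may map
#'   to at most one group.
#' @param compositeGroups groups pooled into the composite (default MI,
#'   stroke, CAD: the statin-responsive cardiovascular set; kidney disease
#'   participates in disease-risk labels but not the composite).
#' @return data.table: `patientId`, `group` (including `"COMPOSITE"`),
#'   `event` (logical), `timeDays`, `eventWithin1yr`.
#' @export
eventOutcomes <- function(claims, cohort, codeMap = hospitalizationCodeMap(),
                          compositeGroups = c("MI", "STROKE", "CAD")) {
  cm <- as.data.table(codeMap)
  dup <- unique(cm$code[duplicated(cm$code)])
  if (length(dup)) stop("code mapped to more than one group: ",
                        paste(dup, collapse = ", "))
  cl <- as.data.table(claims)
  co <- as.data.table(cohort)
  ev <- cl[kind == "code" & code %in% cm$code]
  ev <- merge(ev, cm, by = "code")
  ev <- ev[co[, .(patientId, thresholdMonth)], on = "patientId", nomatch = 0L]
  ev <- ev[month > thresholdMonth,
           .(eventMonth = min(month - thresholdMonth)), by = .(patientId, group)]
  groups <- unique(cm$group)
  grid <- data.table(patientId = rep(co$patientId, each = length(groups)),
                     group = rep(groups, nrow(co)))
  grid <- merge(grid, co[, .(patientId, followupDays)], by = "patientId")
  out <- merge(grid, ev, by = c("patientId", "group"), all.x = TRUE)
  out[, event := !is.na(eventMonth)]
  out[, timeDays := ifelse(event, pmin(monthsToDays(eventMonth), followupDays),
                           followupDays)]
  comp <- out[group %in% compositeGroups,
              .(group = "COMPOSITE", event = any(event),
                timeDays = min(ifelse(event, timeDays, Inf), followupDays[1L]),
                followupDays = followupDays[1L]),
              by = patientId]
  out <- rbind(out[, .(patientId, group, event, timeDays, followupDays)],
               comp[, .(patientId, group, event, timeDays, followupDays)])
  out[, eventWithin1yr := event & timeDays <= 365]
  out[, followupDays := NULL]
  setorder(out, patientId, group)
  out[]
}
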