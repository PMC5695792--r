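# Shared fixtures: small simulated cohorts and independent oracles.
# Oracles are deliberately naive (per-day / per-event loops) so they stay
# independent of the vectorised implementations they check.

quickConfig <- function(n = 600, seed = 1, ...) {
  args <- utils::modifyList(
    list(nPatients = n, nLatentFactors = 5L, nCodeVars = 60L,
         nDrugVars = 40L, meanEventsPerKind = c(code = 20, drug = 20, lab = 1),
         seed = seed),
    list(...))
  do.call(simConfig, args)
}

# the factor-recovery experiment: 300 variables, 5 latent phenotypes,
# per-variable rates balanced across kinds so no kind dominates the
# Frobenius objective
recoveryConfig <- function(seed, n = 2000) {
  simConfig(nPatients = n, nLatentFactors = 5L, nCodeVars = 150L,
            nDrugVars = 144L, nLabVars = 6L,
            meanEventsPerKind = c(code = 40, drug = 40, lab = 1),
            seed = seed)
}

# build a claims table row-by-row with defaults
claimRow <- function(patientId, month, kind = "drug", code = "D1",
                     value = NA_real_, daysSupply = NA_integer_,
                     strength = NA_real_, newRefillFlag = NA) {
  data.table::data.table(patientId = patientId, month = as.integer(month),
                         kind = kind, code = code, value = value,
                         daysSupply = as.integer(daysSupply),
                         strength = strength, newRefillFlag = newRefillFlag)
}

claimsTable <- function(...) data.table::rbindlist(list(...))

demoRow <- function(patientId, age = 50) {
  data.table::data.table(patientId = patientId, age = age, female = 0L,
                         race = "white", tobacco = 0L,
                         pharmacyProgram = "retail")
}

# day-by-day PDC oracle: pills are stockpiled and consumed one per day
# starting at the fill day (months are 30 days); consumption may run past
# the follow-up horizon. PDC = covered days / follow-up days, capped at 1.
pdcDayOracle <- function(months, supplies, followupDays) {
  start <- (months - months[1]) * 30
  pills <- 0
  covered <- 0
  day <- 0
  horizon <- max(followupDays, max(start) + sum(supplies)) + 1
  while (day <= horizon) {
    pills <- pills + sum(supplies[start == day])
    if (pills > 0) {
      covered <- covered + 1
      pills <- pills - 1
    }
    day <- day + 1
    if (pills == 0 && day > max(start)) break
  }
  min(1, covered / followupDays)
}

# union-of-covered-days convention (no stockpiling): each fill covers
# [fill day, fill day + supply); overlapping coverage is not banked.
pdcUnionOracle <- function(months, supplies, followupDays) {
  start <- (months - months[1]) * 30
  covered <- logical(followupDays)
  for (i in seq_along(start)) {
    d <- seq(start[i], min(start[i] + supplies[i] - 1, followupDays - 1))
    d <- d[d >= 0 & d < followupDays]
    covered[d + 1] <- TRUE
  }
  sum(covered) / followupDays
}

# per-event double loop count-matrix oracle
bruteCountMatrix <- function(claims, cohort, windowMonths, excludeCodes) {
  cl <- as.data.frame(claims)
  out <- list()
  for (p in seq_len(nrow(cohort))) {
    pid <- cohort$patientId[p]
    thr <- cohort$thresholdMonth[p]
    for (i in seq_len(nrow(cl))) {
      if (cl$patientId[i] != pid) next
      if (cl$code[i] %in% excludeCodes) next
      if (cl$month[i] < thr - windowMonths + 1 || cl$month[i] > thr) next
      key <- paste(pid, cl$code[i], sep = "\r")
      out[[key]] <- (out[[key]] %||% 0) + 1
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# exact Cox partial log-likelihood (Breslow ties) for one covariate vector,
# maximised by generic 1-d optimisation
coxBreslowOracle <- function(time, event, x) {
  negll <- function(beta) {
    eta <- beta * x
    ll <- 0
    for (t in sort(unique(time[event == 1]))) {
      d <- which(time == t & event == 1)
      risk <- which(time >= t)
      ll <- ll + sum(eta[d]) - length(d) * log(sum(exp(eta[risk])))
    }
    -ll
  }
  stats::optimize(negll, c(-10, 10))$minimum
}
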