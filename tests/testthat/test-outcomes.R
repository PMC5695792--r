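test_that("PDC follows the supplied-days ratio definition", {
  one <- computePdc(data.frame(month = 0, daysSupply = 30), 365)
  expect_equal(one$pdc, 30 / 365)
  expect_false(one$adherent)
  expect_false(one$firstRefill)
  expect_equal(one$followupPdc, 0)

  full <- computePdc(data.frame(month = 0:11, daysSupply = rep(30, 12)), 360)
  expect_equal(full$pdc, 1)
  expect_true(full$adherent)
  expect_true(full$firstRefill)

  quarterly <- computePdc(data.frame(month = c(0, 3, 6, 9),
                                     daysSupply = rep(90, 4)), 360)
  expect_equal(quarterly$pdc, 1)
  expect_equal(pdcDayOracle(c(0, 3, 6, 9), rep(90, 4), 360), 1)

  expect_error(computePdc(data.frame(month = 0, daysSupply = -5), 365),
               "negative")
})

test_that("the adherence boundary is strict at 80%", {
  at <- computePdc(data.frame(month = 0, daysSupply = 292), 365)
  expect_equal(at$pdc, 0.8)
  expect_false(at$adherent)
  above <- computePdc(data.frame(month = 0, daysSupply = 293), 365)
  expect_true(above$adherent)
})

test_that("PDC matches the day-by-day stockpiling oracle on random schedules", {
  set.seed(51)
  for (i in 1:200) {
    nFills <- sample(1:12, 1)
    months <- sort(c(0, sample(1:24, nFills - 1)))
    supplies <- sample(c(30, 60, 90, 180), nFills, TRUE)
    fup <- sample(365:900, 1)
    got <- computePdc(data.frame(month = months, daysSupply = supplies), fup)
    expect_equal(got$pdc, pdcDayOracle(months, supplies, fup),
                 tolerance = 1e-12)
    ## the union-of-covered-days convention never exceeds the ratio
    expect_gte(got$pdc + 1e-12, pdcUnionOracle(months, supplies, fup))
  }
  ## overlapping fills: ratio strictly exceeds the union convention
  months <- c(0, 1); supplies <- c(90, 90); fup <- 365
  expect_gt(computePdc(data.frame(month = months, daysSupply = supplies),
                       fup)$pdc,
            pdcUnionOracle(months, supplies, fup))
})

test_that("follow-up PDC equals PDC of the shifted non-overlapping schedule", {
  set.seed(52)
  for (i in 1:50) {
    supplies <- sample(c(30, 60, 90), 5, TRUE)
    months <- cumsum(c(0, ceiling(supplies[-5] / 30)))   # contiguous refills
    fup <- sum(supplies) + sample(30:200, 1)
    got <- computePdc(data.frame(month = months, daysSupply = supplies), fup)
    shifted <- computePdc(data.frame(month = months[-1], daysSupply = supplies[-1]),
                          fup - supplies[1])
    expect_equal(got$followupPdc, shifted$pdc, tolerance = 1e-12)
  }
})

test_that("adding a fill never decreases PDC", {
  set.seed(53)
  for (i in 1:50) {
    months <- sort(c(0, sample(1:20, 4)))
    supplies <- sample(c(30, 60, 90), 5, TRUE)
    fup <- 700
    base <- computePdc(data.frame(month = months[-3], daysSupply = supplies[-3]),
                       fup)$pdc
    more <- computePdc(data.frame(month = months, daysSupply = supplies), fup)$pdc
    expect_gte(more, base)
  }
})

test_that("cholesterol change compares last-before to first-2-months-after", {
  cohort <- data.table::data.table(patientId = "A", thresholdMonth = 0L)
  cl <- claimsTable(
    claimRow("A", -1, kind = "lab", code = "LAB_LDL", value = 160),
    claimRow("A", 3, kind = "lab", code = "LAB_LDL", value = 120),
    claimRow("A", 8, kind = "lab", code = "LAB_LDL", value = 100),
    claimRow("A", 1, kind = "lab", code = "LAB_TC", value = 210)  # too early
  )
  lc <- lipidChange(cl, cohort)
  ldl <- lc[lc$analyte == "LAB_LDL", ]
  expect_equal(ldl$delta, -40)
  expect_true(ldl$decreased)
  tc <- lc[lc$analyte == "LAB_TC", ]
  expect_true(is.na(tc$followup))     # month +1 violates the 2-month rule
  expect_true(is.na(tc$decreased))
  ## no change is not a decrease (strict inequality)
  cl2 <- claimsTable(
    claimRow("A", 0, kind = "lab", code = "LAB_LDL", value = 130),
    claimRow("A", 4, kind = "lab", code = "LAB_LDL", value = 130)
  )
  expect_false(lipidChange(cl2, cohort)$decreased[1])
})

test_that("event outcomes censor at follow-up and pool the composite", {
  cohort <- data.table::data.table(patientId = c("A", "B"),
                                   thresholdMonth = 0L,
                                   followupDays = 1500)
  cl <- claimsTable(
    claimRow("A", 6, kind = "code", code = "HOSP_MI"),
    claimRow("A", 20, kind = "code", code = "HOSP_STROKE"),
    claimRow("B", 40, kind = "code", code = "VISIT")
  )
  ev <- eventOutcomes(cl, cohort)
  a <- function(g) ev[ev$patientId == "A" & ev$group == g, ]
  expect_true(a("MI")$event)
  expect_equal(a("MI")$timeDays, 180)
  expect_true(a("MI")$eventWithin1yr)
  expect_equal(a("STROKE")$timeDays, 600)
  expect_false(a("STROKE")$eventWithin1yr)
  expect_equal(a("COMPOSITE")$timeDays, 180)   # min over member groups
  expect_false(a("CAD")$event)
  expect_equal(a("CAD")$timeDays, 1500)
  b <- ev[ev$patientId == "B", ]
  expect_true(all(!b$event))
  expect_true(all(b$timeDays == 1500))

  badMap <- rbind(hospitalizationCodeMap(),
                  data.frame(code = "HOSP_MI", group = "STROKE"))
  expect_error(eventOutcomes(cl, cohort, badMap), "more than one group")
})

test_that("cohort-level adherence outcomes agree with per-patient PDC", {
  sim <- simulateEhr(quickConfig(n = 150, seed = 55))
  cs <- applyCohortFilters(sim$claims, sim$demographics, statinCodes())
  ao <- computeAdherenceOutcomes(sim$claims, cs$cohort, statinCodes())
  expect_equal(nrow(ao), nrow(cs$cohort))
  expect_true(all(ao$pdc >= 0 & ao$pdc <= 1))
  expect_identical(ao$adherent, ao$pdc > 0.8)
  ## spot-check three patients against a manual computePdc call
  cl <- data.table::as.data.table(sim$claims)
  for (pid in ao$patientId[c(1, 50, 100)]) {
    co <- cs$cohort[cs$cohort$patientId == pid, ]
    fills <- cl[patientId == pid & kind == "drug" &
                  code %in% statinCodes() & month >= co$thresholdMonth]
    data.table::setorder(fills, month)
    manual <- computePdc(as.data.frame(fills[, .(month, daysSupply)]),
                         co$followupDays)
    expect_equal(ao$pdc[ao$patientId == pid], manual$pdc)
    expect_equal(ao$followupPdc[ao$patientId == pid], manual$followupPdc)
  }
})
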