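statins <- c("S1", "S2")

test_that("first statin fill is the earliest flagged fill", {
  cl <- claimsTable(
    claimRow("A", 6, code = "S1", daysSupply = 30, newRefillFlag = TRUE),
    claimRow("A", 9, code = "S1", daysSupply = 30, newRefillFlag = TRUE),
    claimRow("B", 4, code = "D9", daysSupply = 30, newRefillFlag = TRUE),
    claimRow("C", 5, code = "S2", daysSupply = 30, newRefillFlag = FALSE)
  )
  thr <- identifyFirstStatin(cl, statins)
  expect_equal(thr$patientId, "A")          # B: no statin; C: refill flag off
  expect_equal(thr$thresholdMonth, 6L)
  ## enumerate flag combinations: only flagged fills can define a threshold
  for (flags in list(c(FALSE, FALSE), c(FALSE, TRUE), c(TRUE, TRUE))) {
    cl2 <- claimsTable(
      claimRow("Z", 3, code = "S1", daysSupply = 30, newRefillFlag = flags[1]),
      claimRow("Z", 8, code = "S1", daysSupply = 30, newRefillFlag = flags[2])
    )
    thr2 <- identifyFirstStatin(cl2, statins)
    expected <- c(3L, 8L)[flags]
    if (length(expected)) expect_equal(thr2$thresholdMonth, min(expected))
    else expect_equal(nrow(thr2), 0L)
  }
})

test_that("prescribing window restricts eligible first fills", {
  cl <- claimsTable(
    claimRow("A", 6, code = "S1", daysSupply = 30, newRefillFlag = TRUE),
    claimRow("A", 20, code = "S1", daysSupply = 30, newRefillFlag = TRUE)
  )
  expect_equal(identifyFirstStatin(cl, statins, window = c(10, 24))$thresholdMonth, 20L)
  expect_equal(nrow(identifyFirstStatin(cl, statins, window = c(30, 40))), 0L)
})

# one eligible patient plus one violator per exclusion rule
filterFixture <- function() {
  mkPatient <- function(id, age, thrMonth = 24, supply = 30L,
                        lastMonth = thrMonth + 13, priorStatinMonth = NULL) {
    rows <- list(
      claimRow(id, thrMonth, code = "S1", daysSupply = supply,
               newRefillFlag = TRUE),
      claimRow(id, lastMonth, kind = "code", code = "VISIT")
    )
    if (!is.null(priorStatinMonth))
      rows <- c(rows, list(claimRow(id, priorStatinMonth, code = "S2",
                                    daysSupply = 30, newRefillFlag = FALSE)))
    data.table::rbindlist(rows)
  }
  claims <- data.table::rbindlist(list(
    mkPatient("OK1", 50),
    mkPatient("OLD", 70),                        # age filter
    mkPatient("SUP", 50, supply = 45L),          # non-standard supply
    mkPatient("FUP", 50, lastMonth = 24 + 10),   # 10 months < 365 days
    mkPatient("PRI", 50, priorStatinMonth = 15), # statin 9 months before
    claimRow("NOS", 12, code = "D1", daysSupply = 30, newRefillFlag = TRUE)
  ))
  dem <- data.table::rbindlist(lapply(
    c("OK1", "OLD", "SUP", "FUP", "PRI", "NOS"), demoRow))
  dem$age <- c(50, 70, 50, 50, 50, 50)
  list(claims = claims, dem = dem)
}

test_that("exclusion rules fire in order and tally to the input count", {
  fx <- filterFixture()
  res <- applyCohortFilters(fx$claims, fx$dem, statins)
  expect_equal(res$cohort$patientId, "OK1")
  expect_equal(unname(res$tally[c("noFirstStatin", "priorStatin12mo", "age",
                                  "daysSupply", "followup")]),
               c(1L, 1L, 1L, 1L, 1L))
  expect_equal(sum(res$tally) + nrow(res$cohort), nrow(fx$dem))
  ## 10 months of follow-up is 300 days, under the 365-day floor
  expect_equal(unname(res$tally["followup"]), 1L)
  ## retained row carries first-fill characteristics and follow-up
  expect_equal(res$cohort$firstStatinDaysSupply, 30L)
  expect_equal(res$cohort$followupDays, 13 * 30)
})

test_that("filtering is idempotent", {
  fx <- filterFixture()
  res1 <- applyCohortFilters(fx$claims, fx$dem, statins)
  keep <- res1$cohort$patientId
  res2 <- applyCohortFilters(fx$claims[fx$claims$patientId %in% keep, ],
                             fx$dem[fx$dem$patientId %in% keep, ], statins)
  expect_equal(as.data.frame(res2$cohort), as.data.frame(res1$cohort))
  expect_true(all(res2$tally == 0L))
})

test_that("empty cohorts are returned, not raised", {
  cl <- claimRow("A", 5, code = "D1", daysSupply = 30, newRefillFlag = TRUE)
  res <- applyCohortFilters(cl, demoRow("A"), statins)
  expect_equal(nrow(res$cohort), 0L)
  expect_equal(unname(res$tally["noFirstStatin"]), 1L)
})

test_that("cohort summary detects a planted age difference", {
  set.seed(1)
  n <- 5000
  adherent <- rep(c(TRUE, FALSE), length.out = n)
  cohort <- data.frame(age = rnorm(n, 50, 8) + 5 * adherent,
                       tobacco = rbinom(n, 1, 0.05))
  out <- cohortSummary(cohort, adherent, strataNames = c("adh", "non"))
  expect_lt(out$pValue[out$variable == "age"], 1e-3)
  expect_gt(out$adh[out$variable == "age"] - out$non[out$variable == "age"], 4)
})

test_that("cohort summary p-values are calibrated under the null", {
  set.seed(2)
  n <- 400
  stratum <- rep(c(TRUE, FALSE), each = n / 2)
  vars <- as.data.frame(matrix(rnorm(n * 100), n, 100))
  out <- cohortSummary(vars, stratum)
  expect_equal(nrow(out), 100L)
  expect_gt(ks.test(out$pValue, "punif")$p.value, 0.01)
})

test_that("degenerate summary inputs are reported, not errors", {
  cohort <- data.frame(allMissing = rep(NA_real_, 10),
                       constant = rep(1, 10),
                       x = c(rnorm(9), NA))
  out <- cohortSummary(cohort, rep(c(TRUE, FALSE), 5))
  expect_equal(out$nMissing[out$variable == "allMissing"], 10L)
  expect_true(is.na(out$pValue[out$variable == "allMissing"]))
  expect_true(is.na(out$pValue[out$variable == "constant"]))
  expect_equal(out$nMissing[out$variable == "x"], 1L)
  ## a stratum with < 2 patients cannot be tested
  out2 <- cohortSummary(data.frame(x = rnorm(5)),
                        c(TRUE, rep(FALSE, 4)))
  expect_true(is.na(out2$pValue))
})
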