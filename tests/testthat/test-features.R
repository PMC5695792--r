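test_that("count matrix equals the per-event double-loop oracle", {
  sim <- simulateEhr(quickConfig(n = 60, seed = 31))
  cs <- applyCohortFilters(sim$claims, sim$demographics, statinCodes())
  cohort <- cs$cohort[1:20, ]
  cm <- buildCountMatrix(sim$claims, cohort, windowMonths = 6, minPatients = 1)
  oracle <- bruteCountMatrix(sim$claims, cohort, 6, statinCodes())
  m <- as.matrix(SummarizedExperiment::assay(cm))
  for (p in colnames(m)) for (v in rownames(m)) {
    expect_equal(unname(m[v, p]), oracle[[paste(p, v, sep = "\r")]] %||% 0)
  }
  ## and nothing in the oracle is missing from the matrix
  expect_equal(sum(m), sum(unlist(oracle)))
})

test_that("variables below the patient-prevalence floor are dropped", {
  rows <- list()
  for (i in 1:10) {
    rows <- c(rows, list(
      claimRow(paste0("P", i), 10, kind = "code", code = "COMMON"),
      claimRow(paste0("P", i), 12, code = "S1", daysSupply = 30,
               newRefillFlag = TRUE)
    ))
  }
  for (i in 1:5)
    rows <- c(rows, list(claimRow(paste0("P", i), 9, kind = "code", code = "RARE")))
  cl <- data.table::rbindlist(rows)
  cohort <- data.table::data.table(patientId = paste0("P", 1:10),
                                   thresholdMonth = 12L)
  cm5 <- buildCountMatrix(cl, cohort, minPatients = 5, excludeCodes = "S1")
  cm6 <- buildCountMatrix(cl, cohort, minPatients = 6, excludeCodes = "S1")
  expect_setequal(rownames(cm5), c("COMMON", "RARE"))
  expect_setequal(rownames(cm6), "COMMON")
  expect_error(buildCountMatrix(cl, cohort, windowMonths = 0), "positive")
})

test_that("relaxing the prevalence filter never loses variables", {
  sim <- simulateEhr(quickConfig(n = 200, seed = 37))
  cs <- applyCohortFilters(sim$claims, sim$demographics, statinCodes())
  n1 <- nrow(buildCountMatrix(sim$claims, cs$cohort, minPatients = 1))
  n20 <- nrow(buildCountMatrix(sim$claims, cs$cohort, minPatients = 20))
  expect_gte(n1, n20)
})

test_that("baseline labs pick the most recent in-lookback value", {
  cohort <- data.table::data.table(patientId = "A", thresholdMonth = 24L)
  cl <- claimsTable(
    claimRow("A", 21, kind = "lab", code = "LDL", value = 160),
    claimRow("A", 23, kind = "lab", code = "LDL", value = 120),
    claimRow("A", 24, kind = "lab", code = "HDL", value = 55),   # at threshold
    claimRow("A", 24 - 30, kind = "lab", code = "TG", value = 99), # too old
    claimRow("A", 30, kind = "lab", code = "CK", value = 70)     # after threshold
  )
  labs <- extractBaselineLabs(cl, cohort)
  expect_equal(labs$value[labs$analyte == "LDL"], 120)
  expect_equal(labs$monthMeasured[labs$analyte == "LDL"], 23L)
  expect_equal(labs$value[labs$analyte == "HDL"], 55)
  expect_false("TG" %in% labs$analyte)
  expect_false("CK" %in% labs$analyte)
  ## same-month tie: last record in file order wins
  cl2 <- claimsTable(
    claimRow("A", 24, kind = "lab", code = "LDL", value = 100),
    claimRow("A", 24, kind = "lab", code = "LDL", value = 111)
  )
  expect_equal(extractBaselineLabs(cl2, cohort)$value, 111)
})

test_that("prior PDC follows the supplied-days ratio with a 2-month floor", {
  cohort <- data.table::data.table(patientId = "A", thresholdMonth = 0L)
  perfect <- claimsTable(
    claimRow("A", -6, code = "D1", daysSupply = 30),
    claimRow("A", -5, code = "D1", daysSupply = 30),
    claimRow("A", -4, code = "D1", daysSupply = 30),
    claimRow("A", -3, code = "D1", daysSupply = 30),
    claimRow("A", -2, code = "D1", daysSupply = 30),
    claimRow("A", -1, code = "D1", daysSupply = 30),
    claimRow("A", -6, code = "D2", daysSupply = 30),
    claimRow("A", -1, code = "D3", daysSupply = 30),  # < 2 months of history
    claimRow("A", -4, code = "S1", daysSupply = 30)   # statin: excluded
  )
  pdc <- computePriorPdc(perfect, cohort, statinCodes = "S1")
  expect_equal(pdc$priorPdc[pdc$code == "D1"], 1.0)
  expect_equal(pdc$priorPdc[pdc$code == "D2"], 30 / 180)
  expect_false("D3" %in% pdc$code)
  expect_false("S1" %in% pdc$code)
})

test_that("prior PDC stays in [0, 1] and the cap binds only from above", {
  set.seed(41)
  for (i in 1:25) {
    nFills <- sample(1:8, 1)
    months <- sort(sample(-24:-2, nFills))
    supplies <- sample(c(30, 60, 90), nFills, TRUE)
    cl <- data.table::rbindlist(lapply(seq_len(nFills), function(j)
      claimRow("A", months[j], code = "D1", daysSupply = supplies[j])))
    cohort <- data.table::data.table(patientId = "A", thresholdMonth = 0L)
    got <- computePriorPdc(cl, cohort, statinCodes = character())$priorPdc
    raw <- sum(supplies) / (-min(months) * 30)
    expect_gte(got, 0); expect_lte(got, 1)
    expect_equal(got, min(1, raw))
    expect_gte(raw, got)
  }
})

test_that("interaction counts enumerate in-window events by kind", {
  cohort <- data.table::data.table(patientId = c("A", "B"),
                                   thresholdMonth = c(24L, 24L))
  cl <- claimsTable(
    claimRow("A", 20, kind = "lab", code = "LDL", value = 1),
    claimRow("A", 22, kind = "lab", code = "LDL", value = 1),
    claimRow("A", 18, code = "D1", daysSupply = 30),
    claimRow("A", 19, code = "D1", daysSupply = 30),
    claimRow("A", 20, code = "D2", daysSupply = 30),
    claimRow("A", 21, code = "D2", daysSupply = 30),
    claimRow("A", 24, code = "D2", daysSupply = 30),
    claimRow("A", 23, kind = "code", code = "C1"),
    claimRow("A", 2, kind = "code", code = "C1"),    # outside 12-month window
    claimRow("A", 30, kind = "code", code = "C1")    # after threshold
  )
  ic <- interactionCounts(cl, cohort, excludeCodes = character())
  a <- ic[ic$patientId == "A", ]
  expect_equal(c(a$nLabs, a$nDrugs, a$nCodes), c(2L, 5L, 1L))
  expect_equal(unlist(ic[ic$patientId == "B", c("nLabs", "nDrugs", "nCodes")]),
               c(nLabs = 0L, nDrugs = 0L, nCodes = 0L))
  ## row-order invariance
  perm <- cl[sample(nrow(cl)), ]
  expect_equal(as.data.frame(interactionCounts(perm, cohort,
                                               excludeCodes = character())),
               as.data.frame(ic))
})
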