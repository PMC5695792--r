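test_that("coin-flip labels give a c-statistic near one half", {
  set.seed(71)
  n <- 1000
  x <- as.data.frame(matrix(rnorm(n * 5), n, 5))
  y <- rbinom(n, 1, 0.5) == 1
  fit <- fitAdherence(x, y, nFolds = 10, seed = 1, numTrees = 150)
  expect_lt(abs(fit$cvAuc - 0.5), 0.04)
})

test_that("a deterministic threshold label is learned almost perfectly", {
  set.seed(72)
  n <- 800
  x <- as.data.frame(matrix(rnorm(n * 4), n, 4))
  fit <- fitAdherence(x, x[[2]] > 0, nFolds = 10, seed = 2, numTrees = 150)
  expect_gte(fit$cvAuc, 0.99)
})

test_that("label preconditions are enforced", {
  x <- data.frame(a = rnorm(20))
  expect_error(fitAdherence(x, rep(TRUE, 20)), "single-class")
  expect_error(fitAdherence(x, c(NA, rbinom(19, 1, 0.5)) == 1), "missing")
})

test_that("the rank c-statistic equals trapezoidal ROC integration", {
  set.seed(73)
  for (i in 1:10) {
    score <- c(rnorm(150), sample(rnorm(10), 50, TRUE))   # with ties
    label <- rbinom(200, 1, plogis(score)) == 1
    if (length(unique(label)) < 2) next
    expect_lt(abs(cStatistic(score, label) -
                    trapezoidAuc(rocPoints(score, label))), 1e-10)
  }
})

test_that("missing features are imputed with indicators, fold by fold", {
  set.seed(74)
  n <- 600
  x <- data.frame(a = rnorm(n), b = rnorm(n))
  x$a[sample(n, 100)] <- NA
  y <- rbinom(n, 1, plogis(x$b)) == 1
  fit <- fitAdherence(x, y, nFolds = 5, seed = 3, numTrees = 100)
  expect_false(anyNA(fit$oofProb))
  expect_gt(fit$cvAuc, 0.6)
})

test_that("withheld-variable importance isolates the signal column", {
  set.seed(91)
  n <- 2000
  x <- data.frame(signal = rnorm(n), n1 = rnorm(n), n2 = rnorm(n),
                  n3 = rnorm(n))
  ## log-OR 1 on one standard-normal column: the fitted forest reaches a
  ## cross-validated AUC near 0.7, and that column carries all of it
  y <- rbinom(n, 1, plogis(x$signal)) == 1
  imp <- variableImportance(x, y, nFolds = 10, seed = 4, numTrees = 300)
  expect_equal(imp$variable[1], "signal")
  sig <- imp[imp$variable == "signal", ]
  expect_lt(abs(sig$aucWithout - 0.5), 0.05)     # nothing left to learn
  expect_gt(sig$deltaAuc, 0.15)
  noise <- imp[imp$variable != "signal", ]
  expect_lt(max(abs(noise$deltaAuc)), 0.02)
  expect_equal(nrow(imp), 4L)
})

test_that("grouped withholding treats a factor's columns as one unit", {
  set.seed(76)
  n <- 600
  x <- data.frame(f1a = rnorm(n), f1b = rnorm(n), other = rnorm(n))
  y <- rbinom(n, 1, plogis(0.6 * (x$f1a + x$f1b))) == 1
  imp <- variableImportance(x, y, nFolds = 5, seed = 5, numTrees = 100,
                            groups = list(factor1 = c("f1a", "f1b"),
                                          other = "other"))
  expect_equal(nrow(imp), 2L)
  expect_equal(imp$variable[1], "factor1")
  expect_gt(imp$deltaAuc[1], 0.1)
})

test_that("factor association recovers a planted log-odds effect", {
  set.seed(77)
  n <- 5000
  S <- matrix(rexp(n * 3), n, 3, dimnames = list(NULL, paste0("factor", 1:3)))
  covs <- data.frame(age = rnorm(n, 50, 8))
  risk <- runif(n)
  eta <- -1 + 0.5 * scale(S[, 1])[, 1] + 0.02 * (covs$age - 50)
  y <- rbinom(n, 1, plogis(eta)) == 1
  out <- factorAssociation(y, S, covs, risk)
  expect_equal(out$direction[1], "higher")
  expect_lt(out$pValue[1], 1e-3)
  expect_gt(min(out$pValue[2:3]), 1e-3)
})

test_that("factor-association p-values are calibrated under the null", {
  set.seed(78)
  ps <- replicate(100, {
    n <- 300
    S <- matrix(rexp(n), n, 1, dimnames = list(NULL, "factor1"))
    y <- rbinom(n, 1, 0.3) == 1
    factorAssociation(y, S, data.frame(age = rnorm(n)), runif(n))$pValue
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("adjustment absorbs a factor that only tracks disease risk", {
  set.seed(79)
  nonsig <- replicate(20, {
    n <- 800
    f <- rnorm(n)
    risk <- plogis(f + rnorm(n, 0, 0.5))      # factor drives risk only
    y <- rbinom(n, 1, risk) == 1              # adherence depends on risk alone
    factorAssociation(y, matrix(f, ncol = 1), data.frame(age = rnorm(n)),
                      risk)$pValue > 0.05
  })
  expect_gte(sum(nonsig), 18L)
})

test_that("the first-refill indicator adds discrimination beyond baseline", {
  ## discontinuation is unobserved heterogeneity: baseline covariates cannot
  ## predict it, but the realized first refill reveals it, so adding the
  ## indicator (with the outcome recomputed on the post-first-supply window)
  ## must increase the cross-validated AUC
  sim <- simulateEhr(simConfig(
    nPatients = 2000, nLatentFactors = 4L, nCodeVars = 40L, nDrugVars = 20L,
    meanEventsPerKind = c(code = 15, drug = 15, lab = 1),
    pDiscontinue = 0.25, seed = 131))
  cs <- applyCohortFilters(sim$claims, sim$demographics, statinCodes())
  co <- cs$cohort
  ao <- computeAdherenceOutcomes(sim$claims, co, statinCodes())
  ao <- ao[match(co$patientId, ao$patientId)]
  feats <- data.frame(age = co$age, female = co$female, tobacco = co$tobacco,
                      nLabs = co$nLabs, nDrugs = co$nDrugs, nCodes = co$nCodes)
  yFup <- ao$followupPdc > 0.8
  without <- fitAdherence(feats, yFup, nFolds = 10, seed = 5, numTrees = 200)
  with <- fitAdherence(cbind(feats, firstRefill = as.numeric(ao$firstRefill)),
                       yFup, nFolds = 10, seed = 5, numTrees = 200)
  expect_gt(with$cvAuc, without$cvAuc)
})

test_that("degenerate designs are reported as not estimable", {
  set.seed(80)
  n <- 100
  S <- matrix(0, n, 1, dimnames = list(NULL, "factor1"))   # constant score
  out <- factorAssociation(rbinom(n, 1, 0.5) == 1, S,
                           data.frame(a = rnorm(n)), runif(n))
  expect_true(is.na(out$estimate))
  expect_true(is.na(out$direction))
  expect_true(is.na(out$pValue))
})
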