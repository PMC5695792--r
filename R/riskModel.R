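## Multi-outcome logistic regression with strength borrowing.
##
## Related, individually rare hospitalization outcomes are modelled jointly:
## each outcome's coefficient vector is decomposed as a shared across-outcome
## mean plus an outcome-specific deviation, with a ridge penalty on the
## deviations (strong) and on the mean (weak). As the deviation penalty grows
## the outcomes coalesce onto one common model; as both penalties vanish the
## fit approaches independent logistic regressions.

# negative penalized log-likelihood and gradient; par = c(a_G, mu_p, delta_pG)
multiLogisticObjective_ <- function(par, X, Y, lambdaDelta, lambdaMu) {
  n <- nrow(X); p <- ncol(X); G <- ncol(Y)
  a <- par[seq_len(G)]
  mu <- par[G + seq_len(p)]
  delta <- matrix(par[G + p + seq_len(p * G)], p, G)
  beta <- delta + mu
  eta <- sweep(X %*% beta, 2, a, "+")
  ## stable log(1 + exp(eta))
  lse <- pmax(eta, 0) + log1p(exp(-abs(eta)))
  nll <- -sum(Y * eta - lse) +
    lambdaDelta / 2 * sum(delta^2) + lambdaMu / 2 * sum(mu^2) +
    1e-8 / 2 * sum(a^2)
  P <- plogis(eta)
  R <- P - Y                                  # n x G
  gA <- colSums(R) + 1e-8 * a
  XtR <- crossprod(X, R)                      # p x G
  gMu <- rowSums(XtR) + lambdaMu * mu
  gDelta <- XtR + lambdaDelta * delta
  structure(nll, gradient = c(gA, gMu, as.numeric(gDelta)))
}

fitMultiLogistic_ <- function(X, Y, lambdaDelta, lambdaMu, start = NULL,
                              maxit = 200L) {
  p <- ncol(X); G <- ncol(Y)
  if (is.null(start)) start <- rep(0, G + p + p * G)
  fn <- function(par) as.numeric(multiLogisticObjective_(par, X, Y, lambdaDelta, lambdaMu))
  gr <- function(par) attr(multiLogisticObjective_(par, X, Y, lambdaDelta, lambdaMu), "gradient")
  opt <- optim(start, fn, gr, method = "L-BFGS-B",
               control = list(maxit = maxit, factr = 1e4))
  a <- opt$par[seq_len(G)]
  mu <- opt$par[G + seq_len(p)]
  delta <- matrix(opt$par[G + p + seq_len(p * G)], p, G)
  list(par = opt$par, intercepts = a, mu = mu, delta = delta,
       beta = delta + mu, value = opt$value)
}

predictMultiLogistic_ <- function(fit, X) {
  plogis(sweep(X %*% fit$beta, 2, fit$intercepts, "+"))
}

logLoss_ <- function(P, Y) {
  eps <- 1e-12
  -mean(Y * log(pmax(P, eps)) + (1 - Y) * log(pmax(1 - P, eps)))
}

standardize_ <- function(X, center = NULL, scale = NULL) {
  if (is.null(center)) {
    center <- colMeans(X)
    scale <- apply(X, 2, stats::sd)
    scale[scale == 0 | !is.finite(scale)] <- 1
  }
  list(X = sweep(sweep(X, 2, center, "-"), 2, scale, "/"),
       center = center, scale = scale)
}

designMatrix_ <- function(design) {
  if (is.matrix(design)) return(design)
  df <- as.data.frame(design)
  df <- imputeByTrainingMedian(df, seq_len(nrow(df)))  # median + indicator
  for (nm in names(df)) if (is.character(df[[nm]])) df[[nm]] <- factor(df[[nm]])
  X <- model.matrix(~., data = df)
  X[, colnames(X) != "(Intercept)", drop = FALSE]
}

#' Disease-risk model: cross-validated multi-outcome penalized logistic fit
#'
#' Predicts several related binary hospitalization outcomes (by default
#' event-within-1-year for each diagnosis group) from a shared design,
#' borrowing strength across outcomes: coefficients are shrunk toward a
#' shared across-outcome mean vector (ridge on the per-outcome deviations
#' plus a weak ridge on the mean). The deviation penalty is chosen by
#' nested cross-validation on multi-outcome log-loss within each training
#' fold. Every patient's risk score is out-of-fold: produced by a model
#' whose training data excluded that patient.
#'
#' @param design numeric matrix or data.frame of per-patient covariates
#'   (demographics, statin characteristics, interaction counts, factor
#'   scores). Factors are expanded via `model.matrix`; columns are
#'   standardised using training-fold statistics.
#' @param labels matrix or data.frame of 0/1 outcomes, one column per
#'   diagnosis group (at least 2 columns).
#' @param nFolds number of cross-validation folds, default 30.
#' @param seed fold-assignment seed.
#' @param lambdaGrid candidate deviation-ridge strengths.
#' @param muRidgeFraction weak ridge on the shared mean, as a fraction of
#'   the deviation ridge.
#' @param innerFolds folds for the nested hyperparameter search.
#' @param maxit optimizer iteration cap per fit.
#' @return list of class `"riskFit"`: `oofProb` (n x G out-of-fold
#'   probabilities), `composite` (probability of any event,
#'   `1 - prod(1 - p_g)`), `folds`, `cvAuc` per outcome and for the pooled
#'   any-event label, `lambdaByFold`, and `model` (a final fit on all data
#'   at the modal chosen lambda, for coefficient inspection).
#' @export
fitDiseaseRisk <- function(design, labels, nFolds = 30L, seed = 1L,
                           lambdaGrid = c(0.5, 5, 50),
                           muRidgeFraction = 0.01,
                           innerFolds = 5L, maxit = 200L) {
  X0 <- designMatrix_(design)
  Y <- as.matrix(labels) * 1
  if (ncol(Y) < 2) stop("need at least 2 outcomes to borrow strength across")
  if (!all(Y %in% c(0, 1))) stop("labels must be binary")
  n <- nrow(X0)
  stopifnot(nrow(Y) == n)
  folds <- assignFolds(seq_len(n), nFolds, seed)
  oof <- matrix(NA_real_, n, ncol(Y), dimnames = list(rownames(X0), colnames(Y)))
  lambdaByFold <- numeric(nFolds)
  for (f in seq_len(nFolds)) {
    tr <- which(folds != f); te <- which(folds == f)
    std <- standardize_(X0[tr, , drop = FALSE])
    Xtr <- std$X; Ytr <- Y[tr, , drop = FALSE]
    lam <- chooseLambda_(Xtr, Ytr, lambdaGrid, muRidgeFraction, innerFolds,
                         seed + f, maxit)
    fit <- fitMultiLogistic_(Xtr, Ytr, lam, muRidgeFraction * lam, maxit = maxit)
    Xte <- standardize_(X0[te, , drop = FALSE], std$center, std$scale)$X
    oof[te, ] <- predictMultiLogistic_(fit, Xte)
    lambdaByFold[f] <- lam
  }
  composite <- 1 - apply(1 - oof, 1, prod)
  anyEvent <- as.logical(apply(Y, 1, max))
  cvAuc <- c(
    vapply(seq_len(ncol(Y)), function(g)
      if (length(unique(Y[, g])) == 2) cStatistic(oof[, g], Y[, g]) else NA_real_,
      numeric(1)),
    composite = if (length(unique(anyEvent)) == 2)
      cStatistic(composite, anyEvent) else NA_real_
  )
  names(cvAuc) <- c(colnames(Y), "composite")
  lamFinal <- as.numeric(names(sort(table(lambdaByFold), decreasing = TRUE))[1])
  stdAll <- standardize_(X0)
  final <- fitMultiLogistic_(stdAll$X, Y, lamFinal, muRidgeFraction * lamFinal,
                             maxit = maxit)
  structure(list(
    oofProb = oof, composite = composite, folds = folds, cvAuc = cvAuc,
    lambdaByFold = lambdaByFold, model = final,
    standardization = stdAll[c("center", "scale")], outcomes = colnames(Y)
  ), class = "riskFit")
}

chooseLambda_ <- function(X, Y, lambdaGrid, muRidgeFraction, innerFolds,
                          seed, maxit) {
  if (length(lambdaGrid) == 1L) return(lambdaGrid)
  inner <- assignFolds(seq_len(nrow(X)), innerFolds, seed)
  loss <- matrix(NA_real_, innerFolds, length(lambdaGrid))
  for (f in seq_len(innerFolds)) {
    tr <- which(inner != f); te <- which(inner == f)
    start <- NULL
    for (j in seq_along(lambdaGrid)) {
      lam <- lambdaGrid[j]
      fit <- fitMultiLogistic_(X[tr, , drop = FALSE], Y[tr, , drop = FALSE],
                               lam, muRidgeFraction * lam,
                               start = start, maxit = maxit)
      start <- fit$par
      P <- predictMultiLogistic_(fit, X[te, , drop = FALSE])
      loss[f, j] <- logLoss_(P, Y[te, , drop = FALSE])
    }
  }
  lambdaGrid[which.min(colMeans(loss))]
}

#' Kaplan-Meier curves and log-rank test across score tertiles
#'
#' Cuts a continuous score (out-of-fold composite disease risk, or
#' predicted adherence) at its empirical tertiles, estimates a
#' Kaplan-Meier curve per tertile, and tests equality with the 2-df
#' log-rank test.
#'
#' @param score per-patient continuous score.
#' @param timeDays,event aligned event time (days) and indicator.
#' @return list: `tertile` (factor T1 < T2 < T3), `fit` (a
#'   [survival::survfit] object), `logRankP` (`NA` when not computable,
#'   e.g. all observations censored), `eventsByTertile`.
#' @export
tertileKm <- function(score, timeDays, event) {
  stopifnot(length(score) == length(timeDays), length(score) == length(event))
  if (length(unique(score)) < 3) stop("need at least 3 distinct score values")
  cuts <- quantile(score, c(1, 2) / 3, names = FALSE, type = 7)
  tertile <- cut(score, c(-Inf, cuts, Inf), labels = c("T1", "T2", "T3"))
  df <- data.frame(timeDays = timeDays, event = as.integer(event),
                   tertile = tertile)
  fit <- survfit(Surv(timeDays, event) ~ tertile, data = df)
  logRankP <- NA_real_
  if (sum(df$event) > 0 && length(unique(tertile[df$event == 1])) >= 1) {
    lr <- try(survdiff(Surv(timeDays, event) ~ tertile, data = df), silent = TRUE)
    if (!inherits(lr, "try-error"))
      logRankP <- pchisq(lr$chisq, df = length(lr$n) - 1, lower.tail = FALSE)
  }
  list(tertile = tertile, fit = fit, logRankP = logRankP,
       eventsByTertile = tapply(df$event, tertile, sum))
}

#' @rdname tertileKm
#' @param riskFit a `"riskFit"` from [fitDiseaseRisk()].
#' @param eventOutcome long table from [eventOutcomes()]; the `"COMPOSITE"`
#'   rows are used, aligned to the rows of the risk fit by `patientId`.
#' @export
riskTertileKm <- function(riskFit, eventOutcome) {
  comp <- as.data.table(eventOutcome)[group == "COMPOSITE"]
  comp <- comp[match(rownames(riskFit$oofProb), patientId)]
  if (anyNA(comp$patientId)) stop("event outcomes missing for some patients")
  tertileKm(riskFit$composite, comp$timeDays, comp$event)
}
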