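#' Cross-validated random-forest adherence model
#'
#' Predicts the binary adherence label (PDC > 80%, or its follow-up-window
#' variant when the first-refill indicator is included as a feature) with a
#' probability random forest, under patient-level K-fold cross-validation:
#' each fold's forest is trained on the other folds and predicts the held
#' out patients, and the pooled out-of-fold probabilities give the
#' cross-validated ROC and c-statistic. Missing numeric features are
#' imputed by the training-fold median with an appended missingness
#' indicator column.
#'
#' @param features data.frame of per-patient predictors (numeric, logical,
#'   character/factor).
#' @param labels logical (or 0/1) adherence outcome, no missing values.
#' @param nFolds folds, default 30.
#' @param seed seed for fold assignment and tree randomness.
#' @param numTrees trees per forest, default 500.
#' @param mtry features per split; default `floor(sqrt(p))`.
#' @param minNodeSize minimal terminal-node size; `NULL` uses ranger's
#'   default. Larger nodes give smoother probability estimates, which can
#'   sharpen the ranking (AUC) when the signal is weak and smooth.
#' @return list of class `"adherenceFit"`: `oofProb`, `folds`, `cvAuc`,
#'   `roc` (points from [rocPoints()]), `nFolds`, `featureNames`.
#' @export
fitAdherence <- function(features, labels, nFolds = 30L, seed = 1L,
                         numTrees = 500L, mtry = NULL, minNodeSize = NULL) {
  x <- as.data.frame(features)
  y <- as.logical(labels)
  stopifnot(nrow(x) == length(y))
  if (anyNA(y)) stop("labels must not be missing")
  if (length(unique(y)) < 2) stop("labels are single-class")
  for (nm in names(x)) if (is.character(x[[nm]])) x[[nm]] <- factor(x[[nm]])
  n <- nrow(x)
  folds <- assignFolds(seq_len(n), nFolds, seed)
  oof <- rep(NA_real_, n)
  for (f in seq_len(nFolds)) {
    tr <- which(folds != f); te <- which(folds == f)
    xi <- imputeByTrainingMedian(x, tr)
    dtr <- data.frame(.y = factor(y[tr], c(FALSE, TRUE)),
                      xi[tr, , drop = FALSE])
    rf <- ranger(.y ~ ., data = dtr, probability = TRUE,
                 num.trees = numTrees,
                 mtry = min(mtry %||% max(1L, floor(sqrt(ncol(xi)))), ncol(xi)),
                 min.node.size = minNodeSize,
                 seed = seed + f, num.threads = 1L,
                 respect.unordered.factors = "order")
    oof[te] <- predict(rf, data = xi[te, , drop = FALSE],
                       num.threads = 1L)$predictions[, "TRUE"]
  }
  roc <- rocPoints(oof, y)
  structure(list(
    oofProb = oof, folds = folds, cvAuc = cStatistic(oof, y), roc = roc,
    nFolds = nFolds, featureNames = names(x), labels = y, seed = seed
  ), class = "adherenceFit")
}

#' Leave-one-covariate-out variable importance (delta AUC)
#'
#' For each variable (or named group of variables), reruns the full
#' cross-validated forest pipeline with that variable withheld and reports
#' `deltaAuc = AUC(all) - AUC(without)`. The fold assignment (same seed) is
#' shared across runs so differences reflect the withheld variable, not
#' fold noise. This is a full refit, not permutation importance: it
#' measures what the model loses when the information is truly absent.
#'
#' @param features,labels,nFolds,seed,numTrees,mtry,minNodeSize as
#'   [fitAdherence()].
#' @param groups optional named list mapping a display name to the column
#'   names it spans (e.g. one entry per factor); default one group per
#'   column.
#' @return data.table (`variable`, `aucWithout`, `deltaAuc`), sorted by
#'   decreasing `deltaAuc`; attribute `"aucAll"` carries the full-model
#'   AUC.
#' @export
variableImportance <- function(features, labels, nFolds = 30L, seed = 1L,
                               numTrees = 500L, mtry = NULL,
                               minNodeSize = NULL, groups = NULL) {
  x <- as.data.frame(features)
  if (is.null(groups)) groups <- setNames(as.list(names(x)), names(x))
  full <- fitAdherence(x, labels, nFolds, seed, numTrees, mtry, minNodeSize)
  rows <- lapply(names(groups), function(g) {
    keep <- setdiff(names(x), groups[[g]])
    if (!length(keep)) stop("cannot withhold every feature")
    fit <- fitAdherence(x[, keep, drop = FALSE], labels, nFolds, seed,
                        numTrees, mtry, minNodeSize)
    data.table(variable = g, aucWithout = fit$cvAuc,
               deltaAuc = full$cvAuc - fit$cvAuc)
  })
  out <- rbindlist(rows)
  setorder(out, -deltaAuc)
  structure(out[], aucAll = full$cvAuc)
}

#' Covariate-adjusted association between one factor and adherence
#'
#' Logistic regression of the adherence indicator on each factor score in
#' turn, controlling for all patient/statin characteristics and the
#' composite disease-risk score; reports the factor coefficient's sign and
#' Wald p-value. Degenerate designs (collinearity producing an inestimable
#' factor coefficient) are reported as not estimable rather than failing.
#'
#' @param adherent logical adherence label.
#' @param factorScores patients x K matrix of factor scores.
#' @param covariates data.frame of patient/statin covariates (missing
#'   numeric values are median-imputed with indicators).
#' @param diseaseRisk per-patient composite disease-risk probability.
#' @return data.table: `factor`, `estimate`, `direction` (`"higher"` /
#'   `"lower"` adherence), `pValue`.
#' @export
factorAssociation <- function(adherent, factorScores, covariates, diseaseRisk) {
  y <- as.logical(adherent)
  S <- as.matrix(factorScores)
  stopifnot(length(y) == nrow(S), length(diseaseRisk) == length(y))
  covs <- imputeByTrainingMedian(as.data.frame(covariates), seq_along(y))
  for (nm in names(covs)) if (is.character(covs[[nm]]))
    covs[[nm]] <- factor(covs[[nm]])
  base <- data.frame(covs, .risk = diseaseRisk)
  rows <- lapply(seq_len(ncol(S)), function(j) {
    df <- data.frame(.y = y, .score = S[, j], base)
    fit <- try(suppressWarnings(glm(.y ~ ., data = df, family = binomial())),
               silent = TRUE)
    est <- p <- NA_real_
    if (!inherits(fit, "try-error")) {
      cf <- summary(fit)$coefficients
      if (".score" %in% rownames(cf) && !is.na(coef(fit)[".score"])) {
        est <- cf[".score", "Estimate"]
        p <- cf[".score", "Pr(>|z|)"]
      }
    }
    data.table(
      factor = colnames(S)[j] %||% paste0("factor", j),
      estimate = est,
      direction = if (is.na(est)) NA_character_ else
        if (est > 0) "higher" else "lower",
      pValue = p
    )
  })
  rbindlist(rows)
}
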