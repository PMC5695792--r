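#' ClaimCountMatrix: pre-treatment claim-count matrix
#'
#' A [SummarizedExperiment::SummarizedExperiment] holding nonnegative integer
#' counts of claim-code occurrences in a fixed window before each patient's
#' threshold (first-fill) month. Rows are claim variables (drug, lab or
#' diagnostic/procedure code tokens; `rowData()$kind` records which), columns
#' are patients. `metadata()` records `windowMonths` (the counting window)
#' and `minPatients` (variables observed in fewer patients were dropped).
#'
#' @aliases ClaimCountMatrix-class
#' @export
setClass("ClaimCountMatrix", contains = "SummarizedExperiment")

setValidity("ClaimCountMatrix", function(object) {
  m <- assay(object, "counts")
  vals <- if (inherits(m, "sparseMatrix")) m@x else as.vector(m)
  if (length(vals) && min(vals) < 0) return("counts must be nonnegative")
  if (length(vals) && any(vals %% 1 != 0)) return("counts must be integer-valued")
  if (!"kind" %in% colnames(rowData(object)))
    return("rowData must carry a 'kind' column")
  if (!all(rowData(object)$kind %in% c("drug", "lab", "code")))
    return("variable kind must be drug, lab or code")
  if (!identical(rownames(object), sort(rownames(object), method = "radix")))
    return("variables must be in lexicographic order")
  TRUE
})

#' FactorModel: nonnegative matrix factorization of a count matrix
#'
#' Stores the result of factorizing a patients x variables count matrix
#' `X ~ scores %*% t(loadings)` with all entries nonnegative. Loading
#' columns are normalised to unit L2 norm (the scale lives in the scores).
#' The per-iteration squared-Frobenius reconstruction error is kept so the
#' monotone-descent property of the multiplicative updates can be audited.
#'
#' @slot loadings variables x K nonnegative matrix, unit-L2 columns.
#' @slot scores patients x K nonnegative matrix.
#' @slot K number of factors.
#' @slot objective per-iteration squared Frobenius reconstruction error.
#' @slot seed integer seed used for the random initialisation.
#' @slot converged logical, TRUE if the relative objective change fell below
#'   the tolerance before `maxIter`.
#' @slot iterations number of multiplicative-update iterations performed.
#' @aliases FactorModel-class
#' @export
setClass("FactorModel", representation(
  loadings   = "matrix",
  scores     = "matrix",
  K          = "integer",
  objective  = "numeric",
  seed       = "integer",
  converged  = "logical",
  iterations = "integer"
))

setValidity("FactorModel", function(object) {
  if (min(object@loadings) < 0 || min(object@scores) < 0)
    return("loadings and scores must be nonnegative")
  if (ncol(object@loadings) != object@K || ncol(object@scores) != object@K)
    return("loadings and scores must have K columns")
  if (any(diff(object@objective) > 1e-8 * (1 + object@objective[-length(object@objective)])))
    return("objective trace must be non-increasing")
  nrm <- sqrt(colSums(object@loadings^2))
  if (any(abs(nrm[nrm > 0] - 1) > 1e-6))
    return("nonzero loading columns must have unit L2 norm")
  TRUE
})

#' @describeIn FactorModel-class loading matrix accessor (variables x K)
#' @param object a `FactorModel`.
#' @export
setGeneric("factorLoadings", function(object) standardGeneric("factorLoadings"))

#' @describeIn FactorModel-class factor-score accessor (patients x K)
#' @export
setGeneric("factorScores", function(object) standardGeneric("factorScores"))

#' @describeIn FactorModel-class per-iteration reconstruction-error trace
#' @export
setGeneric("objectiveTrace", function(object) standardGeneric("objectiveTrace"))

#' @export
setMethod("factorLoadings", "FactorModel", function(object) object@loadings)

#' @export
setMethod("factorScores", "FactorModel", function(object) object@scores)

#' @export
setMethod("objectiveTrace", "FactorModel", function(object) object@objective)

setMethod("show", "FactorModel", function(object) {
  cat("FactorModel with", object@K, "factors\n")
  cat("  variables:", nrow(object@loadings), " patients:", nrow(object@scores), "\n")
  cat("  final reconstruction error:",
      format(utils::tail(object@objective, 1), digits = 6),
      if (object@converged) "(converged" else "(max iterations",
      paste0("after ", object@iterations, " iterations)\n"))
})

setMethod("show", "ClaimCountMatrix", function(object) {
  kinds <- table(rowData(object)$kind)
  cat("ClaimCountMatrix:", nrow(object), "variables x", ncol(object), "patients\n")
  cat("  window:", metadata(object)$windowMonths, "months;",
      "variable kinds:", paste(names(kinds), kinds, sep = "=", collapse = ", "), "\n")
  cat("  sparsity:", format(1 - Matrix::nnzero(assay(object)) / length(assay(object)),
                            digits = 3), "\n")
})
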