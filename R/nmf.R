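#' Fit a non-negative matrix factorization of a claim-count matrix
#'
#' Factorizes a nonnegative matrix `X` (patients x variables) as
#' `X ~ scores %*% t(loadings)` with all entries nonnegative, minimising the
#' squared Frobenius reconstruction error by multiplicative updates from a
#' seeded random-uniform initialisation. Iteration stops when the relative
#' objective decrease falls below `tol` or after `maxIter` iterations. After
#' the updates, loading columns are normalised to unit L2 norm and the final
#' scores are recomputed by nonnegative least squares against the fixed
#' loadings (the same routine [scorePatients()] uses), so in-sample
#' re-scoring reproduces the fitted scores.
#'
#' @param counts a [ClaimCountMatrix-class] (variables x patients) or a
#'   nonnegative numeric matrix (patients x variables).
#' @param K number of factors (default 30, the usual operating point for
#'   claim-count matrices of a few hundred to a few thousand variables).
#' @param maxIter,tol stopping rule for the multiplicative updates.
#' @param seed seed for the random initialisation.
#' @param nStarts number of random restarts; the run with the lowest final
#'   reconstruction error wins (multiplicative updates only find local
#'   optima, and restarts are the standard guard against factor collapse).
#'   Restart r uses seed `seed + 1000 * (r - 1)`.
#' @param log1p if TRUE, factorize `log(1 + X)` instead of raw counts
#'   (counts are heavily skewed; off by default so the factorization stays
#'   a factorization of the count matrix itself).
#' @param normalize `"none"` (default), `"rows"` (each patient row scaled
#'   to unit sum) or `"columns"` (each variable scaled to unit sum) before
#'   fitting.
#' @return a [FactorModel-class].
#' @export
fitNmf <- function(counts, K = 30L, maxIter = 500L, tol = 1e-5, seed = 1L,
                   nStarts = 1L, log1p = FALSE,
                   normalize = c("none", "rows", "columns")) {
  normalize <- match.arg(normalize)
  X <- asPatientMatrix_(counts)
  K <- as.integer(K)
  if (K <= 0L) stop("K must be positive")
  if (K >= min(dim(X))) stop("K must be smaller than both dimensions")
  if (all(X == 0)) stop("cannot factorize an all-zero matrix")
  if (min(X) < 0) stop("counts must be nonnegative")
  if (log1p) X <- log1p(X)
  if (normalize == "rows") {
    rs <- rowSums(X); X <- X / pmax(rs, .Machine$double.eps)
  } else if (normalize == "columns") {
    cs <- colSums(X); X <- sweep(X, 2, pmax(cs, .Machine$double.eps), "/")
  }
  best <- NULL
  for (r in seq_len(max(1L, as.integer(nStarts)))) {
    run <- nmfRun_(X, K, maxIter, tol, seed + 1000L * (r - 1L))
    if (is.null(best) || run$obj[length(run$obj)] < best$obj[length(best$obj)])
      best <- run
  }
  S <- best$S; Lo <- best$Lo; obj <- best$obj
  iter <- best$iter; converged <- best$converged
  normX2 <- sum(X^2)
  nrm <- sqrt(colSums(Lo^2))
  pos <- nrm > 0
  Lo[, pos] <- sweep(Lo[, pos, drop = FALSE], 2, nrm[pos], "/")
  S <- nnlsScores_(X, Lo)
  final <- normX2 - 2 * sum(S * (X %*% Lo)) + sum(crossprod(S) * crossprod(Lo))
  obj <- c(obj, max(final, 0))
  dimnames(Lo) <- list(colnames(X), paste0("factor", seq_len(K)))
  dimnames(S) <- list(rownames(X), paste0("factor", seq_len(K)))
  methods::new("FactorModel",
               loadings = Lo, scores = S, K = K, objective = obj,
               seed = as.integer(seed), converged = converged,
               iterations = iter)
}

# one multiplicative-update run from a seeded random-uniform start
nmfRun_ <- function(X, K, maxIter, tol, seed) {
  n <- nrow(X); V <- ncol(X)
  withr_seed(seed)
  S <- matrix(runif(n * K, 1e-3, 1), n, K)
  Lo <- matrix(runif(V * K, 1e-3, 1), V, K)
  eps <- 1e-12
  normX2 <- sum(X^2)
  obj <- numeric(0)
  prev <- Inf
  iter <- 0L
  converged <- FALSE
  while (iter < maxIter) {
    iter <- iter + 1L
    XL <- X %*% Lo
    S <- S * XL / (S %*% crossprod(Lo) + eps)
    XtS <- crossprod(X, S)
    Lo <- Lo * XtS / (Lo %*% crossprod(S) + eps)
    cur <- normX2 - 2 * sum(S * (X %*% Lo)) + sum(crossprod(S) * crossprod(Lo))
    cur <- max(cur, 0)
    obj <- c(obj, cur)
    if (is.finite(prev) && abs(prev - cur) <= tol * max(prev, eps)) {
      converged <- TRUE
      break
    }
    prev <- cur
  }
  list(S = S, Lo = Lo, obj = obj, iter = iter, converged = converged)
}

asPatientMatrix_ <- function(counts) {
  if (methods::is(counts, "ClaimCountMatrix"))
    return(as.matrix(Matrix::t(assay(counts, "counts"))))
  if (methods::is(counts, "SummarizedExperiment"))
    return(as.matrix(Matrix::t(assay(counts))))
  as.matrix(counts)
}

# Nonnegative least squares for all rows of X against fixed loadings, by
# multiplicative updates on the scores only (a convex problem per row, so
# the updates converge to the global minimiser). Deterministic start.
nnlsScores_ <- function(X, Lo, maxIter = 2000L, tol = 1e-12) {
  n <- nrow(X); K <- ncol(Lo)
  XL <- X %*% Lo
  G <- crossprod(Lo)
  eps <- 1e-12
  S <- matrix(1, n, K)
  prev <- Inf
  for (i in seq_len(maxIter)) {
    S <- S * pmax(XL, 0) / (S %*% G + eps)
    if (i %% 25L == 0L) {
      cur <- sum(crossprod(S) * G) - 2 * sum(S * XL)
      if (is.finite(prev) && abs(prev - cur) <= tol * (abs(prev) + 1)) break
      prev <- cur
    }
  }
  S
}

#' Project patients onto a fitted factor basis
#'
#' Nonnegative least-squares projection of each patient's count row onto the
#' model's fixed (unit-norm) loadings. Variables the model knows but the new
#' data lacks are treated as zero counts; variables the model does not know
#' are dropped. Scoring the training matrix reproduces the fitted scores.
#'
#' @param model a [FactorModel-class].
#' @param counts new patients' counts: matrix (patients x variables) with
#'   variable column names, or a [ClaimCountMatrix-class].
#' @return nonnegative matrix, patients x K.
#' @export
setGeneric("scorePatients", function(model, counts) standardGeneric("scorePatients"))

#' @rdname scorePatients
#' @export
setMethod("scorePatients", "FactorModel", function(model, counts) {
  X <- asPatientMatrix_(counts)
  vars <- rownames(model@loadings)
  if (is.null(colnames(X)) && ncol(X) == length(vars)) colnames(X) <- vars
  common <- intersect(colnames(X), vars)
  if (!length(common))
    stop("no overlap between count variables and model variables")
  Xa <- matrix(0, nrow(X), length(vars), dimnames = list(rownames(X), vars))
  Xa[, common] <- X[, common]
  S <- nnlsScores_(Xa, model@loadings)
  dimnames(S) <- list(rownames(X), colnames(model@loadings))
  S
})

#' Top-loading variables per factor
#'
#' For each factor, the `n` variables with largest loading, in descending
#' order; ties are broken lexicographically by variable name so the ranking
#' is stable across runs. Variables with zero loading are never listed.
#'
#' @param model a [FactorModel-class].
#' @param n number of variables per factor, default 10.
#' @return data.table with columns `factor`, `rank`, `variable`, `loading`.
#' @export
setGeneric("topLoadings", function(model, n = 10L) standardGeneric("topLoadings"))

#' @rdname topLoadings
#' @export
setMethod("topLoadings", "FactorModel", function(model, n = 10L) {
  Lo <- model@loadings
  out <- lapply(seq_len(ncol(Lo)), function(j) {
    v <- Lo[, j]
    v <- v[v > 0]
    if (!length(v)) return(NULL)
    o <- order(-v, names(v), method = "radix")
    top <- head(o, n)
    data.table(factor = colnames(Lo)[j], rank = seq_along(top),
               variable = names(v)[top], loading = unname(v[top]))
  })
  rbindlist(out)
})
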