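#' Days per month used throughout the package
#'
#' Claims carry month-truncated dates, so all day arithmetic (follow-up
#' length, percent days covered denominators, event times) converts month
#' indices to days at a flat 30 days per month.
#' @export
DAYS_PER_MONTH <- 30L

#' Concordance statistic (area under the ROC curve)
#'
#' Computed from the Mann-Whitney rank statistic: the probability that a
#' randomly chosen positive outranks a randomly chosen negative, with ties
#' counted one half.
#'
#' @param score numeric predictions, higher = more likely positive.
#' @param label logical or 0/1 outcome.
#' @return AUC in \[0, 1\].
#' @export
cStatistic <- function(score, label) {
  label <- as.logical(label)
  stopifnot(length(score) == length(label), !anyNA(score), !anyNA(label))
  n1 <- sum(label); n0 <- sum(!label)
  if (n1 == 0L || n0 == 0L) stop("cStatistic needs both classes present")
  r <- rank(score, ties.method = "average")
  (sum(r[label]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Empirical ROC curve points
#'
#' @param score,label as in [cStatistic()].
#' @return data.frame with columns `fpr`, `tpr`, `threshold`, ordered by
#'   decreasing threshold; suitable for trapezoidal integration.
#' @export
rocPoints <- function(score, label) {
  label <- as.logical(label)
  o <- order(score, decreasing = TRUE)
  s <- score[o]; y <- label[o]
  tp <- cumsum(y); fp <- cumsum(!y)
  keep <- c(s[-1] != s[-length(s)], TRUE)   # one point per distinct threshold
  data.frame(
    fpr = c(0, fp[keep] / sum(!y)),
    tpr = c(0, tp[keep] / sum(y)),
    threshold = c(Inf, s[keep])
  )
}

#' Area under an ROC curve by trapezoidal integration
#' @param roc output of [rocPoints()].
#' @return numeric AUC.
#' @export
trapezoidAuc <- function(roc) {
  sum(diff(roc$fpr) * (head(roc$tpr, -1) + roc$tpr[-1]) / 2)
}

#' Seeded patient-level cross-validation fold assignment
#'
#' @param ids vector of patient ids (one row per patient).
#' @param nFolds number of folds.
#' @param seed integer seed.
#' @return integer vector of fold labels in `1:nFolds`, one per id; folds
#'   partition the ids and differ in size by at most one.
#' @export
assignFolds <- function(ids, nFolds, seed) {
  n <- length(ids)
  stopifnot(nFolds >= 2, n >= nFolds)
  withr_seed(seed)
  sample(rep_len(seq_len(nFolds), n))
}

# set.seed without touching the caller's RNG state on exit is not wanted
# here -- the package's contract is that a seed argument fixes everything
# downstream of the call, so we deliberately reseed the global RNG.
withr_seed <- function(seed) {
  set.seed(as.integer(seed) %% .Machine$integer.max)
  invisible(NULL)
}

#' Match estimated factors to true factors by cosine similarity
#'
#' Finds the column permutation of `est` maximising total cosine similarity
#' with `truth` by exhaustive search (intended for small K, as used in
#' recovery experiments).
#'
#' @param est,truth nonnegative matrices with the same dimensions
#'   (variables x K).
#' @return list with `perm` (est column matched to each truth column) and
#'   `cosine` (per-truth-column cosine similarity under that matching).
#' @export
matchFactors <- function(est, truth) {
  stopifnot(ncol(est) == ncol(truth), nrow(est) == nrow(truth))
  K <- ncol(truth)
  if (K > 8) stop("exhaustive matching supported for K <= 8")
  nrm <- function(m) sweep(m, 2, pmax(sqrt(colSums(m^2)), .Machine$double.eps), "/")
  S <- crossprod(nrm(truth), nrm(est))        # K x K cosine matrix
  perms <- permutations_(K)
  tot <- apply(perms, 1, function(p) sum(S[cbind(seq_len(K), p)]))
  best <- perms[which.max(tot), ]
  list(perm = best, cosine = S[cbind(seq_len(K), best)])
}

permutations_ <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- permutations_(n - 1L)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub), n - 1L)))
  }
  out
}

# Median-impute columns of a data.frame of numeric features using training-row
# statistics; appends a 0/1 missingness indicator for columns with any NA in
# the training rows. Returns the augmented frame (same rows as input).
imputeByTrainingMedian <- function(x, trainIdx) {
  stopifnot(is.data.frame(x))
  out <- x
  for (nm in names(x)) {
    v <- x[[nm]]
    if (!is.numeric(v)) next
    tr <- v[trainIdx]
    if (anyNA(tr) || anyNA(v)) {
      med <- median(tr, na.rm = TRUE)
      if (is.na(med)) med <- 0
      out[[paste0(nm, "_missing")]] <- as.numeric(is.na(v))
      v[is.na(v)] <- med
      out[[nm]] <- v
    }
  }
  out
}

# month index -> days from threshold (threshold month = 0)
monthsToDays <- function(months) as.numeric(months) * DAYS_PER_MONTH

`%||%` <- function(a, b) if (is.null(a)) b else a
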