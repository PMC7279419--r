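# Internal k-NN machinery. Distances are Euclidean on the signature's rows;
# distance ties are broken deterministically by lowest training-sample index,
# and k is forced odd so two-class majority votes can never tie.

.checkK <- function(k, nTrain) {
  if (k < 1L || k %% 2L == 0L) stop("k must be a positive odd integer")
  if (k > nTrain) stop("k exceeds the number of training samples")
  invisible(k)
}

# squared Euclidean distances between columns of a (genes x n) and b (genes x m)
.sqDist <- function(a, b) {
  d <- colSums(a^2) - 2 * crossprod(a, b)  # n x m, plus colSums(b^2) per col
  sweep(d, 2L, colSums(b^2), "+")
}

# majority vote over the k nearest columns of trainX for each column of testX
.knnCore <- function(trainX, trainInt, testX, k) {
  d <- .sqDist(trainX, testX)
  if (k == 1L) {
    nearest <- max.col(-t(d), ties.method = "first")
    return(trainInt[nearest])
  }
  apply(d, 2L, function(col) {
    nn <- order(col, method = "radix")[seq_len(k)]
    votes <- sum(trainInt[nn] == 2L)
    if (votes * 2L > k) 2L else 1L
  })
}

#' k-NN class prediction on a gene signature
#'
#' Assigns each test sample the majority class of its k nearest training
#' samples under Euclidean distance over the signature's probes. Distance
#' ties resolve to the lowest training-sample index; \code{k} must be odd so
#' two-class votes cannot tie.
#'
#' @param trainExpr,testExpr numeric matrices (signature probes x samples),
#'   same row order. \code{trainExpr} needs at least one column.
#' @param trainClasses factor of length \code{ncol(trainExpr)} with two
#'   levels.
#' @param k positive odd neighbor count, at most \code{ncol(trainExpr)}.
#' @return Factor of predicted classes, one per test sample, with the levels
#'   of \code{trainClasses}.
#' @export
knnPredict <- function(trainExpr, trainClasses, testExpr, k = 1L) {
  if (!is.matrix(trainExpr) || nrow(trainExpr) == 0L) {
    stop("empty signature: at least one probe is required")
  }
  .checkK(k, ncol(trainExpr))
  trainClasses <- as.factor(trainClasses)
  pred <- .knnCore(trainExpr, as.integer(trainClasses), testExpr, as.integer(k))
  factor(levels(trainClasses)[pred], levels = levels(trainClasses))
}

# LOOCV correct-count on a precomputed squared-distance matrix (self = Inf)
.loocvCorrect <- function(d, clInt, k) {
  n <- ncol(d)
  if (k == 1L) {
    nearest <- max.col(-d, ties.method = "first")
    return(sum(clInt[nearest] == clInt))
  }
  correct <- 0L
  for (i in seq_len(n)) {
    nn <- order(d[i, ], method = "radix")[seq_len(k)]
    votes <- sum(clInt[nn] == 2L)
    pred <- if (votes * 2L > k) 2L else 1L
    if (pred == clInt[i]) correct <- correct + 1L
  }
  correct
}

.loocvOnMatrix <- function(x, clInt, k) {
  d <- .sqDist(x, x)
  diag(d) <- Inf
  .loocvCorrect(d, clInt, k)
}

#' Leave-one-out cross-validated accuracy of a signature
#'
#' Predicts every sample from all remaining samples with the k-NN classifier
#' restricted to the signature's probes, and reports the percentage of
#' correctly predicted samples, Acc(g); the percentage prediction error is
#' 100 - Acc(g).
#'
#' @param pe a log2-scale [PhenotypeExperiment-class] with >= 2 samples per
#'   class.
#' @param signature character vector of probe ids (non-empty, present in
#'   \code{pe}).
#' @param k positive odd neighbor count (default 1).
#' @return A [SignatureEvaluation-class] with \code{evaluation = "loocv"}.
#' @export
loocvAccuracy <- function(pe, signature, k = 1L) {
  stopifnot(methods::is(pe, "PhenotypeExperiment"))
  if (exprScale(pe) != "log2") {
    stop("classification runs on the log2 scale; apply log2Transform() first")
  }
  if (length(signature) == 0L) stop("empty signature")
  missing <- setdiff(signature, probeIds(pe))
  if (length(missing)) {
    stop("signature probes absent from the experiment: ",
         paste(utils::head(missing, 3L), collapse = ", "))
  }
  cl <- phenoClasses(pe)
  if (any(tabulate(cl, 2L) < 2L)) stop("each class needs >= 2 samples")
  .checkK(k, ncol(pe) - 1L)
  x <- exprValues(pe)[signature, , drop = FALSE]
  correct <- .loocvOnMatrix(x, as.integer(cl), as.integer(k))
  n <- ncol(x)
  methods::new("SignatureEvaluation",
    genes = as.character(signature),
    accuracy = 100 * correct / n,
    nCorrect = as.integer(correct), nEvaluated = as.integer(n),
    evaluation = "loocv")
}

#' Holdout validation accuracy of a signature
#'
#' Trains the k-NN classifier on the training samples and reports the
#' percentage of validation samples whose class is predicted correctly.
#'
#' @inheritParams loocvAccuracy
#' @param trainIdx,validIdx disjoint sample index vectors.
#' @return A [SignatureEvaluation-class] with
#'   \code{evaluation = "holdout_validation"}.
#' @export
holdoutAccuracy <- function(pe, signature, trainIdx, validIdx, k = 1L) {
  stopifnot(methods::is(pe, "PhenotypeExperiment"),
            length(intersect(trainIdx, validIdx)) == 0L)
  if (exprScale(pe) != "log2") {
    stop("classification runs on the log2 scale; apply log2Transform() first")
  }
  x <- exprValues(pe)[signature, , drop = FALSE]
  cl <- phenoClasses(pe)
  pred <- knnPredict(x[, trainIdx, drop = FALSE], cl[trainIdx],
                     x[, validIdx, drop = FALSE], k = k)
  correct <- sum(pred == cl[validIdx])
  methods::new("SignatureEvaluation",
    genes = as.character(signature),
    accuracy = 100 * correct / length(validIdx),
    nCorrect = as.integer(correct), nEvaluated = as.integer(length(validIdx)),
    evaluation = "holdout_validation")
}

# prefix search on a plain matrix/labeling; shared by the exported method and
# the holdout sampler (which works on training submatrices). Rows of x are
# already in ranking order. Returns list(len, accuracies) where len is the
# smallest argmax prefix. The squared-distance matrix is grown one gene at a
# time (rank-one update), so the whole curve costs one pass over the prefixes.
.prefixSearch <- function(x, clInt, k) {
  nPrefix <- nrow(x)
  n <- ncol(x)
  acc <- numeric(nPrefix)
  d <- matrix(0, n, n)
  for (p in seq_len(nPrefix)) {
    g <- x[p, ]
    d <- d + (matrix(g, n, n) - matrix(g, n, n, byrow = TRUE))^2
    dd <- d
    diag(dd) <- Inf
    acc[p] <- 100 * .loocvCorrect(dd, clInt, k) / n
  }
  list(len = which.max(acc), accuracies = acc)
}

#' Smallest-scale signature search over ranked gene prefixes
#'
#' Evaluates the nested signatures g1..gi for i = 1..\code{maxPrefix} by
#' LOOCV accuracy and returns the shortest prefix attaining the maximum: the
#' smallest-scale signature — the least number of discriminatory genes with
#' the highest accuracy. Deterministic given the ranking and k.
#'
#' @inheritParams loocvAccuracy
#' @param rankedGenes non-empty character vector of probe ids, most
#'   discriminatory first (typically [rankGenes()] output).
#' @param maxPrefix largest prefix length to evaluate (default 200; the
#'   search is capped at \code{length(rankedGenes)}).
#' @return A [SignatureEvaluation-class] for the winning prefix, with the
#'   per-prefix accuracy curve in \code{attr(, "accuracies")}.
#' @export
smallestScaleSignature <- function(pe, rankedGenes, k = 1L, maxPrefix = 200L) {
  stopifnot(methods::is(pe, "PhenotypeExperiment"))
  if (exprScale(pe) != "log2") {
    stop("classification runs on the log2 scale; apply log2Transform() first")
  }
  if (length(rankedGenes) == 0L) stop("rankedGenes must be non-empty")
  .checkK(k, ncol(pe) - 1L)
  x <- exprValues(pe)[rankedGenes[seq_len(min(length(rankedGenes), maxPrefix))],
                      , drop = FALSE]
  cl <- phenoClasses(pe)
  res <- .prefixSearch(x, as.integer(cl), as.integer(k))
  len <- res$len
  n <- ncol(pe)
  correct <- as.integer(round(res$accuracies[len] * n / 100))
  out <- methods::new("SignatureEvaluation",
    genes = as.character(rankedGenes[seq_len(len)]),
    accuracy = res$accuracies[len],
    nCorrect = correct, nEvaluated = as.integer(n),
    evaluation = "loocv")
  attr(out, "accuracies") <- res$accuracies
  out
}
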