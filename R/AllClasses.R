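#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
NULL

#' PhenotypeExperiment: a two-class expression experiment
#'
#' Container for a probes x samples intensity matrix with a two-class
#' phenotype labeling, extending
#' \linkS4class{SummarizedExperiment}. The single assay \code{"exprs"} holds
#' positive raw intensities (\code{exprScale = "raw"}) or log2 intensities
#' (\code{exprScale = "log2"}); \code{colData()$phenoClass} is a two-level
#' factor whose first level is the control-like class (e.g. HC) and whose
#' second level is the case-like class (e.g. LOAD).
#'
#' @slot exprScale character, \code{"raw"} or \code{"log2"}.
#'
#' @seealso [PhenotypeExperiment()] for construction, [log2Transform()],
#'   [geneStatistics()].
#' @export
setClass("PhenotypeExperiment",
  contains = "SummarizedExperiment",
  slots = c(exprScale = "character")
)

setValidity("PhenotypeExperiment", function(object) {
  msg <- character()
  if (!length(object@exprScale) == 1L ||
      !object@exprScale %in% c("raw", "log2")) {
    msg <- c(msg, "exprScale must be 'raw' or 'log2'")
  }
  if (!"exprs" %in% SummarizedExperiment::assayNames(object)) {
    msg <- c(msg, "assay 'exprs' is required")
  } else {
    x <- SummarizedExperiment::assay(object, "exprs")
    if (anyNA(x)) msg <- c(msg, "expression matrix contains missing values")
    if (identical(object@exprScale, "raw") && !all(x > 0)) {
      bad <- which(x <= 0, arr.ind = TRUE)[1L, , drop = TRUE]
      msg <- c(msg, sprintf(
        "raw-scale values must be positive (probe '%s', sample '%s')",
        rownames(x)[bad[1L]], colnames(x)[bad[2L]]))
    }
    if (is.null(rownames(x)) || anyDuplicated(rownames(x))) {
      msg <- c(msg, "probe ids must be present and unique at probe level")
    }
    if (is.null(colnames(x)) || anyDuplicated(colnames(x))) {
      msg <- c(msg, "sample ids must be present and unique")
    }
  }
  cl <- SummarizedExperiment::colData(object)$phenoClass
  if (is.null(cl)) {
    msg <- c(msg, "colData column 'phenoClass' is required")
  } else {
    if (!is.factor(cl) || nlevels(cl) != 2L) {
      msg <- c(msg, "phenoClass must be a factor with exactly two levels")
    } else if (anyNA(cl) || any(tabulate(cl, 2L) == 0L)) {
      msg <- c(msg, "every sample needs a class and both classes must be non-empty")
    }
  }
  if (length(msg)) msg else TRUE
})

#' SignatureEvaluation: an ordered gene signature with its accuracy
#'
#' The result of evaluating an ordered probe list g with the k-NN classifier:
#' the percentage accuracy Acc(g) = 100 * nCorrect / nEvaluated, either by
#' leave-one-out cross-validation or by holdout validation.
#'
#' @slot genes character, ordered probe ids of the signature.
#' @slot accuracy numeric percentage in [0, 100].
#' @slot nCorrect,nEvaluated integer counts behind the accuracy.
#' @slot evaluation character, \code{"loocv"} or \code{"holdout_validation"}.
#' @export
setClass("SignatureEvaluation",
  slots = c(
    genes = "character",
    accuracy = "numeric",
    nCorrect = "integer",
    nEvaluated = "integer",
    evaluation = "character"
  )
)

setValidity("SignatureEvaluation", function(object) {
  msg <- character()
  if (object@nEvaluated > 0L &&
      abs(object@accuracy - 100 * object@nCorrect / object@nEvaluated) > 1e-8) {
    msg <- c(msg, "accuracy must equal 100 * nCorrect / nEvaluated")
  }
  if (!object@evaluation %in% c("loocv", "holdout_validation")) {
    msg <- c(msg, "evaluation must be 'loocv' or 'holdout_validation'")
  }
  if (length(msg)) msg else TRUE
})

#' HoldoutBag: one 75/25 resampling bag
#'
#' One random train/validation partition together with everything learned on
#' it: the Fisher's-ratio gene ranking of the training portion, the
#' smallest-scale signature found on the training samples, and the blind
#' validation accuracy of that signature.
#'
#' @slot bagId integer bag index.
#' @slot trainIdx,validIdx integer sample indices; disjoint, covering all
#'   samples.
#' @slot rankedGenes character, training-portion FR ranking (descending).
#' @slot signature a [SignatureEvaluation-class] learned on the training set.
#' @slot validationAccuracy numeric percentage on the held-out 25%.
#' @export
setClass("HoldoutBag",
  slots = c(
    bagId = "integer",
    trainIdx = "integer",
    validIdx = "integer",
    rankedGenes = "character",
    signature = "SignatureEvaluation",
    validationAccuracy = "numeric"
  )
)

setValidity("HoldoutBag", function(object) {
  if (length(intersect(object@trainIdx, object@validIdx)) > 0L) {
    return("train and validation indices must be disjoint")
  }
  TRUE
})

#' FrequencyTable: posterior gene sampling-frequency ranking
#'
#' Gene appearance counts across the accepted signatures of a sampler, with
#' two frequency conventions: \code{freqSlots} is 100 * count / total sampled
#' gene slots, and \code{freqBags} is 100 * count / number of accepted bags
#' (draws). Rows are sorted by frequency, descending.
#'
#' @slot table a \linkS4class{DataFrame} with columns \code{probeId},
#'   \code{count}, \code{freqSlots}, \code{freqBags}.
#' @slot totalSlots integer, sum of accepted signature lengths.
#' @slot nAcceptedBags integer, number of accepted bags/draws.
#' @export
setClass("FrequencyTable",
  slots = c(
    table = "DataFrame",
    totalSlots = "integer",
    nAcceptedBags = "integer"
  )
)

setValidity("FrequencyTable", function(object) {
  msg <- character()
  tab <- object@table
  need <- c("probeId", "count", "freqSlots", "freqBags")
  if (!all(need %in% colnames(tab))) {
    msg <- c(msg, paste("table needs columns", paste(need, collapse = ", ")))
  } else if (nrow(tab) > 0L) {
    if (object@totalSlots > 0L &&
        any(abs(tab$freqSlots - 100 * tab$count / object@totalSlots) > 1e-8)) {
      msg <- c(msg, "freqSlots must equal 100 * count / totalSlots")
    }
    if (is.unsorted(-tab$freqSlots)) {
      msg <- c(msg, "rows must be sorted by frequency, descending")
    }
  }
  if (length(msg)) msg else TRUE
})

#' ToleranceEllipse: the equivalence region of a linear regression
#'
#' The set M_tol of models m = (a0, a1) whose relative misfit
#' ||y - F m|| / ||y|| stays below a tolerance. For a linear model the region
#' is an ellipse centred at the least-squares solution whose axes are governed
#' by the eigenstructure of F'F: membership is equivalent to
#' (m - center)' F'F (m - center) < tol^2 ||y||^2 - RSS.
#'
#' @slot center numeric length-2, the least-squares fit (a0, a1).
#' @slot tol numeric, relative-misfit tolerance.
#' @slot FtF 2x2 matrix F'F.
#' @slot eigenvalues,eigenvectors eigen decomposition of F'F (decreasing).
#' @slot rss numeric, residual sum of squares at the center.
#' @slot yNormSq numeric, ||y_obs||^2.
#' @export
setClass("ToleranceEllipse",
  slots = c(
    center = "numeric",
    tol = "numeric",
    FtF = "matrix",
    eigenvalues = "numeric",
    eigenvectors = "matrix",
    rss = "numeric",
    yNormSq = "numeric"
  )
)

setValidity("ToleranceEllipse", function(object) {
  if (any(object@eigenvalues < -1e-10)) {
    return("F'F must be positive semi-definite")
  }
  TRUE
})
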