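#' Construct a PhenotypeExperiment
#'
#' Wraps a probes x samples expression matrix and a two-class sample labeling
#' into a [PhenotypeExperiment-class]. The first element of \code{classes}
#' (or the first factor level) is taken as the control-like class; fold
#' changes put its mean in the numerator, so a positive FC means
#' underexpression in cases.
#'
#' @param exprs numeric matrix, probes in rows (unique rownames), samples in
#'   columns (unique colnames). Positive when \code{scale = "raw"}.
#' @param classes character or factor of length \code{ncol(exprs)} assigning
#'   each sample to one of two classes.
#' @param scale \code{"raw"} (positive intensities) or \code{"log2"}.
#' @param classLevels optional length-2 character giving the class order
#'   (control-like first). Defaults to order of first appearance.
#'
#' @return A [PhenotypeExperiment-class].
#' @examples
#' x <- matrix(2^rnorm(20, 8), 4, 5,
#'   dimnames = list(paste0("p", 1:4), paste0("s", 1:5)))
#' pe <- PhenotypeExperiment(x, c("HC", "HC", "HC", "LOAD", "LOAD"))
#' controlClass(pe)
#' @export
PhenotypeExperiment <- function(exprs, classes, scale = c("raw", "log2"),
                                classLevels = NULL) {
  scale <- match.arg(scale)
  if (!is.matrix(exprs) || !is.numeric(exprs)) {
    stop("'exprs' must be a numeric matrix")
  }
  if (length(classes) != ncol(exprs)) {
    stop("'classes' must have one entry per sample (column)")
  }
  if (is.null(classLevels)) {
    classLevels <- if (is.factor(classes)) levels(classes) else
      unique(as.character(classes))
  }
  if (length(classLevels) != 2L) {
    stop("exactly two classes are required, got: ",
         paste(classLevels, collapse = ", "))
  }
  cl <- factor(as.character(classes), levels = classLevels)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = exprs),
    colData = S4Vectors::DataFrame(phenoClass = cl, row.names = colnames(exprs))
  )
  methods::new("PhenotypeExperiment", se, exprScale = scale)
}

#' @describeIn PhenotypeExperiment The expression matrix (probes x samples).
#' @param object,x a [PhenotypeExperiment-class].
#' @export
exprValues <- function(x) SummarizedExperiment::assay(x, "exprs")

#' @describeIn PhenotypeExperiment Scale of the matrix, "raw" or "log2".
#' @export
exprScale <- function(x) x@exprScale

#' @describeIn PhenotypeExperiment Two-level factor of sample classes.
#' @export
phenoClasses <- function(x) SummarizedExperiment::colData(x)$phenoClass

#' @describeIn PhenotypeExperiment Name of the control-like (first) class.
#' @export
controlClass <- function(x) levels(phenoClasses(x))[1L]

#' @describeIn PhenotypeExperiment Name of the case-like (second) class.
#' @export
caseClass <- function(x) levels(phenoClasses(x))[2L]

#' @describeIn PhenotypeExperiment Probe identifiers.
#' @export
probeIds <- function(x) rownames(x)

setMethod("show", "PhenotypeExperiment", function(object) {
  n <- tabulate(phenoClasses(object), 2L)
  cat(sprintf(
    "PhenotypeExperiment: %d probes x %d samples [%s scale]\n",
    nrow(object), ncol(object), exprScale(object)))
  cat(sprintf("  classes: %s (n=%d, control) vs %s (n=%d, case)\n",
              controlClass(object), n[1L], caseClass(object), n[2L]))
})

setMethod("show", "SignatureEvaluation", function(object) {
  cat(sprintf(
    "SignatureEvaluation: %d gene(s), accuracy %.2f%% (%d/%d, %s)\n",
    length(object@genes), object@accuracy, object@nCorrect,
    object@nEvaluated, object@evaluation))
  cat("  genes:", paste(utils::head(object@genes, 8L), collapse = ", "),
      if (length(object@genes) > 8L) "..." else "", "\n")
})

setMethod("show", "HoldoutBag", function(object) {
  cat(sprintf(
    "HoldoutBag #%d: %d train / %d validation; signature %d gene(s); validation accuracy %.2f%%\n",
    object@bagId, length(object@trainIdx), length(object@validIdx),
    length(object@signature@genes), object@validationAccuracy))
})

setMethod("show", "FrequencyTable", function(object) {
  cat(sprintf(
    "FrequencyTable: %d gene(s) over %d sampled slots in %d accepted bags\n",
    nrow(object@table), object@totalSlots, object@nAcceptedBags))
  if (nrow(object@table)) {
    print(utils::head(as.data.frame(object@table), 5L))
    if (nrow(object@table) > 5L) cat("  ...\n")
  }
})

setMethod("show", "ToleranceEllipse", function(object) {
  cat(sprintf(
    "ToleranceEllipse: center (a0, a1) = (%.4f, %.4f), tol = %.3f\n",
    object@center[1L], object@center[2L], object@tol))
  cat(sprintf("  eigenvalues of F'F: %.4g, %.4g; minimum misfit %.4f\n",
              object@eigenvalues[1L], object@eigenvalues[2L],
              sqrt(object@rss / object@yNormSq)))
})

#' Accessors for signature evaluations and frequency tables
#'
#' @param x a [SignatureEvaluation-class] or [FrequencyTable-class].
#' @return \code{signatureGenes}: character vector of ordered probe ids.
#'   \code{signatureAccuracy}: numeric percentage.
#'   \code{frequencyData}: base data.frame of the ranked frequency table.
#' @export
signatureGenes <- function(x) x@genes

#' @rdname signatureGenes
#' @export
signatureAccuracy <- function(x) x@accuracy

#' @rdname signatureGenes
#' @export
frequencyData <- function(x) as.data.frame(x@table)
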