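#' Log2-transform a raw-intensity experiment
#'
#' Replaces every intensity by its base-2 logarithm and flips the scale flag.
#' Fisher's ratios are defined on the log2 scale, so raw experiments pass
#' through here before ranking.
#'
#' @param pe a raw-scale [PhenotypeExperiment-class] with all values > 0.
#' @return The same experiment on log2 scale; ids and labeling unchanged.
#' @examples
#' x <- matrix(c(1, 8, 2, 4), 2, 2,
#'   dimnames = list(c("a", "b"), c("s1", "s2")))
#' pe <- PhenotypeExperiment(x, c("HC", "LOAD"))
#' exprValues(log2Transform(pe))
#' @export
log2Transform <- function(pe) {
  stopifnot(methods::is(pe, "PhenotypeExperiment"))
  if (exprScale(pe) != "raw") {
    stop("log2Transform expects a raw-scale experiment")
  }
  x <- exprValues(pe)
  if (any(x <= 0)) {
    bad <- which(x <= 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("non-positive value at probe '%s', sample '%s'",
                 rownames(x)[bad[1L]], colnames(x)[bad[2L]]))
  }
  SummarizedExperiment::assay(pe, "exprs") <- log2(x)
  pe@exprScale <- "log2"
  methods::validObject(pe)
  pe
}

#' Log2 fold change between two group means
#'
#' \code{log2(meanA / meanB)} with the control-like group first, so a positive
#' fold change means the gene is underexpressed in cases.
#'
#' @param meanA,meanB positive group means (control-like group first).
#' @return Numeric log2 ratio; antisymmetric in its arguments.
#' @examples
#' foldChange(703.3, 472.4)  # 0.57, underexpressed in cases
#' @export
foldChange <- function(meanA, meanB) {
  if (any(meanA <= 0) || any(meanB <= 0)) {
    stop("group means must be positive for a log2 fold change")
  }
  log2(meanA / meanB)
}

#' Fisher's ratio of a two-class probe
#'
#' The separability score FR = (meanA - meanB)^2 / (sdA^2 + sdB^2), invariant
#' under group exchange and under shifting both groups by a constant.
#' Standard deviations are population (ddof = 0) values.
#'
#' @param meanA,sdA,meanB,sdB group means and standard deviations.
#' @return Non-negative numeric. Errors when both SDs are zero (degenerate
#'   probe).
#' @examples
#' fisherRatio(1, 1, 0, 1)  # 0.5
#' @export
fisherRatio <- function(meanA, sdA, meanB, sdB) {
  denom <- sdA^2 + sdB^2
  if (any(denom <= 0)) {
    stop("degenerate probe: both group standard deviations are zero")
  }
  (meanA - meanB)^2 / denom
}

# population (ddof = 0) row means/sds of a matrix, vectorized over probes
.rowMeanSd <- function(x) {
  n <- ncol(x)
  m <- rowMeans(x)
  v <- rowMeans(x^2) - m^2
  v[v < 0] <- 0  # numerical guard
  list(mean = m, sd = sqrt(v), n = n)
}

#' Per-probe discriminatory statistics for a two-class experiment
#'
#' Computes, for every probe, the group means and standard deviations on the
#' experiment's current scale, the log2 fold change of the group means on that
#' scale, and the Fisher's ratio on the log2 scale (raw experiments are
#' log2-transformed internally for the FR only). Group A is the control-like
#' class, group B the case-like class.
#'
#' @param pe a [PhenotypeExperiment-class]; each class needs >= 2 samples.
#' @return A data.frame with columns \code{probeId}, \code{meanA}, \code{sdA},
#'   \code{meanB}, \code{sdB}, \code{fc}, \code{fr}, one row per probe in
#'   input order.
#' @examples
#' sim <- simulateCohort(cohortSpec(nProbes = 50, nPerClass = c(10, 10),
#'                                  seed = 1))
#' head(geneStatistics(sim$experiment))
#' @export
geneStatistics <- function(pe) {
  stopifnot(methods::is(pe, "PhenotypeExperiment"))
  cl <- phenoClasses(pe)
  if (any(tabulate(cl, 2L) < 2L)) {
    stop("each class needs at least 2 samples")
  }
  x <- exprValues(pe)
  a <- .rowMeanSd(x[, cl == levels(cl)[1L], drop = FALSE])
  b <- .rowMeanSd(x[, cl == levels(cl)[2L], drop = FALSE])
  xl <- if (exprScale(pe) == "raw") log2(x) else x
  al <- .rowMeanSd(xl[, cl == levels(cl)[1L], drop = FALSE])
  bl <- .rowMeanSd(xl[, cl == levels(cl)[2L], drop = FALSE])
  # log2 ratio of group means on the current scale; undefined (NA) where a
  # mean is non-positive, which can happen on log2-scale data
  fc <- rep(NA_real_, nrow(x))
  ok <- a$mean > 0 & b$mean > 0
  fc[ok] <- log2(a$mean[ok] / b$mean[ok])
  data.frame(
    probeId = rownames(x),
    meanA = a$mean, sdA = a$sd,
    meanB = b$mean, sdB = b$sd,
    fc = fc,
    fr = fisherRatio(al$mean, al$sd, bl$mean, bl$sd),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Rank probes by Fisher's ratio above a cut-off
#'
#' Retains probes with FR strictly above \code{frCutoff} and sorts them by FR,
#' descending, with ties broken by input order (stable). Raising the cut-off
#' never reorders survivors: rankings are prefix-closed.
#'
#' @param stats data.frame from [geneStatistics()] (needs \code{probeId} and
#'   \code{fr}), or any data.frame with those columns.
#' @param frCutoff non-negative FR cut-off; the discriminatory-gene filter
#'   uses 0.5 by default downstream.
#' @return Character vector of probe ids, possibly empty.
#' @export
rankGenes <- function(stats, frCutoff = 0.5) {
  stopifnot(is.data.frame(stats), all(c("probeId", "fr") %in% names(stats)),
            frCutoff >= 0)
  keep <- which(stats$fr > frCutoff)
  ord <- keep[order(stats$fr[keep], decreasing = TRUE, method = "radix")]
  as.character(stats$probeId[ord])
}
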