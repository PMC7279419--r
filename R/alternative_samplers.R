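#' Fisher's-ratio prior sampler
#'
#' Samples gene signatures from a prior proportional to discriminatory power:
#' each draw picks a signature size uniformly in 1..\code{maxSignatureSize},
#' then that many distinct probes with probability proportional to their
#' Fisher's ratio among probes passing \code{frCutoff}. Each signature is
#' scored by LOOCV accuracy and accepted when the accuracy is strictly above
#' \code{acceptThreshold}; the posterior frequency table is built over the
#' accepted draws with the same conventions as the holdout sampler.
#'
#' @param pe a log2-scale two-class [PhenotypeExperiment-class].
#' @param nDraws number of prior draws (default 1000).
#' @param frCutoff Fisher's-ratio cut-off defining the discriminatory set
#'   (default 0.5).
#' @param maxSignatureSize largest signature size drawn (default 10).
#' @param acceptThreshold acceptance threshold on LOOCV accuracy, strict
#'   (default 80).
#' @param k odd k-NN neighbor count (default 1).
#' @param seed integer root seed; per-draw seeds derive from it by counter.
#' @return A [FrequencyTable-class] over accepted draws.
#' @export
runFisherSampler <- function(pe, nDraws = 1000L, frCutoff = 0.5,
                             maxSignatureSize = 10L, acceptThreshold = 80,
                             k = 1L, seed = 1L) {
  stopifnot(methods::is(pe, "PhenotypeExperiment"),
            nDraws >= 1L, maxSignatureSize >= 1L)
  if (exprScale(pe) != "log2") {
    stop("the sampler runs on the log2 scale; apply log2Transform() first")
  }
  stats <- geneStatistics(pe)
  cand <- which(stats$fr > frCutoff)
  if (length(cand) == 0L) {
    stop("no probes pass the Fisher's-ratio cut-off of ", frCutoff)
  }
  ids <- stats$probeId[cand]
  weight <- stats$fr[cand]
  x <- exprValues(pe)
  clInt <- as.integer(phenoClasses(pe))
  maxSize <- min(maxSignatureSize, length(cand))
  accepted <- list()
  for (i in seq_len(nDraws)) {
    set.seed(.bagSeed(seed, i))
    size <- sample.int(maxSize, 1L)
    sig <- ids[sample.int(length(ids), size, prob = weight)]
    acc <- 100 * .loocvOnMatrix(x[sig, , drop = FALSE], clInt,
                                as.integer(k)) / ncol(x)
    if (acc > acceptThreshold) accepted[[length(accepted) + 1L]] <- sig
  }
  if (length(accepted) == 0L) {
    stop("no draws accepted at accuracy threshold ", acceptThreshold, "%")
  }
  .frequencyFromSignatures(accepted)
}

#' Random-Forest sampler
#'
#' Fits an ensemble of CART-style classification trees (bootstrap samples,
#' sqrt(p) random features per split, Gini impurity) and defines a probe's
#' sampling frequency as the fraction of trees that use it in at least one
#' split. In the returned table, \code{count} is the number of trees using
#' the probe, \code{freqBags} is 100 * count / nTrees (the per-tree usage
#' percentage), and \code{freqSlots} follows the slot convention over all
#' tree-probe usages. Set \code{importance = TRUE} to instead return
#' normalized mean-decrease-in-Gini importances as a data.frame.
#'
#' @param pe a two-class [PhenotypeExperiment-class] (any scale; trees are
#'   invariant to monotone per-feature transforms).
#' @param nTrees number of trees (default 500).
#' @param seed integer seed.
#' @param importance logical; return normalized impurity importances instead
#'   of split-usage frequencies.
#' @return A [FrequencyTable-class], or a data.frame when
#'   \code{importance = TRUE}.
#' @export
runForestSampler <- function(pe, nTrees = 500L, seed = 1L,
                             importance = FALSE) {
  stopifnot(methods::is(pe, "PhenotypeExperiment"), nTrees >= 1L)
  x <- exprValues(pe)
  y <- phenoClasses(pe)
  set.seed(as.integer(seed))
  rf <- randomForest::randomForest(
    x = t(x), y = y, ntree = as.integer(nTrees),
    mtry = max(1L, floor(sqrt(nrow(x)))), importance = importance)
  if (importance) {
    imp <- randomForest::importance(rf, type = 2L)[, 1L]
    imp <- imp / sum(imp)
    out <- data.frame(probeId = names(imp), importance = unname(imp),
                      stringsAsFactors = FALSE)
    return(out[order(out$importance, decreasing = TRUE), , drop = FALSE])
  }
  usage <- lapply(seq_len(nTrees), function(t) {
    tree <- randomForest::getTree(rf, t, labelVar = FALSE)
    vars <- tree[tree[, "status"] == 1, "split var"]
    rownames(x)[unique(vars)]
  })
  .frequencyFromSignatures(usage)
}

#' Compare the top genes of several samplers
#'
#' Pairwise overlap summary of frequency tables over the same probe universe:
#' Jaccard index of the top-\code{topN} gene sets and Spearman rank
#' correlation of the frequency ranks of the genes shared by each pair of
#' top sets.
#'
#' @param tables named list of two or more [FrequencyTable-class] objects.
#' @param topN number of top-ranked genes per table to compare (default 10).
#' @return data.frame with one row per table pair: \code{samplerA},
#'   \code{samplerB}, \code{jaccard}, \code{nShared}, \code{rankCor}
#'   (NA when fewer than 3 shared genes).
#' @export
compareSamplers <- function(tables, topN = 10L) {
  stopifnot(is.list(tables), length(tables) >= 2L)
  if (is.null(names(tables))) {
    names(tables) <- paste0("sampler", seq_along(tables))
  }
  tops <- lapply(tables, function(ft) {
    utils::head(as.character(ft@table$probeId), topN)
  })
  pairs <- utils::combn(names(tables), 2L)
  out <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- tops[[pairs[1L, j]]]
    b <- tops[[pairs[2L, j]]]
    shared <- intersect(a, b)
    rc <- if (length(shared) >= 3L) {
      stats::cor(match(shared, a), match(shared, b), method = "spearman")
    } else NA_real_
    data.frame(samplerA = pairs[1L, j], samplerB = pairs[2L, j],
               jaccard = length(shared) / length(union(a, b)),
               nShared = length(shared), rankCor = rc,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
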