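#' Generate stratified 75/25 holdout bags
#'
#' Draws \code{nBags} independent random partitions of the samples into a
#' training portion (about \code{trainFraction} of the data) and a validation
#' portion. The total training size is \code{floor(trainFraction * n)},
#' allocated across the two classes by largest-remainder apportionment (ties
#' to the control class), so bags are stratified and reproducible given the
#' seed. Per-bag RNG seeds are derived from the root seed by a bag counter,
#' so bag b is identical whether bags are generated singly or in sequence.
#'
#' @param classes two-level factor of sample classes (as
#'   \code{phenoClasses()} returns).
#' @param nBags number of bags (>= 1).
#' @param trainFraction fraction of data used for learning, in (0, 1);
#'   default 0.75.
#' @param seed integer root seed.
#' @return List of [HoldoutBag-class] skeletons (indices only; empty
#'   signatures).
#' @examples
#' bags <- generateHoldouts(factor(rep(c("HC", "LOAD"), c(8, 12))), 5, seed = 1)
#' length(bags[[1]]@trainIdx)  # floor(0.75 * 20) = 15
#' @export
generateHoldouts <- function(classes, nBags, trainFraction = 0.75, seed = 1L) {
  classes <- as.factor(classes)
  stopifnot(nlevels(classes) == 2L, nBags >= 1L,
            trainFraction > 0, trainFraction < 1)
  nc <- tabulate(classes, 2L)
  n <- length(classes)
  nTrain <- .apportionTrain(nc, trainFraction)
  if (sum(n - sum(nTrain)) < 1L || any(nTrain < 1L)) {
    stop("classes too small for a ", trainFraction, " holdout split")
  }
  idxByClass <- split(seq_len(n), classes)
  lapply(seq_len(nBags), function(b) {
    set.seed(.bagSeed(seed, b))
    train <- sort(unlist(lapply(1:2, function(cidx) {
      sample(idxByClass[[cidx]], nTrain[cidx])
    }), use.names = FALSE))
    methods::new("HoldoutBag",
      bagId = as.integer(b),
      trainIdx = as.integer(train),
      validIdx = as.integer(setdiff(seq_len(n), train)),
      rankedGenes = character(),
      signature = .emptyEvaluation(),
      validationAccuracy = NA_real_)
  })
}

# largest-remainder (Hamilton) apportionment of floor(f * n) training slots
# over the class sizes nc; remainder ties go to the earlier class.
.apportionTrain <- function(nc, f) {
  total <- floor(f * sum(nc))
  quota <- f * nc
  base <- floor(quota)
  left <- total - sum(base)
  if (left > 0) {
    extra <- order(quota - base, decreasing = TRUE, method = "radix")[seq_len(left)]
    base[extra] <- base[extra] + 1L
  }
  pmin(as.integer(base), nc)
}

.bagSeed <- function(seed, bagId) {
  (as.integer(seed) %% 1000000000L) + as.integer(bagId)
}

.emptyEvaluation <- function() {
  methods::new("SignatureEvaluation", genes = character(), accuracy = 0,
               nCorrect = 0L, nEvaluated = 0L, evaluation = "loocv")
}

#' Run the holdout sampler
#'
#' The three-step resampling algorithm that samples the uncertainty space of
#' the phenotype classifier: (1) data bagging — \code{nBags} random
#' \code{trainFraction}/rest holdouts; (2) gene selection — per bag, probes
#' are ranked by Fisher's ratio computed on the training portion only, probes
#' with FR above \code{frCutoff} are retained, and the smallest-scale k-NN
#' signature is learned over ranked prefixes; (3) each bag's signature is
#' blind-validated on the held-out samples. Posterior analysis of the
#' accepted bags is then performed with [filterByAccuracy()],
#' [frequencyTable()] and [posteriorWeights()].
#'
#' A bag whose training-portion FR filter retains no probes is recorded with
#' an empty signature and zero accuracy; such bags are excluded downstream.
#'
#' @param pe a log2-scale two-class [PhenotypeExperiment-class].
#' @param frCutoff Fisher's-ratio cut-off for the discriminatory-gene filter
#'   (default 0.5).
#' @param nBags number of holdout bags (default 1000).
#' @param k odd k-NN neighbor count (default 1).
#' @param maxPrefix prefix-search cap (default 200).
#' @param trainFraction learning fraction per bag (default 0.75).
#' @param seed integer root seed; identical seed and configuration give
#'   identical bags and signatures.
#' @return List of completed [HoldoutBag-class] objects.
#' @examples
#' sim <- simulateCohort(cohortSpec(nProbes = 200, nPerClass = c(12, 12),
#'                                  nDifferential = 4, seed = 7))
#' bags <- runHoldoutSampler(log2Transform(sim$experiment), nBags = 10, seed = 7)
#' bags[[1]]
#' @export
runHoldoutSampler <- function(pe, frCutoff = 0.5, nBags = 1000L, k = 1L,
                              maxPrefix = 200L, trainFraction = 0.75,
                              seed = 1L) {
  stopifnot(methods::is(pe, "PhenotypeExperiment"))
  if (exprScale(pe) != "log2") {
    stop("the sampler runs on the log2 scale; apply log2Transform() first")
  }
  bags <- generateHoldouts(phenoClasses(pe), nBags, trainFraction, seed)
  x <- exprValues(pe)
  cl <- phenoClasses(pe)
  clInt <- as.integer(cl)
  lapply(bags, function(bag) {
    tr <- bag@trainIdx
    ranked <- .rankTrainByFisher(x, clInt, tr, frCutoff)
    if (length(ranked) == 0L) {
      bag@validationAccuracy <- 0
      return(bag)
    }
    bag@rankedGenes <- ranked
    xtr <- x[ranked[seq_len(min(length(ranked), maxPrefix))], tr, drop = FALSE]
    res <- .prefixSearch(xtr, clInt[tr], as.integer(k))
    sig <- ranked[seq_len(res$len)]
    nTr <- length(tr)
    bag@signature <- methods::new("SignatureEvaluation",
      genes = sig,
      accuracy = res$accuracies[res$len],
      nCorrect = as.integer(round(res$accuracies[res$len] * nTr / 100)),
      nEvaluated = as.integer(nTr),
      evaluation = "loocv")
    if (length(bag@validIdx)) {
      pred <- .knnCore(x[sig, tr, drop = FALSE], clInt[tr],
                       x[sig, bag@validIdx, drop = FALSE], as.integer(k))
      bag@validationAccuracy <-
        100 * sum(pred == clInt[bag@validIdx]) / length(bag@validIdx)
    } else {
      bag@validationAccuracy <- NA_real_
    }
    bag
  })
}

# FR ranking restricted to training columns; log2 matrix in, ranked ids out
.rankTrainByFisher <- function(x, clInt, trainIdx, frCutoff) {
  xa <- x[, trainIdx[clInt[trainIdx] == 1L], drop = FALSE]
  xb <- x[, trainIdx[clInt[trainIdx] == 2L], drop = FALSE]
  a <- .rowMeanSd(xa)
  b <- .rowMeanSd(xb)
  denom <- a$sd^2 + b$sd^2
  fr <- ifelse(denom > 0, (a$mean - b$mean)^2 / denom, 0)
  keep <- which(fr > frCutoff)
  ord <- keep[order(fr[keep], decreasing = TRUE, method = "radix")]
  rownames(x)[ord]
}

#' Filter bags by validation accuracy
#'
#' Keeps the bags whose blind validation accuracy is strictly higher than the
#' threshold (80% in the reference configuration). Bags with empty signatures
#' never pass. Raising the threshold never adds a bag.
#'
#' @param bags list of [HoldoutBag-class] from [runHoldoutSampler()].
#' @param threshold acceptance threshold in [0, 100]; strict inequality.
#' @return The accepted sub-list, possibly empty (with a warning).
#' @export
filterByAccuracy <- function(bags, threshold = 80) {
  stopifnot(threshold >= 0, threshold <= 100)
  keep <- vapply(bags, function(b) {
    length(b@signature@genes) > 0L && !is.na(b@validationAccuracy) &&
      b@validationAccuracy > threshold
  }, logical(1L))
  out <- bags[keep]
  if (length(out) == 0L) {
    warning("no bags passed the accuracy threshold of ", threshold, "%")
  }
  out
}

#' Posterior gene sampling-frequency table
#'
#' Counts, for each probe, the number of accepted signatures containing it,
#' and reports two frequency conventions: relative to the total number of
#' sampled gene slots (sum of signature lengths; e.g. 997 appearances among
#' 43202 slots is 2.31%) and relative to the number of accepted bags (997 of
#' 1000 holdouts is 99.7%).
#'
#' @param acceptedBags non-empty list of accepted [HoldoutBag-class] objects,
#'   or any list of objects with a \code{signature} slot
#'   ([SignatureEvaluation-class]).
#' @return A [FrequencyTable-class], rows sorted by frequency descending.
#' @export
frequencyTable <- function(acceptedBags) {
  if (length(acceptedBags) == 0L) stop("at least one accepted bag is required")
  sigs <- lapply(acceptedBags, function(b) b@signature@genes)
  .frequencyFromSignatures(sigs)
}

# shared by the holdout and Fisher samplers
.frequencyFromSignatures <- function(sigs) {
  sigs <- sigs[lengths(sigs) > 0L]
  totalSlots <- sum(lengths(sigs))
  nBags <- length(sigs)
  counts <- table(factor(unlist(sigs, use.names = FALSE)))
  ord <- order(as.integer(counts), decreasing = TRUE, method = "radix")
  tab <- S4Vectors::DataFrame(
    probeId = names(counts)[ord],
    count = as.integer(counts)[ord],
    freqSlots = 100 * as.integer(counts)[ord] / totalSlots,
    freqBags = 100 * as.integer(counts)[ord] / nBags
  )
  methods::new("FrequencyTable", table = tab,
               totalSlots = as.integer(totalSlots),
               nAcceptedBags = as.integer(nBags))
}

#' Posterior bag weights from validation accuracies
#'
#' The likelihood of a signature is proportional to exp(Acc), so accepted
#' bags are weighted by normalized exponentials of their validation
#' accuracies. Computed with the max-shift stabilization
#' exp(Acc - max(Acc)) / sum, so weights are finite and sum to one.
#'
#' @param acceptedBags non-empty list of accepted [HoldoutBag-class] objects.
#' @return Named numeric vector of weights (names are bag ids) summing to 1.
#' @export
posteriorWeights <- function(acceptedBags) {
  if (length(acceptedBags) == 0L) stop("at least one accepted bag is required")
  acc <- vapply(acceptedBags, function(b) b@validationAccuracy, numeric(1L))
  w <- exp(acc - max(acc))
  w <- w / sum(w)
  names(w) <- vapply(acceptedBags, function(b) as.character(b@bagId),
                     character(1L))
  w
}
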