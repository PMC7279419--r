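test_that("k-NN with a single training sample assigns its class everywhere", {
  train <- matrix(0, 2, 1, dimnames = list(c("g1", "g2"), "t1"))
  test <- matrix(rnorm(10), 2, 5)
  pred <- knnPredict(train, factor("A", levels = c("A", "B")), test, k = 1)
  expect_true(all(pred == "A"))
})

test_that("1-NN on two separated 1-D clusters is the midpoint-split rule", {
  train <- matrix(c(0, 0.5, 10, 10.5), 1, 4)
  cl <- factor(c("A", "A", "B", "B"))
  test <- matrix(c(-1, 3, 5.24, 5.26, 12), 1, 5)
  pred <- knnPredict(train, cl, test, k = 1)
  expect_identical(as.character(pred), c("A", "A", "A", "B", "B"))
})

test_that("k-NN predictions equal an exhaustive distance-sort oracle", {
  set.seed(21)
  train <- matrix(rnorm(5 * 30), 5, 30,
                  dimnames = list(paste0("g", 1:5), paste0("t", 1:30)))
  cl <- factor(rep(c("A", "B"), 15))
  test <- matrix(rnorm(5 * 12), 5, 12)
  for (k in c(1L, 3L, 5L)) {
    pred <- knnPredict(train, cl, test, k = k)
    oracle <- vapply(seq_len(ncol(test)), function(j) {
      d <- sqrt(colSums((train - test[, j])^2))   # all pairwise distances
      nn <- order(d)[seq_len(k)]
      names(which.max(table(cl[nn])))
    }, character(1))
    expect_identical(as.character(pred), oracle)
  }
})

test_that("k-NN agrees with class::knn on tie-free data", {
  set.seed(31)
  train <- matrix(rnorm(4 * 40), 4, 40)
  cl <- factor(rep(c("A", "B"), 20))
  test <- matrix(rnorm(4 * 15), 4, 15)
  for (k in c(1L, 3L)) {
    expect_identical(
      as.character(knnPredict(train, cl, test, k = k)),
      as.character(class::knn(t(train), t(test), cl, k = k)))
  }
})

test_that("k must be odd and fit the training set", {
  train <- matrix(rnorm(8), 2, 4)
  cl <- factor(c("A", "A", "B", "B"))
  expect_error(knnPredict(train, cl, train, k = 2), "odd")
  expect_error(knnPredict(train, cl, train, k = 5), "exceeds")
  expect_error(knnPredict(train[0, , drop = FALSE], cl, train, k = 1),
               "empty signature")
})

test_that("LOOCV is perfect on a perfectly separating probe", {
  pe <- makeExperiment(5, c(6, 6), delta = 50, nPlanted = 1, seed = 41)
  ev <- loocvAccuracy(pe, "g001")
  expect_equal(signatureAccuracy(ev), 100)
  expect_equal(ev@nCorrect, 12L)
  # Acc(g) + prediction error = 100
  expect_equal(signatureAccuracy(ev) + 100 * (1 - ev@nCorrect / ev@nEvaluated),
               100)
})

test_that("LOOCV equals a hand-rolled double loop on a 12-sample fixture", {
  pe <- makeExperiment(6, c(6, 6), delta = 1.2, nPlanted = 3, seed = 43)
  sig <- c("g001", "g002", "g003")
  x <- exprValues(pe)[sig, ]
  cl <- phenoClasses(pe)
  for (k in c(1L, 3L)) {
    correct <- 0L
    for (i in seq_len(ncol(x))) {          # leave sample i out
      d <- sqrt(colSums((x[, -i, drop = FALSE] - x[, i])^2))
      nn <- order(d)[seq_len(k)]
      pred <- names(which.max(table(cl[-i][nn])))
      if (pred == cl[i]) correct <- correct + 1L
    }
    ev <- loocvAccuracy(pe, sig, k = k)
    expect_equal(ev@nCorrect, correct)
    expect_equal(signatureAccuracy(ev), 100 * correct / ncol(x))
  }
})

test_that("LOOCV accuracy sits near 50% under shuffled labels", {
  set.seed(47)
  x <- matrix(rnorm(5 * 100), 5, 100,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:100)))
  pe <- PhenotypeExperiment(x, sample(rep(c("A", "B"), 50)), scale = "log2",
                            classLevels = c("A", "B"))
  acc <- signatureAccuracy(loocvAccuracy(pe, paste0("g", 1:5)))
  expect_lt(abs(acc - 50), 10)
})

test_that("LOOCV accuracy is invariant to sample order and class renaming", {
  pe <- makeExperiment(8, c(7, 7), delta = 1, nPlanted = 4, seed = 51)
  sig <- paste0("g00", 1:4)
  base <- signatureAccuracy(loocvAccuracy(pe, sig))
  set.seed(52)
  perm <- sample(ncol(pe))
  peP <- PhenotypeExperiment(exprValues(pe)[, perm],
                             as.character(phenoClasses(pe))[perm],
                             scale = "log2", classLevels = c("A", "B"))
  expect_equal(signatureAccuracy(loocvAccuracy(peP, sig)), base)
  ren <- c(A = "ctrl", B = "case")[as.character(phenoClasses(pe))]
  peR <- PhenotypeExperiment(exprValues(pe), ren, scale = "log2",
                             classLevels = c("ctrl", "case"))
  expect_equal(signatureAccuracy(loocvAccuracy(peR, sig)), base)
})

test_that("holdout validation accuracy scores only the held-out samples", {
  pe <- makeExperiment(4, c(8, 8), delta = 40, nPlanted = 2, seed = 53)
  ev <- holdoutAccuracy(pe, c("g001", "g002"), trainIdx = c(1:6, 9:14),
                        validIdx = c(7, 8, 15, 16))
  expect_equal(ev@nEvaluated, 4L)
  expect_equal(signatureAccuracy(ev), 100)
  expect_equal(ev@evaluation, "holdout_validation")
})

test_that("smallest-scale signature keeps a single perfect gene", {
  pe <- makeExperiment(10, c(6, 6), delta = 50, nPlanted = 1, seed = 61)
  ranked <- rankGenes(geneStatistics(pe), 0)
  sig <- smallestScaleSignature(pe, ranked)
  expect_identical(signatureGenes(sig), "g001")
  expect_equal(signatureAccuracy(sig), 100)
})

test_that("prefix search equals exhaustive per-prefix evaluation on 15 genes", {
  pe <- makeExperiment(15, c(8, 8), delta = 1.1, nPlanted = 6, seed = 63)
  ranked <- rankGenes(geneStatistics(pe), 0)[1:15]
  sig <- smallestScaleSignature(pe, ranked, maxPrefix = 15)
  # independently coded: evaluate every prefix from scratch via loocvAccuracy
  accs <- vapply(seq_along(ranked), function(i) {
    signatureAccuracy(loocvAccuracy(pe, ranked[seq_len(i)]))
  }, numeric(1))
  best <- which.max(accs)   # smallest index attaining the max
  expect_length(signatureGenes(sig), best)
  expect_equal(signatureAccuracy(sig), accs[best])
  expect_equal(attr(sig, "accuracies"), accs)
})

test_that("pure-noise genes appended after the optimum never lengthen the signature", {
  pe <- makeExperiment(20, c(8, 8), delta = 30, nPlanted = 2, seed = 65)
  ranked <- rankGenes(geneStatistics(pe), 0)
  short <- smallestScaleSignature(pe, ranked[1:3])
  long <- smallestScaleSignature(pe, ranked)
  expect_lte(length(signatureGenes(long)), length(signatureGenes(short)) + 0)
  expect_identical(signatureGenes(long), signatureGenes(short))
})

test_that("smallest-scale search is deterministic given ranking and k", {
  pe <- makeExperiment(12, c(7, 7), delta = 1, nPlanted = 5, seed = 67)
  ranked <- rankGenes(geneStatistics(pe), 0)
  s1 <- smallestScaleSignature(pe, ranked)
  s2 <- smallestScaleSignature(pe, ranked)
  expect_identical(signatureGenes(s1), signatureGenes(s2))
  expect_identical(signatureAccuracy(s1), signatureAccuracy(s2))
})
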