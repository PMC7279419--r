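test_that("holdout split sizes follow the floor rule", {
  # 4 samples (2 + 2) at 0.75 -> 3 train, 1 validation
  bags <- generateHoldouts(factor(c("A", "A", "B", "B")), 3, seed = 1)
  for (b in bags) {
    expect_length(b@trainIdx, 3L)
    expect_length(b@validIdx, 1L)
  }
  # 329 samples split 225 / 104 at 0.75 -> 246 train, 83 validation,
  # matching per-class floors (168 + 78)
  cl <- factor(rep(c("case", "ctrl"), c(225, 104)), levels = c("ctrl", "case"))
  bags <- generateHoldouts(cl, 2, seed = 1)
  for (b in bags) {
    expect_length(b@trainIdx, 246L)
    expect_length(b@validIdx, 83L)
    expect_equal(sum(cl[b@trainIdx] == "case"), 168L)
    expect_equal(sum(cl[b@trainIdx] == "ctrl"), 78L)
  }
})

test_that("holdout bags partition the samples and are seed-reproducible", {
  cl <- factor(rep(c("A", "B"), c(14, 10)))
  b1 <- generateHoldouts(cl, 10, seed = 99)
  b2 <- generateHoldouts(cl, 10, seed = 99)
  b3 <- generateHoldouts(cl, 10, seed = 100)
  for (i in seq_along(b1)) {
    expect_identical(b1[[i]]@trainIdx, b2[[i]]@trainIdx)
    expect_length(intersect(b1[[i]]@trainIdx, b1[[i]]@validIdx), 0L)
    expect_setequal(c(b1[[i]]@trainIdx, b1[[i]]@validIdx), seq_along(cl))
  }
  expect_false(identical(b3[[1]]@trainIdx, b1[[1]]@trainIdx))
  # distinct index sets across bags with overwhelming probability
  expect_gt(length(unique(lapply(b1, function(b) b@trainIdx))), 8L)
})

test_that("a dominant planted gene appears in nearly all bag signatures", {
  # strong effect: delta = 2 sigma
  pe <- makeExperiment(120, c(20, 20), delta = 2, sd = 1, nPlanted = 1,
                       seed = 71)
  bags <- runHoldoutSampler(pe, nBags = 200, seed = 71)
  withSig <- Filter(function(b) length(b@signature@genes) > 0, bags)
  hit <- mean(vapply(withSig, function(b) "g001" %in% b@signature@genes,
                     logical(1)))
  expect_gte(hit, 0.95)
})

test_that("the sampler is deterministic given seed and configuration", {
  pe <- makeExperiment(60, c(10, 10), delta = 1.5, nPlanted = 3, seed = 73)
  b1 <- runHoldoutSampler(pe, nBags = 20, seed = 5)
  b2 <- runHoldoutSampler(pe, nBags = 20, seed = 5)
  expect_identical(lapply(b1, function(b) b@signature@genes),
                   lapply(b2, function(b) b@signature@genes))
  expect_identical(vapply(b1, function(b) b@validationAccuracy, numeric(1)),
                   vapply(b2, function(b) b@validationAccuracy, numeric(1)))
})

test_that("bags whose FR filter retains nothing get empty signatures and 0 accuracy", {
  pe <- makeExperiment(40, c(15, 15), delta = 0, seed = 75)
  bags <- runHoldoutSampler(pe, frCutoff = 50, nBags = 5, seed = 75)
  for (b in bags) {
    expect_length(b@signature@genes, 0L)
    expect_equal(b@validationAccuracy, 0)
  }
  expect_warning(filterByAccuracy(bags, 0), "no bags")
})

test_that("noise-only data gives chance-level validation accuracy (no leakage)", {
  pe <- makeExperiment(300, c(20, 20), delta = 0, seed = 77)
  bags <- runHoldoutSampler(pe, frCutoff = 0.4, nBags = 200, seed = 77)
  acc <- vapply(Filter(function(b) length(b@signature@genes) > 0, bags),
                function(b) b@validationAccuracy, numeric(1))
  expect_gt(length(acc), 50)
  expect_lt(abs(mean(acc) - 50), 10)
})

test_that("accuracy filtering is strict and monotone", {
  pe <- makeExperiment(30, c(8, 8), delta = 2, nPlanted = 2, seed = 79)
  bags <- runHoldoutSampler(pe, nBags = 30, seed = 79)
  accs <- c(79, 80, 81)
  fake <- lapply(seq_along(accs), function(i) {
    b <- bags[[i]]; b@validationAccuracy <- accs[i]; b
  })
  expect_length(filterByAccuracy(fake, 80), 1L)         # only 81 survives
  nKept <- vapply(c(0, 25, 50, 75, 90, 100),
                  function(t) length(suppressWarnings(filterByAccuracy(bags, t))),
                  integer(1) + 0)
  expect_true(all(diff(nKept) <= 0))
})

test_that("frequency table reproduces both printed frequency conventions", {
  # 997 appearances among 43202 sampled slots -> 2.31%; 997 of 1000 holdouts
  # -> 99.7% under the per-holdout convention
  expect_equal(round(100 * 997 / 43202, 2), 2.31)
  mk <- function(genes) methods::new("HoldoutBag", bagId = 1L,
    trainIdx = 1L, validIdx = 2L, rankedGenes = genes,
    signature = methods::new("SignatureEvaluation", genes = genes,
      accuracy = 100, nCorrect = 1L, nEvaluated = 1L, evaluation = "loocv"),
    validationAccuracy = 100)
  bags <- c(lapply(1:3, function(i) mk(c("X", "Y"))), list(mk(c("X", "Z"))))
  ft <- frequencyTable(bags)
  df <- frequencyData(ft)
  expect_equal(ft@totalSlots, 8L)                       # conservation
  expect_equal(sum(df$count), 8L)
  expect_equal(df$freqSlots[df$probeId == "X"], 100 * 4 / 8)
  expect_equal(df$freqBags[df$probeId == "X"], 100 * 4 / 4)
  expect_equal(df$freqBags[df$probeId == "Y"], 75)
  expect_false(is.unsorted(-df$freqSlots))
  expect_true(all(df$freqSlots > 0 & df$freqSlots <= 100))
  # single bag with a single gene -> 100%
  one <- frequencyTable(list(mk("A")))
  expect_equal(frequencyData(one)$freqSlots, 100)
})

test_that("posterior weights are normalized exponentials of accuracy", {
  mkAcc <- function(acc, id) methods::new("HoldoutBag", bagId = id,
    trainIdx = 1L, validIdx = 2L, rankedGenes = "X",
    signature = methods::new("SignatureEvaluation", genes = "X",
      accuracy = acc, nCorrect = 0L, nEvaluated = 0L, evaluation = "loocv"),
    validationAccuracy = acc)
  equal <- lapply(1:4, function(i) mkAcc(85, i))
  expect_equal(unname(posteriorWeights(equal)), rep(0.25, 4))
  two <- posteriorWeights(list(mkAcc(100, 1L), mkAcc(0, 2L)))
  expect_equal(unname(two), c(1 / (1 + exp(-100)), exp(-100) / (1 + exp(-100))))
  set.seed(81)
  accs <- runif(10, 0, 100)
  w <- posteriorWeights(lapply(seq_along(accs), function(i)
    mkAcc(accs[i], i)))
  expect_equal(unname(w), exp(accs) / sum(exp(accs)), tolerance = 1e-12)
  expect_equal(sum(w), 1)
})

test_that("per-bag rankings use only the training samples", {
  pe <- makeExperiment(50, c(12, 12), delta = 1.5, nPlanted = 3, seed = 83)
  bags <- runHoldoutSampler(pe, nBags = 5, seed = 83)
  x <- exprValues(pe)
  cl <- as.integer(phenoClasses(pe))
  for (b in bags[1:2]) {
    tr <- b@trainIdx
    fr <- vapply(rownames(x), function(g) {
      a <- x[g, tr[cl[tr] == 1]]; bb <- x[g, tr[cl[tr] == 2]]
      (mean(a) - mean(bb))^2 / (popSd(a)^2 + popSd(bb)^2)
    }, numeric(1))
    keep <- names(fr)[fr > 0.5]
    oracle <- keep[order(fr[keep], decreasing = TRUE)]
    expect_identical(b@rankedGenes, oracle)
  }
})
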