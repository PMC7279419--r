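# Shared fixtures for the suite.

# reference per-gene statistics (group means with printed FC/FR) for the
# LOAD/MCI comparisons, used in the worked-example checks
referenceStats <- function() {
  utils::read.delim(
    system.file("extdata", "reference_gene_stats.tsv",
                package = "phenoSampler"),
    stringsAsFactors = FALSE)
}

# small labeled log2-scale experiment with controllable separation
makeExperiment <- function(nProbes, nPerClass, delta = 0, sd = 1,
                           seed = 1, nPlanted = 0) {
  set.seed(seed)
  n <- sum(nPerClass)
  x <- matrix(rnorm(nProbes * n, mean = 10, sd = sd), nProbes, n,
              dimnames = list(sprintf("g%03d", seq_len(nProbes)),
                              sprintf("s%03d", seq_len(n))))
  classes <- rep(c("A", "B"), nPerClass)
  if (nPlanted > 0) {
    x[seq_len(nPlanted), classes == "B"] <-
      x[seq_len(nPlanted), classes == "B"] - delta
  }
  PhenotypeExperiment(x, classes, scale = "log2", classLevels = c("A", "B"))
}

# population-SD helper for brute-force oracles
popSd <- function(v) sqrt(mean((v - mean(v))^2))
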