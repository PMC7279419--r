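---
title: "Sampling the uncertainty space of phenotype prediction"
author: "phenoSampler"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sampling the uncertainty space of phenotype prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenoSampler)
```

## The problem

Two-class phenotype prediction from expression data — e.g. separating
Late-Onset Alzheimer's Disease (LOAD) or Mild Cognitive Impairment (MCI)
patients from healthy controls (HC) using blood microarray intensities — is
massively underdetermined: tens of thousands of probes against a few hundred
subjects. Many different small gene lists classify the phenotype equally
well, so any single "best" signature is an arbitrary point in a large
equivalence region of the classifier. phenoSampler implements a resampling
strategy that *samples* that region instead of collapsing it: many random
75/25 train/validation holdouts, a minimal high-accuracy signature per
holdout, and a posterior frequency analysis that separates *header genes*
(selected consistently, the robust explanation of the phenotype) from
*helper genes* (selected through noise and underdeterminacy).

## Model and procedure

**Per-gene statistics.** For probe $g$ with class means $\mu_1,\mu_2$ and
standard deviations $\sigma_1,\sigma_2$ on the $\log_2$ scale, the Fisher's
ratio is

$$\mathrm{FR}(g) = \frac{(\mu_1-\mu_2)^2}{\sigma_1^2+\sigma_2^2},$$

a symmetric, shift-invariant separability score. The exact two-class variant
in the literature varies; we use the sum-of-variances form with population
(ddof = 0) standard deviations, which reproduces the behaviour of the
reference tables (the printed precision cannot distinguish population from
sample SDs). FR is always computed on $\log_2$ intensities; the fold change
$\mathrm{FC} = \log_2(\mu_A/\mu_B)$ is computed from the group means on
whatever scale the matrix carries, with the control-like class in the
numerator so that positive FC means underexpression in cases. On
$\log_2$-scale matrices a group mean can be non-positive, where FC is
reported as `NA` rather than an error.

**Classifier and accuracy.** The classifier $L^*(g)$ is k-nearest-neighbors
(Euclidean metric) on the signature's probes, and
$\mathrm{Acc}(g) = 100 \cdot n_\text{correct}/n$ so that accuracy plus
percentage prediction error is 100. The neighbor count is never specified in
the methodology this implements; we default to $k=1$ (the "simple" reading),
require $k$ odd so two-class votes cannot tie, and break distance ties by
lowest sample index so reruns are bit-identical. `class::knn` is not used
internally precisely because its tie-breaking is randomized; it serves as an
independent cross-check in the test suite.

**Smallest-scale signature.** Candidate signatures are *prefixes* of the
FR-descending ranking (probes with FR above a cut-off, 0.5 by default): the
accuracy columns of the reference tables are cumulative over ranked genes,
which a prefix scheme reproduces structurally, and nested signatures make
the search $O(\text{maxPrefix})$ instead of exponential. Every prefix
$g_1..g_i$, $i \le$ `maxPrefix` (default 200, which covers the longest
reported optima of ~118 genes), is scored by LOOCV, and the shortest prefix
attaining the maximum accuracy wins. The implementation grows the pairwise
squared-distance matrix by one rank-one update per gene, so the whole
accuracy curve costs one pass.

**The holdout sampler.** For each of `nBags` (reference configuration 1000)
random stratified 75/25 partitions: rank genes by FR *on the training
samples only* (no leakage into validation), learn the smallest-scale
signature on the training portion, and blind-validate it on the held-out
25%. Bags whose validation accuracy exceeds 80% (strictly — "higher than")
are accepted, and gene sampling frequencies are tabulated over the accepted
signatures under two conventions that the reference bookkeeping defines:
per sampled slot (997 appearances among 43202 slots = 2.31%) and per
holdout (997 of 1000 = 99.7%). Accepted bags can also be weighted by
normalized exponentials of their accuracy,
$P(c_{obs}|g) = k\,e^{\mathrm{Acc}(g)}$, computed with the usual max-shift
stabilization.

One split-rule subtlety: the holdout is stratified, and the two size
conventions quoted for it (per-class floors; total floor) disagree on tiny
classes. We allocate $\lfloor 0.75\,n \rfloor$ total training slots across
classes by largest-remainder apportionment (ties to the control class),
which reproduces both documented examples exactly — 4 samples (2+2) give a
3/1 split, and 225 + 104 samples give 246 train / 83 validation with
per-class counts 168 + 78. Per-bag RNG seeds derive from the root seed by a
bag counter, so bag $b$ is reproducible independently of how many bags run.

**Alternative samplers.** Two comparison samplers probe *biological
invariance* — the idea that pathways implicated in a disease should not
depend on the algorithm used to find them. The Fisher's-ratio sampler draws
a signature size uniformly in 1..`maxSignatureSize`, then draws that many
distinct probes with probability proportional to FR among probes passing
the cut-off, scores by LOOCV, and accepts above the threshold; this is a
direct prior-times-likelihood sampler with the discriminatory-power prior.
The Random-Forest sampler fits bootstrap CART trees with $\sqrt{p}$ random
features per split (Gini impurity, via the randomForest package) and defines a
probe's frequency as the fraction of trees using it in at least one split —
a per-tree usage fraction, consistent with the small (≤ 0.25) frequency
scale of the reference output; normalized mean-decrease-in-Gini is
available behind the `importance` flag. `compareSamplers()` summarises
agreement by top-$n$ Jaccard overlap and Spearman rank correlation of
shared genes.

**Correlation networks and enrichment.** The published networks are
described with "sub-tree" vocabulary but without an algorithm; we adopt the
maximum spanning tree on absolute Pearson correlation (computed across all
samples of the comparison, not per class — the source is silent, and the
pooled choice is declared) with signed $r$ carried on edges, and offer a
threshold graph as the alternative. Over-representation of the most
frequently sampled genes in local GMT gene-set collections uses the
hypergeometric upper tail with Benjamini–Hochberg adjustment — a local
stand-in for the online ontological platforms, which are out of scope.

## The regression demonstrator

The intuition for the whole pipeline comes from linear regression. For
$y \approx a_0 + a_1 x$ the set of parameter pairs whose *relative misfit*
$\lVert y_{obs} - F m\rVert / \lVert y_{obs}\rVert$ stays below a tolerance
is an ellipse centred at the least-squares solution, with axes governed by
the eigenstructure of $F^\top F$:
$\lVert y - Fm\rVert^2 = \mathrm{RSS} + (m-\hat m)^\top F^\top F (m-\hat m)$.
Refitting on random 75% subsets samples this ellipse, most densely along
the eigenvector of the smallest eigenvalue (the axis of maximum
uncertainty). `demoRegression()` reproduces this numerically; with 10%
relative noise and tolerance 0.2, essentially all of 500 bagged solutions
fall inside the region and their principal spread axis aligns with the
minimal eigenvector to well under 15 degrees. The quoted tolerance for the
original illustration is 15% in one place and 20% in another, so the demo
exposes `tol` as a parameter (default 0.15).

## The synthetic cohort generator

Real cohort data (38323 probes; 145 LOAD / 80 MCI / 104 HC) is not
redistributable, so every stage is validated against `simulateCohort()`,
which emulates the relevant structure with known ground truth: log-normal
intensities (Gaussian on $\log_2$ — the statistics are defined on that
scale and raw array means are positive and right-skewed), a probe-specific
baseline drawn from U(6, 14) $\log_2$ units (typical array dynamic range),
within-group SD $\sigma$, and a planted minority of differential probes
shifted by $\pm\delta$ in the case class, 90% of them downwards by default
(case-underexpression dominates the reference comparisons). The theoretical
Fisher's ratio of a planted probe is $\delta^2/(2\sigma^2)$, which the
tests use for calibration: $\sigma = 0.8$, $\delta = \sqrt{2\cdot1.29}\,
\sigma$ reproduces the headline maximum FR of 1.29. Matrices are exported
on the raw scale ($2^x$) so pipelines exercise the `log2Transform()` path.

The default *desk-scale* study conditions — 2000 probes, 60 + 60 samples,
20 planted probes at $\delta = 1.5\sigma$ ($\sigma = 0.8$), 300 bags — run
the full sampler in seconds per seed and were chosen once as a realistic
miniature; they are the conditions under which the acceptance checks
measure recovery. What the generator deliberately does **not** emulate:
probe-level array artifacts (batch effects, background, missingness),
correlation structure between probes, heavy-tailed noise, and three-class
generative structure beyond pairwise relabeling. Passing tests therefore
demonstrate correctness of the machinery and calibration under the stated
model, not performance on real arrays.

## Numerical choices and degenerate inputs

- Sorting is stable everywhere (radix), with input-order tie-breaking, so
  rankings and reruns are bit-identical; raising the FR cut-off never
  reorders surviving probes.
- A probe with zero variance in both groups is a degenerate input for
  `fisherRatio()` (error); inside the per-bag ranking its FR is treated as
  0 so one flat probe cannot abort a 1000-bag run.
- A bag whose training FR filter retains nothing is recorded with an empty
  signature and 0 accuracy and is excluded downstream; zero-variance genes
  are dropped from correlation networks with a warning; degenerate
  regression bags (all abscissas equal) are redrawn.
- The acceptance threshold and the FR cut-off are strict inequalities.
- `posteriorWeights()` uses max-shifted exponentials, exact for accuracy
  differences down to machine precision.

## Known limitations

On a fixed noise realisation, resampling does not make null sampling
frequencies uniform: probes whose full-data FR lands in the extreme tail
pass the per-bag filter in most bags, so even pure-noise cohorts show
frequency concentration (this is precisely the helper-gene effect the
method is designed to damp, and the frequency analysis ranks such probes —
it cannot erase them). Validation accuracy, by contrast, is unbiased around
chance on null data, which the tests assert. Other limitations: FR assumes
roughly symmetric unimodal within-class distributions; prefix search can
miss non-nested optimal subsets by construction; the RF frequency
normalization is a declared choice (per-tree usage fraction) since the
published scale is not defined; and the reported cohort-level accuracies of
the original study (84% / 81.5% / 74%) require the original cohort and are
explicitly out of scope.

## A compact run

```{r example, eval = FALSE}
sim <- simulateCohort(cohortSpec(seed = 1))
pe <- log2Transform(sim$experiment)
bags <- runHoldoutSampler(pe, nBags = 300, seed = 1)
accepted <- filterByAccuracy(bags, 80)
head(frequencyData(frequencyTable(accepted)))
net <- correlationNetwork(pe, head(frequencyData(
  frequencyTable(accepted))$probeId, 10))
```
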