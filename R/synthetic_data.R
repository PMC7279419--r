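#' Specification of a synthetic two-class cohort
#'
#' Parameters of the log-normal cohort generator: per-probe log2 intensities
#' are Gaussian with a probe-specific baseline drawn uniformly from
#' \code{baselineRange} and within-group SD \code{withinSd}; a planted
#' minority of probes is shifted by \code{effectSize} log2 units in the case
#' class, a fraction \code{fractionUnderexpressed} of them downwards
#' (underexpressed in cases, the direction dominating the reference cohort).
#' The defaults are the desk-scale study conditions: 2000 probes, 60 + 60
#' samples, 20 planted probes at an effect of 1.5 standard deviations.
#'
#' @param nPerClass length-2 integer, samples in the control and case class.
#' @param nProbes total number of probes.
#' @param nDifferential number of planted differential probes
#'   (<= \code{nProbes}).
#' @param effectSize mean log2 shift of planted probes (delta).
#' @param withinSd within-group SD on the log2 scale (sigma > 0).
#' @param baselineRange length-2 numeric, range of per-probe baseline log2
#'   means.
#' @param fractionUnderexpressed fraction of planted probes underexpressed in
#'   cases.
#' @param classNames length-2 character, control-like class first.
#' @param seed integer seed; identical spec and seed give bit-identical
#'   cohorts.
#' @return A list of class \code{"cohortSpec"}.
#' @export
cohortSpec <- function(nPerClass = c(60L, 60L), nProbes = 2000L,
                       nDifferential = 20L, effectSize = 1.2,
                       withinSd = 0.8, baselineRange = c(6, 14),
                       fractionUnderexpressed = 0.9,
                       classNames = c("HC", "CASE"), seed = 1L) {
  spec <- list(nPerClass = as.integer(nPerClass), nProbes = as.integer(nProbes),
               nDifferential = as.integer(nDifferential),
               effectSize = effectSize, withinSd = withinSd,
               baselineRange = baselineRange,
               fractionUnderexpressed = fractionUnderexpressed,
               classNames = classNames, seed = as.integer(seed))
  if (length(spec$nPerClass) != 2L || any(spec$nPerClass < 4L)) {
    stop("both class sizes must be >= 4")
  }
  if (spec$nDifferential > spec$nProbes) {
    stop("nDifferential cannot exceed nProbes")
  }
  if (spec$withinSd <= 0) stop("withinSd must be positive")
  if (spec$fractionUnderexpressed < 0 || spec$fractionUnderexpressed > 1) {
    stop("fractionUnderexpressed must lie in [0, 1]")
  }
  structure(spec, class = "cohortSpec")
}

#' Simulate a synthetic cohort with planted differential probes
#'
#' Draws a cohort per the [cohortSpec()]: Gaussian log2 intensities, planted
#' case-class shifts, and export on the raw scale via 2^value so downstream
#' analysis exercises the [log2Transform()] path. The theoretical Fisher's
#' ratio of a planted probe is delta^2 / (2 sigma^2).
#'
#' @param spec a [cohortSpec()].
#' @return List with \code{experiment} (raw-scale
#'   [PhenotypeExperiment-class]) and \code{truth} (data.frame of planted
#'   \code{probeId}, \code{delta}, \code{direction}: \code{"down"} =
#'   underexpressed in cases).
#' @export
simulateCohort <- function(spec) {
  if (!inherits(spec, "cohortSpec")) stop("'spec' must come from cohortSpec()")
  set.seed(spec$seed)
  n <- sum(spec$nPerClass)
  probes <- sprintf("probe%05d", seq_len(spec$nProbes))
  samples <- sprintf("s%03d", seq_len(n))
  classes <- rep(spec$classNames, spec$nPerClass)
  baseline <- stats::runif(spec$nProbes, spec$baselineRange[1L],
                           spec$baselineRange[2L])
  x <- matrix(stats::rnorm(spec$nProbes * n, mean = baseline,
                           sd = spec$withinSd),
              nrow = spec$nProbes, ncol = n,
              dimnames = list(probes, samples))
  truth <- data.frame(probeId = character(), delta = numeric(),
                      direction = character(), stringsAsFactors = FALSE)
  if (spec$nDifferential > 0L) {
    planted <- sort(sample.int(spec$nProbes, spec$nDifferential))
    nDown <- round(spec$fractionUnderexpressed * spec$nDifferential)
    sign <- rep(c(-1, 1), c(nDown, spec$nDifferential - nDown))
    caseCols <- which(classes == spec$classNames[2L])
    x[planted, caseCols] <- x[planted, caseCols] + sign * spec$effectSize
    truth <- data.frame(probeId = probes[planted],
                        delta = spec$effectSize * sign,
                        direction = ifelse(sign < 0, "down", "up"),
                        stringsAsFactors = FALSE)
  }
  pe <- PhenotypeExperiment(2^x, classes, scale = "raw",
                            classLevels = spec$classNames)
  list(experiment = pe, truth = truth)
}

#' Deterministic worked-example fixture
#'
#' A hand-computable 6-probe, 8-sample log2-scale experiment used across the
#' unit tests: per probe, the control group takes the values
#' (b, b, b + 2, b + 2) (population SD exactly 1) and the case group the same
#' values shifted down by a probe-specific gap, so Fisher's ratios are
#' gap^2 / 2 and strictly decreasing by construction.
#'
#' @return A log2-scale [PhenotypeExperiment-class] with classes HC/CASE.
#' @export
workedExample <- function() {
  gaps <- c(2, 1.8, 1.6, 1.2, 0.8, 0)
  b <- 9
  hc <- c(b, b, b + 2, b + 2)
  x <- t(vapply(gaps, function(g) c(hc, hc - g), numeric(8L)))
  dimnames(x) <- list(paste0("p", seq_along(gaps)), paste0("s", 1:8))
  PhenotypeExperiment(x, rep(c("HC", "CASE"), each = 4L), scale = "log2",
                      classLevels = c("HC", "CASE"))
}
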