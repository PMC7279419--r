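# Didactic linear-regression demonstrator of the equivalence-region idea:
# the set of lines y = a0 + a1 x whose relative misfit stays below a
# tolerance is an ellipse governed by the eigenstructure of F'F, and bagged
# least-squares refits sample that ellipse anisotropically.

.designMatrix <- function(x) cbind(`(Intercept)` = 1, x = x)

#' Least-squares fit of a straight line
#'
#' Solves F m = y_obs in the least-squares sense for m = (a0, a1), where F
#' has a unit column and the abscissas.
#'
#' @param x,y numeric vectors of equal length >= 2; at least two distinct x
#'   values.
#' @return Named numeric length-2 vector \code{c(a0, a1)}.
#' @examples
#' leastSquaresFit(c(0, 1), c(1, 3))  # (1, 2), exact interpolation
#' @export
leastSquaresFit <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  if (length(unique(x)) < 2L) {
    stop("at least two distinct abscissas are required (rank-deficient design)")
  }
  fit <- stats::lm.fit(.designMatrix(x), y)
  stats::setNames(fit$coefficients, c("a0", "a1"))
}

#' Relative misfit of a candidate model
#'
#' ||y_obs - F m||_2 / ||y_obs||_2: the misfit of the line m = (a0, a1)
#' relative to the size of the observations.
#'
#' @inheritParams leastSquaresFit
#' @param m numeric length-2 model (a0, a1).
#' @return Non-negative numeric. Errors when \code{y} is the zero vector.
#' @export
relativeMisfit <- function(x, y, m) {
  stopifnot(length(m) == 2L)
  ny <- sqrt(sum(y^2))
  if (ny == 0) stop("zero observation vector: relative misfit undefined")
  sqrt(sum((y - .designMatrix(x) %*% m)^2)) / ny
}

#' Equivalence-region ellipse of a linear regression
#'
#' Builds the tolerance region M_tol = { m : ||y - F m|| / ||y|| < tol }.
#' Writing m-hat for the least-squares center and using
#' ||y - F m||^2 = RSS + (m - m-hat)' F'F (m - m-hat), membership is the
#' ellipse test (m - m-hat)' F'F (m - m-hat) < tol^2 ||y||^2 - RSS, with axes
#' along the eigenvectors of F'F and lengths inverse to the square roots of
#' its eigenvalues.
#'
#' @inheritParams leastSquaresFit
#' @param tol relative-misfit tolerance in (0, 1].
#' @return A [ToleranceEllipse-class].
#' @export
toleranceEllipse <- function(x, y, tol = 0.15) {
  stopifnot(tol > 0)
  center <- leastSquaresFit(x, y)
  F <- .designMatrix(x)
  FtF <- crossprod(F)
  e <- eigen(FtF, symmetric = TRUE)
  rss <- sum((y - F %*% center)^2)
  methods::new("ToleranceEllipse",
    center = center, tol = tol, FtF = FtF,
    eigenvalues = e$values, eigenvectors = e$vectors,
    rss = rss, yNormSq = sum(y^2))
}

#' Equivalence-region membership test
#'
#' TRUE iff the relative misfit of \code{m} is strictly below the tolerance.
#' Regions are nested: a member at tol1 < tol2 is a member at tol2.
#'
#' @param ellipse a [ToleranceEllipse-class], or NULL to test directly from
#'   data via \code{x}, \code{y}, \code{tol}.
#' @param m numeric length-2 model (a0, a1).
#' @param x,y,tol used only when \code{ellipse} is NULL.
#' @return Logical.
#' @export
inToleranceRegion <- function(m, ellipse = NULL, x = NULL, y = NULL,
                              tol = NULL) {
  if (is.null(ellipse)) {
    return(relativeMisfit(x, y, m) < tol)
  }
  dm <- m - ellipse@center
  qf <- drop(t(dm) %*% ellipse@FtF %*% dm)
  qf < ellipse@tol^2 * ellipse@yNormSq - ellipse@rss
}

#' Bagged least-squares solutions
#'
#' Refits the line on many random subsets holding \code{fraction} of the data
#' points, mirroring the 75/25 holdout idea: each bagged solution is an
#' equivalent model, and together they sample the equivalence-region ellipse,
#' most densely along the axis of maximum uncertainty (the eigenvector of the
#' smallest eigenvalue of F'F). Degenerate bags (all abscissas equal) are
#' redrawn.
#'
#' @inheritParams leastSquaresFit
#' @param nBags number of bags (default 500).
#' @param fraction fraction of points per bag (default 0.75).
#' @param seed integer root seed.
#' @return nBags x 2 matrix of (a0, a1) solutions, one row per bag.
#' @export
bagRegressionSolutions <- function(x, y, nBags = 500L, fraction = 0.75,
                                   seed = 1L) {
  stopifnot(length(x) == length(y), nBags >= 1L,
            fraction > 0, fraction < 1)
  s <- length(x)
  m <- max(2L, floor(fraction * s))
  out <- matrix(NA_real_, nBags, 2L, dimnames = list(NULL, c("a0", "a1")))
  for (b in seq_len(nBags)) {
    set.seed(.bagSeed(seed, b))
    repeat {
      idx <- sample.int(s, m)
      if (length(unique(x[idx])) >= 2L) break
    }
    out[b, ] <- leastSquaresFit(x[idx], y[idx])
  }
  out
}

#' Regression uncertainty demonstration
#'
#' Generates a noisy straight-line data set, fits it, bags it, and summarises
#' how the bagged solutions populate the equivalence region: the fraction
#' inside the tolerance ellipse and the angle between their principal spread
#' axis and the minimal-eigenvalue eigenvector of F'F.
#'
#' @param nPoints number of data points (default 30).
#' @param a0,a1 true intercept and slope of the generating line.
#' @param relNoise relative Gaussian noise amplitude (default 0.1).
#' @param tol equivalence-region tolerance (default 0.15; the companion
#'   narrative also quotes 20%, so the demo exposes it as a parameter).
#' @param nBags number of bagged refits (default 500).
#' @param seed integer seed.
#' @return List: \code{x}, \code{y}, \code{fit}, \code{ellipse},
#'   \code{solutions}, \code{insideFraction}, \code{alignmentAngleDeg}.
#' @export
demoRegression <- function(nPoints = 30L, a0 = 1, a1 = 2, relNoise = 0.1,
                           tol = 0.15, nBags = 500L, seed = 1L) {
  set.seed(.bagSeed(seed, 0L))
  x <- seq(0, 10, length.out = nPoints)
  clean <- a0 + a1 * x
  y <- clean + stats::rnorm(nPoints, sd = relNoise * sqrt(mean(clean^2)))
  ell <- toleranceEllipse(x, y, tol = tol)
  sols <- bagRegressionSolutions(x, y, nBags = nBags, seed = seed)
  inside <- vapply(seq_len(nrow(sols)), function(i) {
    inToleranceRegion(sols[i, ], ellipse = ell)
  }, logical(1L))
  # principal axis of the bagged cloud vs. the minimal eigenvector of F'F
  pc <- eigen(stats::cov(sols), symmetric = TRUE)$vectors[, 1L]
  vmin <- ell@eigenvectors[, which.min(ell@eigenvalues)]
  ang <- acos(min(1, abs(sum(pc * vmin)) /
                    (sqrt(sum(pc^2)) * sqrt(sum(vmin^2))))) * 180 / pi
  list(x = x, y = y, fit = ell@center, ellipse = ell, solutions = sols,
       insideFraction = mean(inside), alignmentAngleDeg = ang)
}
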