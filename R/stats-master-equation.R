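## Empirical estimation of the chemical master equation solution P(x, t):
## one shared set of state bins, one normalised across-run histogram per
## grid time. This module only estimates from ensembles; it never integrates
## the master equation numerically.

#' Empirical master-equation estimate over a time interval
#'
#' Builds a uniform [TimeGrid-class] over `[start, stop]`, resolves one shared
#' set of state-bin edges from the global minimum and maximum of `var` over
#' all runs and all grid points, and estimates the distribution of `var`
#' across runs at every grid time on those shared edges. Each row of the
#' result is a normalised probability mass function, so the matrix is the
#' ensemble estimate of the master-equation solution P(x, t) on the interval.
#'
#' Because sampling is zero-order hold and deterministic, refining the grid
#' never changes a time slice that coincides with a coarser grid point.
#'
#' @param ens an [Ensemble-class].
#' @param var variable name.
#' @param start,stop interval endpoints, `start < stop`.
#' @param nTimePoints number of grid times (default 50).
#' @param bins a [BinningSpec-class]; the default `"auto"` rule gives unit
#'   bins centred on integers for count data.
#' @return A [MasterEqEstimate-class].
#' @examples
#' m <- immigrationDeath(k = 5, mu = 1)
#' ens <- generateEnsemble(m, nRuns = 50, tMax = 4, seed = 1)
#' masterEquation(ens, "X", start = 0, stop = 4, nTimePoints = 9)
#' @export
masterEquation <- function(ens, var, start, stop, nTimePoints = 50L,
                           bins = binningSpec()) {
  stopifnot(is(ens, "Ensemble"))
  if (!(start < stop)) stop("parameter error: start must be < stop")
  if (nTimePoints < 1L) stop("parameter error: nTimePoints must be >= 1")
  grid <- timeGrid(start, stop, nTimePoints)
  j <- match(var, varNames(ens))
  .checkVar(ens@trajectories[[1L]], var)

  # one resample pass: samples[i, r] = value of var in run r at grid time i
  mats <- .resampleAll(ens, grid)
  samples <- vapply(mats, function(m) m[, j], numeric(grid@nPoints))
  samples <- matrix(samples, nrow = grid@nPoints)

  edges <- .resolveEdges(as.numeric(samples), bins)
  prob <- t(apply(samples, 1L, function(row) {
    cnt <- .binCounts(row, edges)
    cnt / sum(cnt)
  }))
  prob <- matrix(prob, nrow = grid@nPoints)  # guard the 1-bin edge case
  new("MasterEqEstimate", varName = var, grid = grid, binEdges = edges,
      prob = prob)
}
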