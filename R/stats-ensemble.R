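## Ensemble-level first and second moments on a shared time grid.

# Resample every run on the grid once; returns list of matrices.
.resampleAll <- function(ens, grid) {
  short <- FALSE
  out <- lapply(ens@trajectories, function(tr) {
    withCallingHandlers(resample(tr, grid),
      warning = function(w) { short <<- TRUE; invokeRestart("muffleWarning") })
  })
  if (short)
    warning("grid extends beyond the final recorded time of some runs: holding last values")
  out
}

#' Ensemble mean trace
#'
#' The across-run average of every variable on a shared time grid:
#' `mean(t, v) = (1/n) * sum over runs of sampleAt(run, t, v)`.
#'
#' @param ens an [Ensemble-class].
#' @param grid a [TimeGrid-class].
#' @return A [Trajectory-class] whose times are the grid points and whose
#'   values are the per-variable means.
#' @seealso [ensembleSD()]
#' @export
ensembleMean <- function(ens, grid) {
  stopifnot(is(ens, "Ensemble"), is(grid, "TimeGrid"))
  mats <- .resampleAll(ens, grid)
  acc <- Reduce(`+`, mats) / length(mats)
  Trajectory(gridPoints(grid), acc, varNames = varNames(ens))
}

#' Ensemble standard-deviation trace
#'
#' The across-run standard deviation of every variable on a shared time grid.
#' The default convention is the population form (divide by `n`), consistent
#' with the maximum-likelihood variance used by [gaussianFit()];
#' `unbiased = TRUE` switches to the `n - 1` denominator.
#'
#' @inheritParams ensembleMean
#' @param unbiased use the `n - 1` (sample) denominator instead of `n`.
#' @return A [Trajectory-class] of per-variable standard deviations.
#' @export
ensembleSD <- function(ens, grid, unbiased = FALSE) {
  stopifnot(is(ens, "Ensemble"), is(grid, "TimeGrid"))
  mats <- .resampleAll(ens, grid)
  n <- length(mats)
  m <- Reduce(`+`, mats) / n
  ss <- Reduce(`+`, lapply(mats, function(x) (x - m)^2))
  denom <- if (unbiased) max(n - 1L, 1L) else n
  Trajectory(gridPoints(grid), sqrt(ss / denom), varNames = varNames(ens))
}

#' Per-variable summary of an ensemble
#'
#' Global extrema of every variable over all runs and all recorded times
#' (exact, no resampling), plus the ensemble size and the overall time span.
#'
#' @param ens an [Ensemble-class].
#' @return A `data.frame` with one row per variable and columns `var`, `min`,
#'   `max`, `nRuns`, `tFirst`, `tLast`.
#' @export
ensembleSummary <- function(ens) {
  stopifnot(is(ens, "Ensemble"))
  vn <- varNames(ens)
  mins <- rep(Inf, length(vn)); maxs <- rep(-Inf, length(vn))
  tFirst <- Inf; tLast <- -Inf
  for (tr in ens@trajectories) {
    mins <- pmin(mins, apply(tr@values, 2L, min))
    maxs <- pmax(maxs, apply(tr@values, 2L, max))
    tFirst <- min(tFirst, tr@times[1L])
    tLast <- max(tLast, tr@times[length(tr@times)])
  }
  data.frame(var = vn, min = mins, max = maxs, nRuns = length(ens@trajectories),
             tFirst = tFirst, tLast = tLast, row.names = NULL)
}

#' Phase-space path of one trajectory
#'
#' Projects a run onto 2 or 3 selected variables at its recorded event times,
#' in time order: the variable-vs-variable view that reveals oscillations and
#' attractors.
#'
#' @param traj a [Trajectory-class].
#' @param vars 2 or 3 distinct variable names, in axis order.
#' @return A [PhasePath-class].
#' @export
phaseSpace <- function(traj, vars) {
  stopifnot(is(traj, "Trajectory"))
  if (!length(vars) %in% c(2L, 3L)) stop("phase space needs 2 or 3 variables")
  if (anyDuplicated(vars)) stop("phase-space variables must be distinct")
  for (v in vars) .checkVar(traj, v)
  new("PhasePath", varNames = as.character(vars),
      points = traj@values[, match(vars, traj@varNames), drop = FALSE],
      times = traj@times)
}

#' Phase-space path of the ensemble mean
#'
#' [phaseSpace()] applied to [ensembleMean()] on the given grid.
#'
#' @param ens an [Ensemble-class].
#' @param grid a [TimeGrid-class].
#' @param vars 2 or 3 distinct variable names.
#' @return A [PhasePath-class].
#' @export
phaseSpaceAvg <- function(ens, grid, vars) {
  phaseSpace(ensembleMean(ens, grid), vars)
}

#' Total variation distance between two discrete distributions
#'
#' `0.5 * sum(abs(p - q))`; the closeness metric used when comparing an
#' empirical density against an analytic law. Shorter of the two vectors is
#' zero-padded.
#'
#' @param p,q non-negative vectors (normalised probability vectors for the
#'   metric to lie in `[0, 1]`).
#' @return numeric distance.
#' @export
totalVariation <- function(p, q) {
  n <- max(length(p), length(q))
  length(p) <- n; length(q) <- n
  p[is.na(p)] <- 0; q[is.na(q)] <- 0
  0.5 * sum(abs(p - q))
}
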