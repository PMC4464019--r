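## Core sampling convention: zero-order hold on piecewise-constant paths.

# Index of the active row for each query time: largest k with times[k] <= t.
# Errors for t before the first time point; warns (once) past the last.
.holdIndex <- function(times, t) {
  if (anyNA(t)) stop("query time contains NA")
  if (any(t < times[1L]))
    stop(sprintf("query time %g is earlier than the first recorded time %g",
                 min(t), times[1L]))
  if (any(t > times[length(times)]))
    warning(sprintf(
      "query beyond the final recorded time %g: holding the last value",
      times[length(times)]))
  findInterval(t, times)
}

.checkVar <- function(x, var) {
  if (length(var) != 1L || !var %in% x@varNames)
    stop(sprintf("unknown variable '%s' (available: %s)",
                 paste(var, collapse = ","), paste(x@varNames, collapse = ", ")))
}

#' @rdname sampleAt
setMethod("sampleAt", "Trajectory", function(x, t, var) {
  .checkVar(x, var)
  unname(x@values[.holdIndex(x@times, t), match(var, x@varNames)])
})

#' @rdname resample
setMethod("resample", signature(x = "Trajectory", grid = "TimeGrid"),
  function(x, grid) {
    if (grid@start < x@times[1L])
      stop(sprintf("grid starts at %g, before the trajectory's first time %g",
                   grid@start, x@times[1L]))
    idx <- suppressWarnings(.holdIndex(x@times, gridPoints(grid)))
    m <- x@values[idx, , drop = FALSE]
    rownames(m) <- NULL
    m
  })

## Accessors -----------------------------------------------------------------

#' @rdname accessors
setMethod("varNames", "Trajectory", function(x) x@varNames)
#' @rdname accessors
setMethod("varNames", "Ensemble", function(x) x@trajectories[[1L]]@varNames)
#' @rdname accessors
setMethod("varNames", "PhasePath", function(x) x@varNames)
#' @rdname accessors
setMethod("varNames", "DensityEstimate", function(x) x@varName)
#' @rdname accessors
setMethod("varNames", "MasterEqEstimate", function(x) x@varName)

#' @rdname accessors
setMethod("trajTimes", "Trajectory", function(x) x@times)
#' @rdname accessors
setMethod("trajTimes", "PhasePath", function(x) x@times)
#' @rdname accessors
setMethod("trajValues", "Trajectory", function(x) x@values)

#' @rdname accessors
setMethod("trajectories", "Ensemble", function(x) x@trajectories)
#' @rdname accessors
setMethod("nRuns", "Ensemble", function(x) length(x@trajectories))

#' Number of member trajectories
#' @param x an [Ensemble-class].
#' @return integer count.
#' @export
setMethod("length", "Ensemble", function(x) length(x@trajectories))

#' Extract one member trajectory
#' @param x an [Ensemble-class].
#' @param i run index.
#' @return the i-th [Trajectory-class].
#' @export
setMethod("[[", "Ensemble", function(x, i) x@trajectories[[i]])

#' @rdname accessors
setMethod("gridPoints", "TimeGrid", function(x)
  if (x@nPoints == 1L) x@start else seq(x@start, x@stop, length.out = x@nPoints))
#' @rdname accessors
setMethod("gridPoints", "MasterEqEstimate", function(x) gridPoints(x@grid))

#' @rdname accessors
setMethod("binEdges", "DensityEstimate", function(x) x@binEdges)
#' @rdname accessors
setMethod("binEdges", "MasterEqEstimate", function(x) x@binEdges)
#' @rdname accessors
setMethod("binMass", "DensityEstimate", function(x) x@mass)
#' @rdname accessors
setMethod("densityFit", "DensityEstimate", function(x) x@fit)
#' @rdname accessors
setMethod("probMatrix", "MasterEqEstimate", function(x) x@prob)
#' @rdname accessors
setMethod("pathPoints", "PhasePath", function(x) x@points)

## show methods --------------------------------------------------------------

setMethod("show", "Trajectory", function(object) {
  cat(sprintf("Trajectory: %d time points over [%g, %g], %d variable(s): %s\n",
              length(object@times), object@times[1L],
              object@times[length(object@times)], length(object@varNames),
              paste(object@varNames, collapse = ", ")))
})

setMethod("show", "Ensemble", function(object) {
  spans <- vapply(object@trajectories,
                  function(tr) tr@times[length(tr@times)], numeric(1))
  cat(sprintf("Ensemble of %d trajectories, variables: %s\n",
              length(object@trajectories),
              paste(varNames(object), collapse = ", ")))
  cat(sprintf("  final times in [%g, %g]", min(spans), max(spans)))
  if (!is.na(object@provenance[1L]))
    cat(sprintf("; source: %s", object@provenance[1L]))
  cat("\n")
})

setMethod("show", "TimeGrid", function(object) {
  cat(sprintf("TimeGrid: %d points over [%g, %g]\n",
              object@nPoints, object@start, object@stop))
})

setMethod("show", "GaussianFit", function(object) {
  cat(sprintf("GaussianFit: mu = %g, sigma2 = %g\n", object@mu, object@sigma2))
})

setMethod("show", "DensityEstimate", function(object) {
  cat(sprintf("DensityEstimate of '%s' at t = %g: %d bins over [%g, %g] (%s, n = %d)\n",
              object@varName, object@time, length(object@mass),
              object@binEdges[1L], object@binEdges[length(object@binEdges)],
              object@normed, object@nSamples))
  if (!is.null(object@fit))
    cat(sprintf("  Gaussian fit: mu = %g, sigma2 = %g\n",
                object@fit@mu, object@fit@sigma2))
})

setMethod("show", "MasterEqEstimate", function(object) {
  cat(sprintf("MasterEqEstimate of '%s': %d time points over [%g, %g] x %d state bins\n",
              object@varName, object@grid@nPoints, object@grid@start,
              object@grid@stop, ncol(object@prob)))
})

setMethod("show", "PhasePath", function(object) {
  cat(sprintf("PhasePath (%dD) of %s: %d points\n", length(object@varNames),
              paste(object@varNames, collapse = " vs "), nrow(object@points)))
})

setMethod("show", "ReactionModel", function(object) {
  cat(sprintf("ReactionModel '%s': %d species (%s), %d reactions, x0 = (%s)\n",
              object@label, length(object@species),
              paste(object@species, collapse = ", "), length(object@reactions),
              paste(object@x0, collapse = ", ")))
})
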