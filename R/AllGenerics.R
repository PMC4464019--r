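#' Sample a trajectory at an arbitrary time (zero-order hold)
#'
#' Returns the value of `var` at the largest recorded event time `<= t`.
#' Jump-process sample paths are right-continuous piecewise-constant
#' functions, so this is the exact semantics of reading the state between
#' events; linear interpolation would fabricate fractional states. For `t`
#' beyond the last event time the last value is held, with a warning: runs
#' stopped by event-count limits end at different times, and a hard failure
#' would make an ensemble with one short run unusable.
#'
#' @param x a [Trajectory-class].
#' @param t time point(s), each `>= x@times[1]`.
#' @param var a variable name.
#' @return numeric value(s) of `var` at `t`.
#' @examples
#' tr <- Trajectory(c(0, 2, 5), cbind(X = c(10, 7, 3)))
#' sampleAt(tr, 3, "X")  # 7
#' sampleAt(tr, 5, "X")  # 3 (post-event value applies at an event time)
#' @export
setGeneric("sampleAt", function(x, t, var) standardGeneric("sampleAt"))

#' Resample a trajectory on a uniform time grid
#'
#' Evaluates [sampleAt()] at every grid point for every variable, giving a
#' dense matrix comparable across runs whose event times differ.
#'
#' @param x a [Trajectory-class].
#' @param grid a [TimeGrid-class] with `start >= x@times[1]`.
#' @return numeric matrix, `nPoints` rows, one column per variable.
#' @export
setGeneric("resample", function(x, grid) standardGeneric("resample"))

#' @title Accessors for the ensemble-kinetics classes
#' @description Read-only access to the slots of [Trajectory-class],
#'   [Ensemble-class], [TimeGrid-class], [DensityEstimate-class],
#'   [MasterEqEstimate-class], [PhasePath-class] and [GaussianFit-class].
#' @param x an object of one of the classes above.
#' @return The requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("varNames", function(x) standardGeneric("varNames"))

#' @rdname accessors
#' @export
setGeneric("trajTimes", function(x) standardGeneric("trajTimes"))

#' @rdname accessors
#' @export
setGeneric("trajValues", function(x) standardGeneric("trajValues"))

#' @rdname accessors
#' @export
setGeneric("trajectories", function(x) standardGeneric("trajectories"))

#' @rdname accessors
#' @export
setGeneric("nRuns", function(x) standardGeneric("nRuns"))

#' @rdname accessors
#' @export
setGeneric("gridPoints", function(x) standardGeneric("gridPoints"))

#' @rdname accessors
#' @export
setGeneric("binEdges", function(x) standardGeneric("binEdges"))

#' @rdname accessors
#' @export
setGeneric("binMass", function(x) standardGeneric("binMass"))

#' @rdname accessors
#' @export
setGeneric("densityFit", function(x) standardGeneric("densityFit"))

#' @rdname accessors
#' @export
setGeneric("probMatrix", function(x) standardGeneric("probMatrix"))

#' @rdname accessors
#' @export
setGeneric("pathPoints", function(x) standardGeneric("pathPoints"))
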