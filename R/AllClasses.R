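#' @useDynLib EnsembleKinetics, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
NULL

.RESERVED_TIME_NAME <- "time"

## ---------------------------------------------------------------------------
## Trajectory
## ---------------------------------------------------------------------------

#' Trajectory: one realisation of a stochastic (or deterministic) model
#'
#' A `Trajectory` holds one simulation run: a strictly increasing vector of
#' event times and a matrix of variable values, one row per time point and one
#' column per model variable. Molecule counts are the typical case, but values
#' are stored as reals so deterministic or rescaled output loads identically.
#'
#' Jump-process sample paths are piecewise constant: row `k` is the state on
#' the half-open interval `[times[k], times[k+1])`. All sampling in this
#' package uses that zero-order-hold convention (see [sampleAt()]).
#'
#' @slot times numeric, strictly increasing, length >= 1.
#' @slot values numeric matrix, `length(times)` rows, one column per variable.
#' @slot varNames character, unique, non-empty; must not contain the reserved
#'   time-column name `"time"`.
#'
#' @seealso [sampleAt()], [resample()], [readTimeSeries()]
#' @export
setClass("Trajectory",
  representation(times = "numeric", values = "matrix", varNames = "character"))

setValidity("Trajectory", function(object) {
  msg <- character()
  tm <- object@times
  if (length(tm) < 1L) msg <- c(msg, "'times' must have length >= 1")
  if (anyNA(tm)) msg <- c(msg, "'times' contains NA")
  if (length(tm) > 1L && any(diff(tm) <= 0))
    msg <- c(msg, "'times' must be strictly increasing")
  if (!is.numeric(object@values)) msg <- c(msg, "'values' must be numeric")
  if (nrow(object@values) != length(tm))
    msg <- c(msg, "nrow(values) must equal length(times)")
  vn <- object@varNames
  if (ncol(object@values) != length(vn))
    msg <- c(msg, "ncol(values) must equal length(varNames)")
  if (anyDuplicated(vn)) msg <- c(msg, "duplicate variable names")
  if (any(!nzchar(vn))) msg <- c(msg, "empty variable name")
  if (.RESERVED_TIME_NAME %in% vn)
    msg <- c(msg, sprintf("variable names must not include the reserved name '%s'",
                          .RESERVED_TIME_NAME))
  if (length(msg)) msg else TRUE
})

#' Construct a Trajectory
#'
#' @param times numeric vector of time points, strictly increasing.
#' @param values numeric matrix or vector (one column per variable; a plain
#'   vector is treated as a single-variable run).
#' @param varNames character vector of variable names; defaults to the column
#'   names of `values` or `V1..Vk`.
#' @return A [Trajectory-class] object.
#' @examples
#' tr <- Trajectory(c(0, 2, 5), cbind(X = c(10, 7, 3)))
#' sampleAt(tr, 3, "X")  # 7: zero-order hold
#' @export
Trajectory <- function(times, values, varNames = NULL) {
  if (is.vector(values)) values <- matrix(values, ncol = 1L)
  storage.mode(values) <- "double"
  if (is.null(varNames)) {
    varNames <- colnames(values)
    if (is.null(varNames)) varNames <- paste0("V", seq_len(ncol(values)))
  }
  colnames(values) <- varNames
  new("Trajectory", times = as.numeric(times), values = values,
      varNames = as.character(varNames))
}

## ---------------------------------------------------------------------------
## Ensemble
## ---------------------------------------------------------------------------

#' Ensemble: an ordered collection of independent trajectories
#'
#' The "dataset" of this package: `n` independent realisations of the same
#' model, all sharing the same variable names in the same order. When loaded
#' from a folder, members are ordered by sorted source filename so loading is
#' deterministic across runs, worker counts and platforms.
#'
#' @slot trajectories list of [Trajectory-class] objects.
#' @slot provenance character; source-folder descriptor or `NA`.
#' @seealso [loadDataset()], [generateEnsemble()], [ensembleMean()]
#' @export
setClass("Ensemble",
  representation(trajectories = "list", provenance = "character"))

setValidity("Ensemble", function(object) {
  trs <- object@trajectories
  if (length(trs) < 1L) return("an Ensemble needs at least one trajectory")
  if (!all(vapply(trs, is, logical(1), "Trajectory")))
    return("all members must be Trajectory objects")
  ref <- trs[[1L]]@varNames
  same <- vapply(trs, function(tr) identical(tr@varNames, ref), logical(1))
  if (!all(same))
    return(sprintf("trajectories %s have variable names differing from the first",
                   paste(which(!same), collapse = ", ")))
  TRUE
})

#' Construct an Ensemble from a list of trajectories
#'
#' @param trajectories list of [Trajectory-class] objects with identical
#'   variable names.
#' @param provenance optional source descriptor (e.g. a folder path).
#' @return An [Ensemble-class] object.
#' @export
Ensemble <- function(trajectories, provenance = NA_character_) {
  new("Ensemble", trajectories = trajectories,
      provenance = as.character(provenance))
}

## ---------------------------------------------------------------------------
## TimeGrid
## ---------------------------------------------------------------------------

#' TimeGrid: a uniform discretisation of a time interval
#'
#' Statistics that compare asynchronous trajectories (whose stochastic event
#' times differ run to run) are evaluated on a shared uniform grid of
#' `nPoints` points from `start` to `stop` inclusive.
#'
#' @slot start,stop numeric; `start <= stop`.
#' @slot nPoints integer >= 1; if 1, `start` must equal `stop`.
#' @export
setClass("TimeGrid",
  representation(start = "numeric", stop = "numeric", nPoints = "integer"))

setValidity("TimeGrid", function(object) {
  if (length(object@start) != 1L || length(object@stop) != 1L ||
      length(object@nPoints) != 1L) return("scalar slots expected")
  if (is.na(object@nPoints) || object@nPoints < 1L) return("nPoints must be >= 1")
  if (object@start > object@stop) return("start must be <= stop")
  if (object@nPoints == 1L && object@start != object@stop)
    return("a single-point grid requires start == stop")
  TRUE
})

#' Construct a TimeGrid
#'
#' @param start,stop interval endpoints (inclusive), `start <= stop`.
#' @param nPoints number of uniformly spaced points (>= 1).
#' @return A [TimeGrid-class] object.
#' @examples
#' gridPoints(timeGrid(0, 4, 5))  # 0 1 2 3 4
#' @export
timeGrid <- function(start, stop, nPoints = 50L) {
  new("TimeGrid", start = as.numeric(start), stop = as.numeric(stop),
      nPoints = as.integer(nPoints))
}

## ---------------------------------------------------------------------------
## GaussianFit
## ---------------------------------------------------------------------------

#' GaussianFit: maximum-likelihood Gaussian parameters
#'
#' Closed-form MLE of a normal law: `mu` is the sample mean and `sigma2` the
#' biased (divide-by-n) variance. Attached to density estimates when a fit is
#' requested.
#'
#' @slot mu numeric mean.
#' @slot sigma2 numeric variance, >= 0.
#' @seealso [gaussianFit()]
#' @export
setClass("GaussianFit", representation(mu = "numeric", sigma2 = "numeric"))

setValidity("GaussianFit", function(object) {
  if (length(object@mu) != 1L || length(object@sigma2) != 1L)
    return("mu and sigma2 must be scalars")
  if (is.na(object@sigma2) || object@sigma2 < 0) return("sigma2 must be >= 0")
  TRUE
})

setClassUnion("GaussianFitOrNULL", c("GaussianFit", "NULL"))

## ---------------------------------------------------------------------------
## DensityEstimate
## ---------------------------------------------------------------------------

#' DensityEstimate: binned probability of one variable at one time
#'
#' A histogram of the across-run values of one variable at one time point:
#' the empirical estimate of P(X_t = x). `normed` records the scale of
#' `mass`: `"mass"` (per-bin probability, sums to 1), `"density"` (per-bin
#' density, integrates to 1) or `"count"` (raw counts).
#'
#' @slot varName variable name.
#' @slot time the time point.
#' @slot binEdges numeric vector of B+1 strictly increasing edges.
#' @slot mass numeric vector of B non-negative bin values.
#' @slot normed one of `"mass"`, `"density"`, `"count"`.
#' @slot nSamples number of samples binned.
#' @slot sampleMin,sampleMax observed extrema of the raw samples.
#' @slot fit optional [GaussianFit-class] of the raw samples.
#' @seealso [pdfAt()], [pdfMulti()]
#' @export
setClass("DensityEstimate",
  representation(varName = "character", time = "numeric",
                 binEdges = "numeric", mass = "numeric", normed = "character",
                 nSamples = "integer", sampleMin = "numeric",
                 sampleMax = "numeric", fit = "GaussianFitOrNULL"))

setValidity("DensityEstimate", function(object) {
  e <- object@binEdges; m <- object@mass
  if (length(e) < 2L || any(diff(e) <= 0))
    return("binEdges must be >= 2 strictly increasing values")
  if (length(m) != length(e) - 1L)
    return("mass must have length(binEdges) - 1 entries")
  if (any(m < 0)) return("negative bin mass")
  if (!object@normed %in% c("mass", "density", "count"))
    return("normed must be 'mass', 'density' or 'count'")
  if (object@normed == "mass" && abs(sum(m) - 1) > 1e-12)
    return("probability masses must sum to 1 (tolerance 1e-12)")
  if (object@normed == "density" && abs(sum(m * diff(e)) - 1) > 1e-12)
    return("density must integrate to 1 (tolerance 1e-12)")
  TRUE
})

## ---------------------------------------------------------------------------
## MasterEqEstimate
## ---------------------------------------------------------------------------

#' MasterEqEstimate: empirical master-equation solution P(x, t)
#'
#' A time-grid-by-state-bin matrix of probability masses: row i is the binned
#' distribution of one variable across runs at grid time i, all rows sharing
#' one set of state-bin edges. This is the ensemble estimate of the solution
#' of the chemical master equation for that variable.
#'
#' @slot varName variable name.
#' @slot grid the [TimeGrid-class] of evaluation times.
#' @slot binEdges shared state-bin edges (B+1 values).
#' @slot prob matrix (`nPoints` x B); every row sums to 1.
#' @seealso [masterEquation()]
#' @export
setClass("MasterEqEstimate",
  representation(varName = "character", grid = "TimeGrid",
                 binEdges = "numeric", prob = "matrix"))

setValidity("MasterEqEstimate", function(object) {
  p <- object@prob
  if (nrow(p) != object@grid@nPoints)
    return("prob must have one row per grid point")
  if (ncol(p) != length(object@binEdges) - 1L)
    return("prob must have one column per bin")
  if (any(p < 0) || any(p > 1)) return("probabilities must lie in [0, 1]")
  if (any(abs(rowSums(p) - 1) > 1e-12))
    return("every time slice must sum to 1 (tolerance 1e-12)")
  TRUE
})

## ---------------------------------------------------------------------------
## PhasePath
## ---------------------------------------------------------------------------

#' PhasePath: a trajectory in variable-vs-variable coordinates
#'
#' The projection of a run (or of an ensemble mean) onto 2 or 3 selected
#' variables, time implicit, used to reveal oscillations and attractors.
#'
#' @slot varNames 2 or 3 variable names, in axis order.
#' @slot points matrix with one row per time point and 2 or 3 columns.
#' @slot times matching time vector, increasing.
#' @seealso [phaseSpace()], [phaseSpaceAvg()]
#' @export
setClass("PhasePath",
  representation(varNames = "character", points = "matrix", times = "numeric"))

setValidity("PhasePath", function(object) {
  k <- length(object@varNames)
  if (!k %in% c(2L, 3L)) return("a phase path uses 2 or 3 variables")
  if (ncol(object@points) != k) return("points must have one column per variable")
  if (nrow(object@points) != length(object@times))
    return("points and times must have equal length")
  if (length(object@times) > 1L && any(diff(object@times) <= 0))
    return("times must be strictly increasing")
  TRUE
})

## ---------------------------------------------------------------------------
## BinningSpec
## ---------------------------------------------------------------------------

#' BinningSpec: how samples are aggregated into bins
#'
#' Controls histogram binning for [pdfAt()], [pdfMulti()] and
#' [masterEquation()]. The default `"auto"` rule: if every sample is (within
#' 1e-9) an integer, use bins of width 1 centred on integers over the sample
#' range — the natural choice for molecule counts; otherwise 30 equal-width
#' bins. If all samples are equal, a single bin of width 1 centred on the
#' value is used.
#'
#' Edge convention: a value exactly on an interior edge belongs to the bin on
#' its right; the last bin is closed on both sides.
#'
#' @slot nBins `"auto"` or an integer >= 1.
#' @slot integerAligned logical; `NA` means decide from the data.
#' @slot range numeric(2) `(lo, hi)` or `numeric(0)` to use the sample range.
#' @export
setClass("BinningSpec",
  representation(nBins = "ANY", integerAligned = "logical", range = "numeric"))

setValidity("BinningSpec", function(object) {
  nb <- object@nBins
  ok <- (is.character(nb) && identical(nb, "auto")) ||
    (is.numeric(nb) && length(nb) == 1L && !is.na(nb) && nb >= 1)
  if (!ok) return("nBins must be \"auto\" or an integer >= 1")
  if (length(object@integerAligned) != 1L) return("integerAligned must be a scalar flag")
  r <- object@range
  if (!length(r) %in% c(0L, 2L)) return("range must be numeric(0) or numeric(2)")
  if (length(r) == 2L && r[1] > r[2]) return("range lo must be <= hi")
  TRUE
})

#' Construct a BinningSpec
#'
#' @param nBins `"auto"` (default rule, see [BinningSpec-class]) or a bin count.
#' @param integerAligned force (`TRUE`) or forbid (`FALSE`) unit bins centred
#'   on integers; `NA` (default) decides from the data.
#' @param range optional `c(lo, hi)` binning range; defaults to the sample range.
#' @return A [BinningSpec-class] object.
#' @export
binningSpec <- function(nBins = "auto", integerAligned = NA, range = NULL) {
  if (is.numeric(nBins)) nBins <- as.integer(nBins)
  new("BinningSpec", nBins = nBins, integerAligned = as.logical(integerAligned),
      range = if (is.null(range)) numeric(0) else as.numeric(range))
}

## ---------------------------------------------------------------------------
## LoadSpec
## ---------------------------------------------------------------------------

#' LoadSpec: how to read delimited trajectory files
#'
#' Bundles the parsing options shared by [readTimeSeries()] and
#' [loadDataset()]. Delimiter auto-detection tries tab, comma, semicolon and
#' whitespace, in that order, on the first non-comment line; header
#' auto-detection treats a first line containing any non-numeric token as a
#' header. Explicit settings override detection, and `colNames` (first entry
#' naming the time column) overrides any header. Lines starting with `#` are
#' comments.
#'
#' @slot path file or directory path.
#' @slot pattern filename glob used when `path` is a directory.
#' @slot colNames optional column names, first = time (`character(0)` = unset).
#' @slot delimiter `"auto"`, or an explicit single-character delimiter
#'   (`" "` means any whitespace).
#' @slot hasHeader `"auto"`, `"yes"` or `"no"`.
#' @slot timeColumn 1-based index of the time column.
#' @slot nWorkers number of parallel loader processes.
#' @export
setClass("LoadSpec",
  representation(path = "character", pattern = "character",
                 colNames = "character", delimiter = "character",
                 hasHeader = "character", timeColumn = "integer",
                 nWorkers = "integer"))

setValidity("LoadSpec", function(object) {
  if (!object@hasHeader %in% c("auto", "yes", "no"))
    return("hasHeader must be 'auto', 'yes' or 'no'")
  if (object@nWorkers < 1L) return("nWorkers must be >= 1")
  if (object@timeColumn < 1L) return("timeColumn must be >= 1")
  TRUE
})

#' Construct a LoadSpec
#'
#' @param path file (for [readTimeSeries()]) or directory (for [loadDataset()]).
#' @param pattern filename glob, default `"*"`.
#' @param colNames optional character vector naming all columns, first = time.
#' @param delimiter `"auto"` (default) or an explicit delimiter character.
#' @param hasHeader `"auto"` (default), `TRUE` or `FALSE`.
#' @param timeColumn 1-based index of the time column (default 1).
#' @param nWorkers parallel worker count for folder loading (default 1).
#' @return A [LoadSpec-class] object.
#' @export
loadSpec <- function(path, pattern = "*", colNames = NULL, delimiter = "auto",
                     hasHeader = "auto", timeColumn = 1L, nWorkers = 1L) {
  hh <- if (is.logical(hasHeader)) (if (isTRUE(hasHeader)) "yes" else "no")
        else as.character(hasHeader)
  new("LoadSpec", path = as.character(path), pattern = as.character(pattern),
      colNames = if (is.null(colNames)) character(0) else as.character(colNames),
      delimiter = as.character(delimiter), hasHeader = hh,
      timeColumn = as.integer(timeColumn), nWorkers = as.integer(nWorkers))
}

## ---------------------------------------------------------------------------
## ReactionModel
## ---------------------------------------------------------------------------

#' ReactionModel: a stochastic mass-action reaction network
#'
#' Defines the model simulated by [ssaSimulate()]: species names, an initial
#' integer state, and a list of reactions. Each reaction is a list with a
#' `change` integer vector (state update, one entry per species) and either
#'
#' * `rate` (a stochastic rate constant) plus `reactants` (non-negative
#'   multiplicities per species), giving the combinatorial mass-action
#'   propensity `rate * prod(choose(x_i, r_i))`; or
#' * `propensity`, an arbitrary R function `state -> non-negative rate`
#'   (simulated by the R fallback path).
#'
#' @slot species character vector of species names.
#' @slot reactions list of reaction descriptions (see above).
#' @slot x0 integer initial state, one entry per species.
#' @slot label free-text model label.
#' @seealso [lotkaVolterra()], [immigrationDeath()], [pureDeath()]
#' @export
setClass("ReactionModel",
  representation(species = "character", reactions = "list", x0 = "integer",
                 label = "character"))

setValidity("ReactionModel", function(object) {
  ns <- length(object@species)
  if (ns < 1L) return("at least one species required")
  if (anyDuplicated(object@species)) return("duplicate species names")
  if (length(object@x0) != ns) return("x0 must have one entry per species")
  if (any(is.na(object@x0)) || any(object@x0 < 0L))
    return("x0 must be non-negative integers")
  for (k in seq_along(object@reactions)) {
    rx <- object@reactions[[k]]
    if (!is.list(rx) || is.null(rx$change) || length(rx$change) != ns)
      return(sprintf("reaction %d: 'change' must have one entry per species", k))
    hasMA <- !is.null(rx$rate) && !is.null(rx$reactants)
    hasFn <- is.function(rx$propensity)
    if (!hasMA && !hasFn)
      return(sprintf("reaction %d needs rate+reactants or a propensity function", k))
    if (hasMA) {
      if (rx$rate < 0) return(sprintf("reaction %d: negative rate constant", k))
      if (length(rx$reactants) != ns || any(rx$reactants < 0L))
        return(sprintf("reaction %d: invalid reactant multiplicities", k))
    }
  }
  TRUE
})

#' Construct a ReactionModel
#'
#' @param species character vector of species names.
#' @param reactions list of reactions; see [ReactionModel-class].
#' @param x0 initial integer state.
#' @param label optional model label.
#' @return A [ReactionModel-class] object.
#' @export
reactionModel <- function(species, reactions, x0, label = "") {
  reactions <- lapply(reactions, function(rx) {
    rx$change <- as.integer(rx$change)
    if (!is.null(rx$reactants)) rx$reactants <- as.integer(rx$reactants)
    rx
  })
  new("ReactionModel", species = as.character(species), reactions = reactions,
      x0 = as.integer(x0), label = as.character(label))
}

## ---------------------------------------------------------------------------
## PlotRequest
## ---------------------------------------------------------------------------

.PLOT_KINDS <- c("traces", "mean", "sd", "mean_sd", "pdf_bar", "pdf_3d",
                 "meq_heatmap", "meq_surface", "phase2d", "phase3d")

#' PlotRequest: a declarative description of one figure
#'
#' Names the plot kind, the variable subset, an optional time window, the
#' density flags where they apply, and the output image path. The file format
#' (png, svg or pdf) is inferred from the path extension unless given.
#'
#' @slot kind one of `r paste0('"', .PLOT_KINDS, '"', collapse = ", ")`.
#' @slot columns variable subset (`character(0)` = all).
#' @slot start,stop optional time window (`NA` = unbounded).
#' @slot normed,fit density flags (meaningful for `pdf_bar` / `pdf_3d` only).
#' @slot outPath output image file.
#' @slot format `"png"`, `"svg"` or `"pdf"`.
#' @seealso [plotRequest()], [renderPlot()]
#' @export
setClass("PlotRequest",
  representation(kind = "character", columns = "character", start = "numeric",
                 stop = "numeric", normed = "logical", fit = "logical",
                 outPath = "character", format = "character"))

setValidity("PlotRequest", function(object) {
  if (!object@kind %in% .PLOT_KINDS)
    return(sprintf("unknown plot kind '%s'", object@kind))
  if (!object@format %in% c("png", "svg", "pdf"))
    return("format must be png, svg or pdf")
  if (object@fit && !object@kind %in% c("pdf_bar", "pdf_3d"))
    return(sprintf("'fit' is not meaningful for kind '%s'", object@kind))
  if (!is.na(object@start) && !is.na(object@stop) && object@start > object@stop)
    return("start must be <= stop")
  TRUE
})

#' Construct a PlotRequest
#'
#' @param kind plot kind; see [PlotRequest-class].
#' @param outPath output image path (`.png`, `.svg` or `.pdf`).
#' @param columns optional variable subset.
#' @param start,stop optional time window applied before drawing.
#' @param normed,fit density options for `pdf_bar` / `pdf_3d`.
#' @param format image format; default inferred from `outPath`.
#' @return A [PlotRequest-class] object.
#' @export
plotRequest <- function(kind, outPath, columns = NULL, start = NA, stop = NA,
                        normed = TRUE, fit = FALSE, format = NULL) {
  if (is.null(format)) {
    format <- tolower(tools::file_ext(outPath))
    if (!nzchar(format)) format <- "png"
  }
  new("PlotRequest", kind = as.character(kind),
      columns = if (is.null(columns)) character(0) else as.character(columns),
      start = as.numeric(start), stop = as.numeric(stop),
      normed = as.logical(normed), fit = as.logical(fit),
      outPath = as.character(outPath), format = as.character(format))
}
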