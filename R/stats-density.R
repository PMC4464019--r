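## Histogram machinery. The edge convention is fixed and deliberate:
## values exactly on an interior edge fall in the bin to their right
## (half-open [lo, hi) bins), and the last bin is closed on both sides so the
## sample maximum is never lost. hist()'s right-closed default contradicts
## this, hence findInterval()/tabulate() rather than hist().

.INT_TOL <- 1e-9
.MAX_AUTO_UNIT_BINS <- 2048L

# Resolve bin edges for a sample vector under a BinningSpec.
# "auto" rule: near-integer samples get unit bins centred on integers (the
# natural quantisation for molecule counts); otherwise 30 equal-width bins.
# Unit bins are only auto-selected while the range needs at most
# .MAX_AUTO_UNIT_BINS of them — a run-away population (e.g. prey explosion
# after predator extinction) would otherwise quantise a 10^6-wide range into
# 10^6 bins; such ranges fall back to equal-width binning. An explicit
# integerAligned = TRUE is always honoured.
# Degenerate range (all samples equal and no usable range): one unit bin
# centred on the value.
.resolveEdges <- function(samples, spec = binningSpec()) {
  stopifnot(is(spec, "BinningSpec"))
  if (!length(samples)) stop("cannot bin an empty sample vector")
  rng <- if (length(spec@range)) spec@range else range(samples)
  lo <- rng[1L]; hi <- rng[2L]
  intAligned <- spec@integerAligned
  if (is.na(intAligned))
    intAligned <- all(abs(samples - round(samples)) < .INT_TOL) &&
      (round(hi) - round(lo) + 1) <= .MAX_AUTO_UNIT_BINS
  if (intAligned)
    return(seq(round(lo) - 0.5, round(hi) + 0.5, by = 1))
  if (hi - lo < .Machine$double.eps * max(1, abs(lo)))  # degenerate: one unit bin
    return(c(lo - 0.5, lo + 0.5))
  nb <- if (identical(spec@nBins, "auto")) 30L else as.integer(spec@nBins)
  if (nb < 1L) stop("parameter error: n_bins must be >= 1")
  seq(lo, hi, length.out = nb + 1L)
}

# Counts per bin under the package edge convention. Samples outside
# [edges[1], edges[B+1]] are dropped (only possible with an explicit range).
.binCounts <- function(samples, edges) {
  idx <- findInterval(samples, edges, rightmost.closed = TRUE)
  B <- length(edges) - 1L
  tabulate(idx[idx >= 1L & idx <= B], nbins = B)
}

# Assemble a DensityEstimate from raw samples on known edges.
.densityFromSamples <- function(samples, edges, varName, time,
                                normed = TRUE, asDensity = FALSE, fit = FALSE) {
  counts <- .binCounts(samples, edges)
  n <- sum(counts)
  mass <- if (!normed) as.numeric(counts)
          else if (asDensity) counts / n / diff(edges)
          else counts / n
  new("DensityEstimate", varName = varName, time = as.numeric(time),
      binEdges = edges, mass = mass,
      normed = if (!normed) "count" else if (asDensity) "density" else "mass",
      nSamples = length(samples),
      sampleMin = min(samples), sampleMax = max(samples),
      fit = if (fit) gaussianFit(samples) else NULL)
}

#' Closed-form Gaussian maximum-likelihood fit
#'
#' Returns the exact MLE of a normal law: `mu` the sample mean and `sigma2`
#' the biased variance `sum((x - mu)^2) / n`. No iterative optimisation is
#' involved, so the result is exact on rational inputs.
#'
#' @param samples numeric vector, length >= 1.
#' @return A [GaussianFit-class].
#' @examples
#' gaussianFit(c(2, 4))  # mu = 3, sigma2 = 1
#' @export
gaussianFit <- function(samples) {
  if (!length(samples)) stop("cannot fit a Gaussian to an empty sample")
  mu <- mean(samples)
  new("GaussianFit", mu = mu, sigma2 = mean((samples - mu)^2))
}

#' Across-run probability density of one variable at one time
#'
#' Samples every run of the ensemble at time `t` (zero-order hold) and bins
#' the values: the empirical estimate of P(X_t = x). With `normed = TRUE`
#' (default) bin masses sum to 1; `normed = FALSE` returns raw counts;
#' `asDensity = TRUE` rescales masses by bin width so the histogram
#' integrates to 1. With `fit = TRUE` a closed-form Gaussian MLE of the raw
#' samples is attached — reported alongside the histogram, never replacing
#' it. The observed sample minimum and maximum are always recorded.
#'
#' @param ens an [Ensemble-class].
#' @param t the time point.
#' @param var variable name.
#' @param bins a [BinningSpec-class] (default: the `"auto"` rule).
#' @param normed return probability mass (`TRUE`) or raw counts (`FALSE`).
#' @param fit attach a [GaussianFit-class] of the raw samples.
#' @param asDensity with `normed = TRUE`, normalise as a density
#'   (integrates to 1) instead of as per-bin mass (sums to 1).
#' @return A [DensityEstimate-class].
#' @seealso [pdfMulti()] for several comparable time points,
#'   [masterEquation()] for a whole time interval.
#' @export
pdfAt <- function(ens, t, var, bins = binningSpec(), normed = TRUE,
                  fit = FALSE, asDensity = FALSE) {
  stopifnot(is(ens, "Ensemble"))
  samples <- .ensembleSamplesAt(ens, t, var)
  edges <- .resolveEdges(samples, bins)
  .densityFromSamples(samples, edges, var, t,
                      normed = normed, asDensity = asDensity, fit = fit)
}

#' Comparable densities at several time points
#'
#' Applies [pdfAt()] at each requested time with a single set of bin edges,
#' resolved over the union of the samples from all times, so bars are
#' directly comparable across times (the 3D/pdf-at-multiple-times view).
#'
#' @inheritParams pdfAt
#' @param times numeric vector of time points.
#' @return A list of [DensityEstimate-class], one per time, all sharing
#'   identical `binEdges`.
#' @export
pdfMulti <- function(ens, times, var, bins = binningSpec(), normed = TRUE,
                     fit = FALSE, asDensity = FALSE) {
  stopifnot(is(ens, "Ensemble"), length(times) >= 1L)
  sampleSets <- lapply(times, function(t) .ensembleSamplesAt(ens, t, var))
  edges <- .resolveEdges(unlist(sampleSets), bins)
  lapply(seq_along(times), function(i)
    .densityFromSamples(sampleSets[[i]], edges, var, times[i],
                        normed = normed, asDensity = asDensity, fit = fit))
}

# All runs sampled at one time, hold-last warnings collapsed to one.
.ensembleSamplesAt <- function(ens, t, var) {
  .checkVar(ens@trajectories[[1L]], var)
  j <- match(var, varNames(ens))
  short <- FALSE
  out <- vapply(ens@trajectories, function(tr) {
    withCallingHandlers(
      tr@values[.holdIndex(tr@times, t), j],
      warning = function(w) { short <<- TRUE; invokeRestart("muffleWarning") })
  }, numeric(1))
  if (short)
    warning(sprintf("time %g is beyond the final recorded time of some runs: holding last values", t))
  out
}
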