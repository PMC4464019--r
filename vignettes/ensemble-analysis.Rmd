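---
title: "Estimating ensemble statistics and master equations from stochastic kinetic time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating ensemble statistics and master equations from stochastic kinetic time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Stochastic models of biochemical networks — Gillespie-type Markov jump
processes, stochastic differential equations, hybrid schemes — are analysed
through *simulation ensembles*: `n` independent realisations of the same
model, each stored as one time-series file. The quantities a modeller needs
are statistical functionals of that ensemble:

* the across-run mean trace $\bar X_t$ and standard deviation $\sigma_X(t)$
  of every variable;
* the distribution of a variable at a fixed time,
  $P(X_t = x)$, estimated by binning the across-run values at $t$;
* the same distribution swept over a time interval, which is the empirical
  estimate of the solution $P(x, t)$ of the chemical master equation
  $\partial_t P(x,t)$ — in general computable only from simulation
  ensembles;
* phase-space projections (variable vs. variable) that expose oscillations
  and attractors.

EnsembleKinetics computes these from folders of delimited run files (or
SBRML time courses), renders every statistic to an image, and ships a
Gillespie simulator so that validated fixture ensembles — including models
with exactly known transient laws — can be produced on demand.

## The sampling convention: zero-order hold

Different runs of a jump process realise events at different times, so no
two files share a time column. Every statistic therefore evaluates runs on
a shared uniform `TimeGrid` through a fixed sampling rule: the value of a
trajectory at time $t$ is its value at the largest recorded event time
$\le t$ (zero-order hold). This is not an approximation: a jump-process
sample path *is* a right-continuous piecewise-constant function, so the
hold reproduces the state between events exactly. Linear interpolation
would fabricate fractional molecule counts and is deliberately not offered.
At a recorded event time the post-event value applies.

Two boundary rules complete the convention:

* a query before a run's first recorded time is an error (nothing is
  known there);
* a query after a run's last recorded time returns the last value, with a
  warning. Runs stopped by an event-count cap end at different times; a
  hard failure would make an ensemble with one short run unusable, while
  holding the last value is exact for runs that ended in an absorbing
  state.

Runs stopped by the simulation horizon `tMax` get a closing row repeating
the final state at exactly `tMax`, so their recorded domain covers the full
simulated interval and interval-end queries are warning-free. Absorbing
stops (total propensity zero) and event-capped stops do not get a closing
row: for an absorbing stop the hold rule is already exact, and an
event-capped run genuinely ends early.

Because the hold is deterministic, resampling a resampled trajectory on the
same grid is the identity, and refining a master-equation time grid never
changes the slices that coincide with coarser grid points. Both properties
are tested.

## Binning

Histograms use half-open bins $[lo, hi)$ with two deliberate conventions: a
value exactly on an interior edge belongs to the bin on its right, and the
last bin is closed on both sides so the sample maximum is never dropped.
`hist()`'s right-closed default contradicts this, which is why binning is
implemented directly on `findInterval()`.

The `"auto"` rule of `binningSpec()`:

* if every sample is within $10^{-9}$ of an integer — the molecule-count
  case — bins have width 1 and are centred on integers over the sample
  range, so each bin is one state and the histogram *is* the empirical
  probability mass function;
* otherwise 30 equal-width bins over the range (a conventional default for
  continuous output);
* if all samples are equal, a single bin of width 1 centred on the value
  carries mass 1.

`normed` controls the scale: per-bin probability mass (sums to 1, the
default), raw counts, or — via `asDensity` — a density that integrates
to 1. Mass is the default because for count data on unit bins it equals
$P(X_t = x)$ directly; both normalisations are exposed since either reading
of a "normalised" histogram is defensible.

## Gaussian fits and the SD convention

`gaussianFit()` is the closed-form maximum-likelihood estimate: $\hat\mu$
the sample mean, $\hat\sigma^2 = \frac1n \sum (x_i - \hat\mu)^2$ the biased
variance. No iterative optimisation is involved, so results are exact on
rational inputs — a property the tests assert literally. For consistency,
`ensembleSD()` defaults to the same population ($n$) denominator; an
`unbiased = TRUE` switch gives the $n-1$ convention. Fits are reported
*alongside* histograms, never in place of them.

## The master-equation estimate

`masterEquation(ens, var, start, stop)` builds a uniform grid (default 50
points — fine enough to resolve the oscillations of the demonstration
model, coarse enough that a 100-run ensemble still gives ~2 runs per
time-state cell), resolves **one** shared set of state-bin edges from the
global extrema of the variable over all runs and grid points, and bins the
across-run values at every grid time on those shared edges. Shared edges
make rows comparable, so the matrix can be drawn as a heatmap or surface of
$P(x, t)$; every row sums to 1 to within $10^{-12}$ by construction and by
validity check. The module estimates from ensembles only; it never
integrates the master equation numerically.

## The built-in simulator and what the fixtures emulate

`ssaSimulate()` implements the Gillespie direct method: waiting times
$\sim \mathrm{Exponential}(a_0)$, reaction $j$ chosen with probability
$a_j / a_0$, state recorded after every event (no thinning), with an event
cap (default $10^6$) guarding against population explosion. Mass-action
models run in compiled code with the combinatorial propensity
$a_j = c_j \prod_i \binom{x_i}{r_{ij}}$; models defined by arbitrary R
propensity closures run in an R loop with identical draw semantics — the
two paths produce bit-identical trajectories under the same seed, which is
tested. Per-run seeds derive from the master seed by a fixed affine map of
the run index, so ensembles are reproducible regardless of generation
order.

Three models are built in:

* `lotkaVolterra(k1 = 1, k2 = 0.004, k3 = 1, prey0 = 250, pred0 = 250)` —
  prey birth, predation, predator death. The defaults are this package's
  own choice: they place the coexistence fixed point at
  $(k_3/k_2,\, k_1/k_2) = (250, 250)$, start the system there, and give a
  deterministic oscillation period $2\pi/\sqrt{k_1 k_3} \approx 6.3$ time
  units; at this population scale both species persist beyond $t = 100$ in
  most stochastic runs. Period and survival are parameter-dependent
  properties of a *parameterisation*, not of the model family, and are not
  treated as validation targets.
* `immigrationDeath(k, mu)` — exact transient law
  $X(t) \sim \mathrm{Poisson}\!\big(\tfrac{k}{\mu}(1 - e^{-\mu t})\big)$
  from an empty start, stationary mean $k/\mu$.
* `pureDeath(mu, n0)` — exact transient law
  $X(t) \sim \mathrm{Binomial}(n_0, e^{-\mu t})$.

The last two exist *because* their closed forms are independent oracles:
the validation suite generates 2000-run ensembles and requires the
estimated densities to sit within total-variation distance 0.05 of the
exact laws (at that ensemble size the expected distance is about 0.036 for
the stationary immigration-death law, so the bound tests recovery, not
luck). What passing these tests shows is that the estimator machinery —
sampling, binning, normalisation — is faithful on data whose truth is
known. What it does **not** show is anything about real experimental data:
the fixtures are Markovian, have exact integer states, carry no
measurement noise, no missingness and no correlated errors, and their
files are written by the package's own writer. Tests on them validate the
arithmetic, not the modelling.

## I/O

Run files are delimited text, one run per file, first column time.
Delimiter detection tries tab, comma, semicolon, then whitespace on the
first non-comment line; a first line with any non-numeric token is a
header; `#` lines are comments; explicit settings and `colNames` override
detection. Written files print each value with 17 significant digits, which
reproduces the IEEE double exactly, so write/read round-trips are lossless.
Large well-formed files are tokenised by `data.table::fread` after the
package's own dialect detection; files with comments or unusual layouts go
through a line-based parser that owns the error reporting — the fast path
can only fall back, never change a result. Folder loading can fork over workers
(`parallel::mclapply`), and the merge is by sorted filename, so results
are bit-identical for every worker count — the tested contract is the
determinism, not the mechanism.

SBRML support covers the time-course layout (per result component, an
outer composite dimension indexed by time and an inner one indexed by
variable name). The subset is deliberately minimal and everything else is
rejected with an error naming the offending element, rather than
half-parsed. Write followed by read reproduces an ensemble exactly.

`cacheGetOrCompute()` memoises expensive statistics under keys hashed from
the *content* of inputs plus all parameters (128-bit xxHash of the
serialized objects), never from paths or timestamps, so an edited value or
changed bin count always forces recomputation. A corrupt entry is
discarded with a warning and recomputed — the cache can cost time, never
correctness. The store is size-capped with least-recently-used eviction.

## Rendering and reports

Trajectories are drawn as step (post) functions, matching the hold
semantics; only mean traces are smooth lines. Heatmaps use the viridis
map with the colour scale anchored at $[0, \max \text{mass}]$ per plot.
Traces longer than 2000 points are resampled (zero-order hold) onto a
2000-point grid before drawing: the drawn values are exact sample-path
values, only the drawing resolution is capped. SVG output is
byte-reproducible for identical requests, giving a regression surface for
figures.

`runReport()` executes a declarative YAML config — dataset location (or a
fixture-generation block with a seed), an ordered list of analysis steps,
an output directory — validating every step before running any. It writes
`images/`, `tables/` (densities and master-equation matrices as delimited
text), a `run.log` recording every parameter actually used including
resolved defaults, dataset size, per-variable extrema and Gaussian-fit
$\mu/\sigma^2$ where requested, and a `MANIFEST` whose first line states
completeness. A config is declarative rather than an executable script on
purpose: batch report generation should not execute arbitrary code, and R
users already have the full API.

## Problem sizes used by the validation suite

Unit tests run on ensembles of 2–30 short runs. The statistical
acceptance checks use the 2000-run oracle ensembles described above
(immigration-death over $[0,5]$, pure death to $t=2$) and one end-to-end
workflow on a generated 100-run Lotka-Volterra dataset simulated to
$t = 100$ (roughly $7.5\times10^6$ events in total), which exercises
folder writing, parallel-safe loading, all three demonstration analyses
and the exported tables.

## Known limitations

* Interpolation is zero-order hold only; models whose output is genuinely
  continuous between samples (e.g. SDE solvers with coarse output) are
  resampled as staircases.
* The SBRML subset is the time-course layout only; no SED-ML, Teddy or
  SBML import.
* No kernel density estimation, no multivariate joint densities, no
  moment closure or numerical master-equation integration.
* No spatial models: variables are scalar abundances.
* The simulator is exact SSA only — no tau-leaping, delays or hybrid
  schemes — and mass-action propensities use the combinatorial
  convention; rate constants fitted under the $x^r$ convention must be
  converted.
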