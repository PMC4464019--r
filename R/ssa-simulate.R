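## Gillespie direct method. Mass-action models run in the compiled core;
## models with arbitrary R propensity closures use an R loop with identical
## semantics (waiting time ~ Exponential(a0), reaction j with probability
## a_j/a0, state recorded after every event). Both paths draw from R's RNG,
## so set.seed() governs either.

#' Simulate one trajectory with the Gillespie direct method
#'
#' Exact stochastic simulation of a [ReactionModel-class]: at each step the
#' waiting time is drawn from `Exponential(a0)` (`a0` = total propensity) and
#' the reaction is chosen with probability `a_j / a0`. The trajectory records
#' the initial state at `t = 0` and the state after every event, stopping at
#' `tMax`, after `maxEvents` events, or when `a0` reaches zero (absorbing
#' state). A run stopped by `tMax` gets a closing row repeating the final
#' state at exactly `tMax`, so its recorded domain covers the whole simulated
#' interval; absorbing or event-capped stops do not. Runs are reproducible:
#' the same `seed` yields a bit-identical trajectory.
#'
#' @param model a [ReactionModel-class].
#' @param tMax stop time (> 0).
#' @param seed optional integer seed (`set.seed()` is called when given).
#' @param maxEvents cap on the number of events (default `1e6`), a guard
#'   against population explosion.
#' @return A [Trajectory-class] with the model's species as variables.
#' @examples
#' tr <- ssaSimulate(pureDeath(mu = 1, n0 = 5), tMax = 100, seed = 1)
#' trajValues(tr)[nrow(trajValues(tr)), ]  # 0: all particles die
#' @export
ssaSimulate <- function(model, tMax, seed = NULL, maxEvents = 1e6L) {
  stopifnot(is(model, "ReactionModel"))
  if (!(tMax > 0)) stop("parameter error: tMax must be > 0")
  if (!is.null(seed)) set.seed(seed)
  massAction <- all(vapply(model@reactions,
                           function(rx) !is.null(rx$rate) && !is.null(rx$reactants),
                           logical(1)))
  res <- if (massAction) {
    nu <- do.call(rbind, lapply(model@reactions, `[[`, "change"))
    re <- do.call(rbind, lapply(model@reactions, `[[`, "reactants"))
    rates <- vapply(model@reactions, `[[`, numeric(1), "rate")
    ssa_direct_cpp(model@x0, nu, re, rates, tMax, as.integer(maxEvents))
  } else {
    .ssaDirectR(model, tMax, as.integer(maxEvents))
  }
  Trajectory(res$times, res$values, varNames = model@species)
}

# Reference R implementation for models with propensity closures; also the
# cross-check for the compiled path.
.ssaDirectR <- function(model, tMax, maxEvents) {
  x <- as.numeric(model@x0)
  ns <- length(x)
  nu <- do.call(rbind, lapply(model@reactions, `[[`, "change"))
  prop <- lapply(model@reactions, function(rx) {
    if (is.function(rx$propensity)) rx$propensity
    else local({
      rate <- rx$rate; r <- rx$reactants
      function(state) rate * prod(choose(state, r))
    })
  })
  cap <- 1024L
  times <- numeric(cap); states <- matrix(0, cap, ns)
  times[1L] <- 0; states[1L, ] <- x
  nrows <- 1L; t <- 0; nEvents <- 0L; hitTmax <- FALSE
  while (nEvents < maxEvents) {
    a <- vapply(prop, function(f) f(x), numeric(1))
    if (any(a < 0)) stop("negative propensity encountered")
    a0 <- sum(a)
    if (a0 <= 0) break
    t <- t + stats::rexp(1L, rate = a0)
    if (t > tMax) { hitTmax <- TRUE; break }
    # inversion on the cumulative propensities, mirroring the compiled path
    j <- findInterval(stats::runif(1L) * a0, cumsum(a), left.open = TRUE) + 1L
    if (j > length(a)) j <- length(a)
    x <- x + nu[j, ]
    if (nrows == cap) {
      cap <- cap * 2L
      length(times) <- cap
      states <- rbind(states, matrix(0, cap - nrow(states), ns))
    }
    nrows <- nrows + 1L
    times[nrows] <- t; states[nrows, ] <- x
    nEvents <- nEvents + 1L
  }
  times <- times[seq_len(nrows)]
  states <- states[seq_len(nrows), , drop = FALSE]
  if (hitTmax && times[nrows] < tMax) {  # closing row at the stop time
    times <- c(times, tMax)
    states <- rbind(states, states[nrows, ])
  }
  list(times = times, values = states, n_events = nEvents)
}

#' Generate an ensemble of independent runs
#'
#' Simulates `nRuns` independent trajectories of `model`. Per-run seeds are
#' derived from the master `seed` by a counter-based rule (a fixed affine map
#' of the run index modulo 2^31 - 1), so run `i` is reproducible on its own
#' and ensembles are identical regardless of the order or parallelism of
#' generation. With `outDir`, each run is also written as a delimited text
#' file (`run_0001.txt`, ...) in the native dialect of [writeTrajectory()],
#' producing an on-disk dataset that [loadDataset()] reads back equal to the
#' in-memory ensemble.
#'
#' @param model a [ReactionModel-class].
#' @param nRuns number of independent runs (>= 1).
#' @param tMax stop time for every run.
#' @param seed master integer seed.
#' @param outDir optional folder to write one file per run into (created if
#'   missing).
#' @param maxEvents per-run event cap (see [ssaSimulate()]).
#' @return An [Ensemble-class] of `nRuns` trajectories.
#' @export
generateEnsemble <- function(model, nRuns, tMax, seed, outDir = NULL,
                             maxEvents = 1e6L) {
  if (nRuns < 1L) stop("parameter error: nRuns must be >= 1")
  seeds <- .deriveSeeds(seed, nRuns)
  trs <- lapply(seq_len(nRuns), function(i)
    ssaSimulate(model, tMax, seed = seeds[i], maxEvents = maxEvents))
  ens <- Ensemble(trs, provenance = if (is.null(outDir)) NA_character_ else outDir)
  if (!is.null(outDir)) {
    ok <- dir.exists(outDir) || dir.create(outDir, recursive = TRUE)
    if (!ok || file.access(outDir, mode = 2L) != 0L)
      stop(sprintf("cannot write to output directory %s", outDir))
    for (i in seq_len(nRuns))
      writeTrajectory(trs[[i]], file.path(outDir, sprintf("run_%04d.txt", i)))
  }
  ens
}

# Counter-based per-run seed derivation: distinct, deterministic, < 2^31.
.deriveSeeds <- function(seed, n) {
  as.integer((as.numeric(seed) + 1664525 * seq_len(n)) %% 2147483647) + 1L
}
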