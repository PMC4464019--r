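# Shared fixtures, all generated in code.

makeTraj <- function(times = c(0, 2, 5), vals = cbind(X = c(10, 7, 3))) {
  Trajectory(times, vals)
}

# small two-variable trajectory with asynchronous jumps
makeTraj2 <- function() {
  Trajectory(c(0, 1, 3, 4.5),
             cbind(A = c(5, 6, 6, 2), B = c(1, 1, 0, 3)))
}

# an ensemble of short immigration-death runs (compiled SSA, seeded)
randomEnsemble <- function(nRuns = 6, seed = 1, k = 5, mu = 1, tMax = 3) {
  generateEnsemble(immigrationDeath(k, mu), nRuns, tMax, seed)
}

# brute-force double-loop oracles, independent of the resample machinery
bruteMean <- function(ens, grid, var) {
  vapply(gridPoints(grid), function(t)
    mean(vapply(trajectories(ens),
                function(tr) suppressWarnings(sampleAt(tr, t, var)),
                numeric(1))), numeric(1))
}

bruteSD <- function(ens, grid, var) {
  vapply(gridPoints(grid), function(t) {
    xs <- vapply(trajectories(ens),
                 function(tr) suppressWarnings(sampleAt(tr, t, var)), numeric(1))
    sqrt(sum((xs - mean(xs))^2) / length(xs))
  }, numeric(1))
}

# analytic pmf binned onto unit integer-centred bins given by edges;
# probability outside the edges is reported separately as tail mass
binnedPmf <- function(edges, pmfFn) {
  mids <- (edges[-1L] + edges[-length(edges)]) / 2
  pmfFn(round(mids))
}

# TV between an empirical mass vector on integer-centred unit bins and an
# analytic pmf, counting the analytic tail mass outside the binned support
tvAgainstPmf <- function(d, pmfFn) {
  p <- binnedPmf(binEdges(d), pmfFn)
  0.5 * sum(abs(binMass(d) - p)) + 0.5 * (1 - sum(p))
}

writeTempDataset <- function(ens, dir = tempfile("ds")) {
  dir.create(dir)
  for (i in seq_len(length(ens)))
    writeTrajectory(ens[[i]], file.path(dir, sprintf("run_%04d.txt", i)))
  dir
}
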