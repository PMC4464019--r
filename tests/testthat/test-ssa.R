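test_that("absorbing starts, single-event chains and seed determinism behave", {
  # all-zero propensities: only the initial row
  m0 <- reactionModel("X", list(list(change = 1L, rate = 0, reactants = 0L)), 5L)
  tr0 <- ssaSimulate(m0, tMax = 10, seed = 1)
  expect_identical(length(trajTimes(tr0)), 1L)
  expect_identical(unname(trajValues(tr0)[1L, ]), 5)
  # pure death from one particle: exactly one event, final state 0
  trd <- ssaSimulate(pureDeath(mu = 2, n0 = 1L), tMax = 1e6, seed = 7)
  expect_identical(length(trajTimes(trd)), 2L)
  expect_identical(unname(trajValues(trd)[2L, ]), 0)
  # same seed, same trajectory, bit for bit
  a <- ssaSimulate(lotkaVolterra(), 2, seed = 123)
  b <- ssaSimulate(lotkaVolterra(), 2, seed = 123)
  expect_identical(trajTimes(a), trajTimes(b))
  expect_identical(trajValues(a), trajValues(b))
})

test_that("compiled and R propensity-closure paths are bit-identical", {
  mMA <- immigrationDeath(7, 0.5)
  mFN <- reactionModel("X", list(
    list(change = 1L, propensity = function(x) 7),
    list(change = -1L, propensity = function(x) 0.5 * x[1L])), 0L)
  a <- ssaSimulate(mMA, 10, seed = 11)
  b <- ssaSimulate(mFN, 10, seed = 11)
  expect_identical(trajTimes(a), trajTimes(b))
  expect_identical(trajValues(a), trajValues(b))
})

test_that("species counts never go negative along trajectories", {
  for (seed in 1:5) {
    tr <- ssaSimulate(lotkaVolterra(prey0 = 20L, pred0 = 20L, k2 = 0.05),
                      tMax = 10, seed = seed)
    expect_true(all(trajValues(tr) >= 0))
  }
})

test_that("waiting times of a constant-propensity model are exponential", {
  # immigration only: a Poisson process with rate k, so inter-event gaps are
  # iid Exponential(k)
  k <- 4
  m <- reactionModel("X", list(list(change = 1L, rate = k, reactants = 0L)), 0L)
  tr <- ssaSimulate(m, tMax = 5000 / k + 1000, seed = 31, maxEvents = 5001L)
  gaps <- diff(trajTimes(tr))[1:5000]
  ks <- suppressWarnings(stats::ks.test(gaps, "pexp", rate = k))
  expect_lt(unname(ks$statistic), 1.628 / sqrt(5000))  # 1% critical value
})

test_that("Lotka-Volterra reactions have the stated structure and edge cases", {
  lv <- lotkaVolterra(prey0 = 0L, pred0 = 10L)
  tr <- ssaSimulate(lv, 3, seed = 2)
  expect_true(all(trajValues(tr)[, "Preys"] == 0))      # no spontaneous prey
  lv2 <- lotkaVolterra(prey0 = 10L, pred0 = 0L, k1 = 2)
  tr2 <- ssaSimulate(lv2, 2, seed = 3, maxEvents = 2000L)
  prey <- trajValues(tr2)[, "Preys"]
  expect_true(all(diff(prey) >= 0))                     # prey grows monotonically
  expect_true(all(trajValues(tr2)[, "Predators"] == 0))
  expect_error(lotkaVolterra(k1 = -1), "parameter error")
})

test_that("immigration-death and pure-death match their closed-form means", {
  # immigration-death stationary mean k/mu within 3 standard errors
  k <- 10; mu <- 1; n <- 400
  ens <- generateEnsemble(immigrationDeath(k, mu), n, tMax = 8, seed = 91)
  x <- vapply(trajectories(ens), function(tr) sampleAt(tr, 8, "X"), numeric(1))
  se <- stats::sd(x) / sqrt(n)
  expect_lt(abs(mean(x) - k / mu), 3 * se)
  # pure death at the half-life: mean n0/2 within 3 SE
  mu2 <- 0.3; n0 <- 20L; tHalf <- log(2) / mu2
  ens2 <- generateEnsemble(pureDeath(mu2, n0), n, tMax = tHalf + 0.5, seed = 92)
  y <- vapply(trajectories(ens2), function(tr)
    suppressWarnings(sampleAt(tr, tHalf, "X")), numeric(1))
  se2 <- stats::sd(y) / sqrt(n)
  expect_lt(abs(mean(y) - n0 / 2), 3 * se2)
})

test_that("generateEnsemble is reproducible and round-trips through disk", {
  m <- immigrationDeath(5, 1)
  e1 <- generateEnsemble(m, 6, tMax = 3, seed = 77)
  e2 <- generateEnsemble(m, 6, tMax = 3, seed = 77)
  expect_identical(lapply(trajectories(e1), trajValues),
                   lapply(trajectories(e2), trajValues))
  # written folder re-loads equal to the in-memory ensemble
  dir <- tempfile("runs")
  e3 <- generateEnsemble(m, 6, tMax = 3, seed = 77, outDir = dir)
  loaded <- loadDataset(dir)
  expect_identical(lapply(trajectories(loaded), trajTimes),
                   lapply(trajectories(e3), trajTimes))
  expect_identical(lapply(trajectories(loaded), trajValues),
                   lapply(trajectories(e3), trajValues))
  # identical master seed, identical folder contents
  dir2 <- tempfile("runs")
  generateEnsemble(m, 6, tMax = 3, seed = 77, outDir = dir2)
  f1 <- list.files(dir, full.names = TRUE)
  f2 <- list.files(dir2, full.names = TRUE)
  expect_identical(basename(f1), basename(f2))
  expect_identical(lapply(f1, readLines), lapply(f2, readLines))
})

test_that("event caps truncate runs without a closing row", {
  m <- immigrationDeath(100, 0)  # unbounded growth
  tr <- ssaSimulate(m, tMax = 1e6, seed = 5, maxEvents = 50L)
  expect_identical(length(trajTimes(tr)), 51L)  # initial row + 50 events
  expect_lt(max(trajTimes(tr)), 1e6)
})

test_that("declarative model configs build the equivalent mass-action model", {
  cfg <- tempfile(fileext = ".yaml")
  writeLines(c("label: imdeath", "species: [X]", "x0: [0]", "reactions:",
               "  - rate: 7", "    products: {X: 1}",
               "  - rate: 0.5", "    reactants: {X: 1}"), cfg)
  m <- readModelConfig(cfg)
  ref <- immigrationDeath(7, 0.5)
  a <- ssaSimulate(m, 5, seed = 13)
  b <- ssaSimulate(ref, 5, seed = 13)
  expect_identical(trajTimes(a), trajTimes(b))
  expect_identical(trajValues(a), trajValues(b))
  writeLines(c("species: [X]", "x0: [0]", "reactions:",
               "  - rate: 1", "    products: {Y: 1}"), cfg)
  expect_error(readModelConfig(cfg), "unknown species")
})
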