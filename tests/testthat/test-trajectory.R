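test_that("sampleAt follows the zero-order-hold convention", {
  tr <- makeTraj()  # times 0,2,5; X = 10,7,3
  expect_identical(sampleAt(tr, 3, "X"), 7)    # hold between events
  expect_identical(sampleAt(tr, 5, "X"), 3)    # post-event value at event time
  expect_identical(sampleAt(tr, 0, "X"), 10)   # initial condition
  expect_warning(v <- sampleAt(tr, 9, "X"), "final recorded time")
  expect_identical(v, 3)                       # hold-last beyond the end
})

test_that("sampleAt rejects out-of-range times and unknown variables", {
  tr <- makeTraj()
  expect_error(sampleAt(tr, -1, "X"), "earlier than the first")
  expect_error(sampleAt(tr, 3, "Y"), "unknown variable")
})

test_that("sampleAt equals values[k] on [times[k], times[k+1]) exhaustively", {
  tr <- makeTraj2()
  tms <- trajTimes(tr)
  for (k in seq_along(tms)) {
    probes <- if (k < length(tms)) {
      seq(tms[k], tms[k + 1L] - 1e-9, length.out = 5L)
    } else tms[k]
    for (v in varNames(tr)) {
      expect_equal(sampleAt(tr, probes, v),
                   rep(unname(trajValues(tr)[k, v]), length(probes)))
    }
  }
})

test_that("resample matches a naive per-point sampleAt loop", {
  tr <- ssaSimulate(immigrationDeath(4, 0.7), tMax = 6, seed = 99)
  grid <- timeGrid(0, 6, 25)
  m <- resample(tr, grid)
  naive <- vapply(gridPoints(grid), function(t) sampleAt(tr, t, "X"), numeric(1))
  expect_identical(unname(m[, 1L]), naive)
})

test_that("resample handles constant and small explicit trajectories", {
  const <- Trajectory(c(0, 1), cbind(X = c(4, 4)))
  expect_true(all(resample(const, timeGrid(0, 1, 7)) == 4))
  tr <- makeTraj()
  expect_identical(unname(resample(tr, timeGrid(0, 4, 5))[, 1L]),
                   c(10, 10, 7, 7, 7))
  expect_error(resample(tr, timeGrid(-1, 4, 3)), "before the trajectory")
})

test_that("resampling a resampled trajectory on the same grid is the identity", {
  tr <- ssaSimulate(immigrationDeath(3, 1), tMax = 4, seed = 5)
  grid <- timeGrid(0, 4, 17)
  m1 <- resample(tr, grid)
  tr2 <- Trajectory(gridPoints(grid), m1, varNames = varNames(tr))
  expect_identical(resample(tr2, grid), m1)
})

test_that("Trajectory validity enforces its invariants", {
  expect_error(Trajectory(c(0, 2, 1), cbind(X = 1:3)), "strictly increasing")
  expect_error(Trajectory(c(0, 1), cbind(X = 1:3)), "nrow")
  expect_error(Trajectory(c(0, 1), matrix(1:4, 2), varNames = c("A", "A")),
               "duplicate")
  expect_error(Trajectory(c(0, 1), matrix(1:4, 2), varNames = c("A", "time")),
               "reserved")
})

test_that("Ensemble requires identical variable names across members", {
  a <- Trajectory(0, cbind(X = 1))
  b <- Trajectory(0, cbind(Y = 1))
  expect_error(Ensemble(list(a, b)), "differing")
  expect_error(Ensemble(list()), "at least one")
  expect_identical(length(Ensemble(list(a, a))), 2L)
})

test_that("TimeGrid points span the interval inclusively", {
  expect_identical(gridPoints(timeGrid(0, 4, 5)), c(0, 1, 2, 3, 4))
  expect_identical(gridPoints(timeGrid(2, 2, 1)), 2)
  expect_error(timeGrid(3, 1, 5), "start must be <= stop")
  expect_error(timeGrid(0, 1, 1), "single-point grid")
})
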