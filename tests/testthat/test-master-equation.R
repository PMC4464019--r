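test_that("an all-constant ensemble concentrates every time slice in one bin", {
  ens <- Ensemble(lapply(1:5, function(i)
    Trajectory(c(0, 10), cbind(X = c(7, 7)))))
  est <- masterEquation(ens, "X", 0, 10, nTimePoints = 6)
  expect_identical(ncol(probMatrix(est)), 1L)
  expect_true(all(probMatrix(est) == 1))
  expect_true(binEdges(est)[1L] < 7 && binEdges(est)[2L] > 7)
})

test_that("every time slice of a master-equation estimate sums to one", {
  for (seed in c(3, 14, 27)) {
    ens <- randomEnsemble(nRuns = 12, seed = seed, tMax = 4)
    est <- masterEquation(ens, "X", 0, 4, nTimePoints = 13)
    expect_true(all(abs(rowSums(probMatrix(est)) - 1) < 1e-12))
    expect_true(all(probMatrix(est) >= 0 & probMatrix(est) <= 1))
  }
})

test_that("state bins are shared and anchored at the global extrema", {
  ens <- randomEnsemble(nRuns = 20, seed = 5, tMax = 4)
  est <- masterEquation(ens, "X", 0, 4, nTimePoints = 9)
  # integer count data: unit bins centred on integers spanning the range
  # of the resampled values
  e <- binEdges(est)
  expect_true(all(abs((e - 0.5) - round(e - 0.5)) < 1e-9))
  expect_identical(diff(range(e)), as.numeric(length(e) - 1L))
})

test_that("grid refinement never changes coinciding time slices", {
  ens <- randomEnsemble(nRuns = 15, seed = 11, tMax = 5)
  coarse <- masterEquation(ens, "X", 0, 5, nTimePoints = 6)   # step 1
  fine <- masterEquation(ens, "X", 0, 5, nTimePoints = 11)    # step 0.5
  # the coarse grid points are the odd rows of the fine grid
  shared <- match(gridPoints(coarse), gridPoints(fine))
  expect_false(anyNA(shared))
  expect_identical(probMatrix(fine)[shared, , drop = FALSE],
                   probMatrix(coarse))
})

test_that("parameter validation rejects degenerate intervals", {
  ens <- randomEnsemble(nRuns = 2, seed = 1)
  expect_error(masterEquation(ens, "X", 5, 5), "start must be <")
  expect_error(masterEquation(ens, "X", 5, 1), "start must be <")
  expect_error(masterEquation(ens, "Y", 0, 2), "unknown variable")
})

test_that("master-equation tables round-trip their header structure", {
  ens <- randomEnsemble(nRuns = 10, seed = 2, tMax = 3)
  est <- masterEquation(ens, "X", 0, 3, nTimePoints = 7)
  f <- tempfile(fileext = ".tsv")
  writeMasterEqTable(est, f)
  tab <- utils::read.delim(f, comment.char = "#", check.names = FALSE)
  expect_identical(nrow(tab), 7L)
  expect_identical(ncol(tab), ncol(probMatrix(est)) + 1L)
  expect_equal(tab$time, gridPoints(est@grid))
  expect_equal(unname(as.matrix(tab[, -1L])), unname(probMatrix(est)),
               tolerance = 1e-15)
})
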