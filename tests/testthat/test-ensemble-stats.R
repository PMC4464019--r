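constEnsemble <- function(values, tEnd = 10) {
  Ensemble(lapply(values, function(v)
    Trajectory(c(0, tEnd), cbind(X = c(v, v)))))
}

test_that("ensemble mean and SD reproduce closed-form toy cases", {
  ens <- constEnsemble(c(4, 6))
  grid <- timeGrid(0, 10, 11)
  m <- ensembleMean(ens, grid)
  s <- ensembleSD(ens, grid)
  expect_true(all(trajValues(m) == 5))
  expect_true(all(trajValues(s) == 1))  # population convention: sqrt(((4-5)^2+(6-5)^2)/2)
  # identical runs have zero dispersion
  expect_true(all(trajValues(ensembleSD(constEnsemble(c(7, 7, 7)), grid)) == 0))
  # unbiased switch uses the n-1 denominator
  su <- ensembleSD(ens, grid, unbiased = TRUE)
  expect_equal(unname(trajValues(su)[1L, 1L]), sqrt(2))
  # single-run ensemble: mean is the run itself resampled
  one <- randomEnsemble(nRuns = 1, seed = 4)
  g2 <- timeGrid(0, 3, 7)
  expect_identical(trajValues(ensembleMean(one, g2)),
                   resample(one[[1L]], g2))
  expect_error(ensembleMean(Ensemble(list()), grid), "at least one")
})

test_that("mean, SD and summary agree with brute-force loops on random ensembles", {
  for (seed in 1:10) {
    ens <- randomEnsemble(nRuns = 5, seed = seed, tMax = 2)
    grid <- timeGrid(0, 2, 9)
    expect_equal(unname(trajValues(ensembleMean(ens, grid))[, 1L]),
                 bruteMean(ens, grid, "X"), tolerance = 1e-12)
    expect_equal(unname(trajValues(ensembleSD(ens, grid))[, 1L]),
                 bruteSD(ens, grid, "X"), tolerance = 1e-12)
    s <- ensembleSummary(ens)
    flat <- unlist(lapply(trajectories(ens), function(tr) trajValues(tr)[, 1L]))
    expect_identical(s$min, min(flat))
    expect_identical(s$max, max(flat))
  }
})

test_that("summary reports ensemble size and global time span", {
  a <- Trajectory(c(0, 10), cbind(X = c(4, 4)))
  b <- Trajectory(c(3, 7), cbind(X = c(2, 9)))
  s <- ensembleSummary(Ensemble(list(a, b)))
  expect_identical(s$tFirst, 0)
  expect_identical(s$tLast, 10)
  expect_identical(s$nRuns, 2L)
  s1 <- ensembleSummary(constEnsemble(4))
  expect_identical(c(s1$min, s1$max), c(4, 4))
})

test_that("gaussianFit returns the closed-form MLE exactly", {
  expect_identical(gaussianFit(c(0, 0))@mu, 0)
  expect_identical(gaussianFit(c(0, 0))@sigma2, 0)
  g <- gaussianFit(c(2, 4))
  expect_identical(g@mu, 3)
  expect_identical(g@sigma2, 1)  # biased variance: ((2-3)^2+(4-3)^2)/2
  expect_error(gaussianFit(numeric(0)), "empty")
})

test_that("gaussianFit recovers parameters from a large normal sample", {
  set.seed(4242)
  x <- rnorm(1e5, mean = 5, sd = 2)
  g <- gaussianFit(x)
  expect_lt(abs(g@mu - 5), 0.05)
  expect_lt(abs(g@sigma2 - 4), 0.1)
})

test_that("pdfAt counts, normalises and attaches fits as documented", {
  # samples {1,1,2,2} on integer-aligned unit bins
  ens <- constEnsemble(c(1, 1, 2, 2))
  d <- pdfAt(ens, 5, "X", normed = TRUE)
  expect_identical(binEdges(d), c(0.5, 1.5, 2.5))
  expect_identical(binMass(d), c(0.5, 0.5))
  expect_identical(d@sampleMin, 1)
  expect_identical(d@sampleMax, 2)
  # raw counts with normed = FALSE
  dc <- pdfAt(ens, 5, "X", normed = FALSE)
  expect_identical(binMass(dc), c(2, 2))
  # density normalisation integrates to 1
  dd <- pdfAt(ens, 5, "X", asDensity = TRUE)
  expect_equal(sum(binMass(dd) * diff(binEdges(dd))), 1, tolerance = 1e-12)
  # degenerate: all samples equal -> one bin, mass 1
  d1 <- pdfAt(constEnsemble(c(3, 3, 3)), 5, "X")
  expect_identical(length(binMass(d1)), 1L)
  expect_identical(binMass(d1), 1)
  expect_true(binEdges(d1)[1L] < 3 && binEdges(d1)[2L] > 3)
  # fit attached alongside the histogram
  df <- pdfAt(ens, 5, "X", fit = TRUE)
  expect_s4_class(densityFit(df), "GaussianFit")
  expect_identical(densityFit(df)@mu, 1.5)
  expect_error(pdfAt(ens, 5, "X", bins = binningSpec(0)), "nBins")
})

test_that("non-integer samples fall back to 30 equal-width bins", {
  ens <- Ensemble(lapply(seq(0.1, 2.05, length.out = 12), function(v)
    Trajectory(0, cbind(X = v))))
  d <- pdfAt(ens, 0, "X")
  expect_identical(length(binMass(d)), 30L)
  expect_equal(sum(binMass(d)), 1, tolerance = 1e-12)
  # explicit bin count override
  d8 <- pdfAt(ens, 0, "X", bins = binningSpec(8))
  expect_identical(length(binMass(d8)), 8L)
})

test_that("values on an edge go right and the last bin is closed", {
  ens <- Ensemble(lapply(c(0, 0.5, 1, 1.5, 2), function(v)
    Trajectory(0, cbind(X = v))))
  d <- pdfAt(ens, 0, "X", bins = binningSpec(4, integerAligned = FALSE))
  # edges 0,.5,1,1.5,2: each interior edge value starts its own bin;
  # the maximum lands in the final (doubly closed) bin
  expect_identical(binMass(d), c(0.2, 0.2, 0.2, 0.4))
})

test_that("pdfMulti shares one set of edges across times", {
  ens <- randomEnsemble(nRuns = 30, seed = 6, tMax = 4)
  ds <- pdfMulti(ens, c(1, 2, 4), "X")
  expect_identical(length(ds), 3L)
  expect_identical(binEdges(ds[[2L]]), binEdges(ds[[1L]]))
  expect_identical(binEdges(ds[[3L]]), binEdges(ds[[1L]]))
  for (d in ds) expect_equal(sum(binMass(d)), 1, tolerance = 1e-12)
  # duplicate times give identical estimates
  dd <- pdfMulti(ens, c(2, 2), "X")
  expect_identical(binMass(dd[[1L]]), binMass(dd[[2L]]))
  # a constant ensemble gives identical single-bin masses at both times
  dc <- pdfMulti(constEnsemble(c(4, 4)), c(1, 9), "X")
  expect_identical(binMass(dc[[1L]]), 1)
  expect_identical(binMass(dc[[2L]]), 1)
})

test_that("phase space projects variables in the requested order", {
  tr <- Trajectory(c(0, 1, 2), cbind(A = c(1, 2, 3), B = c(4, 5, 6),
                                     C = c(7, 8, 9)))
  pp <- phaseSpace(tr, c("C", "A"))
  expect_identical(varNames(pp), c("C", "A"))
  expect_identical(unname(pathPoints(pp)),
                   unname(cbind(c(7, 8, 9), c(1, 2, 3))))
  expect_identical(trajTimes(pp), trajTimes(tr))
  # constant trajectory: all points identical
  ppc <- phaseSpace(Trajectory(c(0, 1), cbind(A = c(2, 2), B = c(3, 3))),
                    c("A", "B"))
  expect_true(all(pathPoints(ppc)[1L, ] == pathPoints(ppc)[2L, ]))
  expect_error(phaseSpace(tr, c("A", "A")), "distinct")
  expect_error(phaseSpace(tr, c("A", "Z")), "unknown variable")
  expect_error(phaseSpace(tr, "A"), "2 or 3")
})

test_that("phaseSpaceAvg composes phaseSpace with ensembleMean", {
  ens <- Ensemble(list(
    ssaSimulate(lotkaVolterra(prey0 = 30L, pred0 = 30L, k2 = 0.03), 3, seed = 1),
    ssaSimulate(lotkaVolterra(prey0 = 30L, pred0 = 30L, k2 = 0.03), 3, seed = 2)))
  grid <- timeGrid(0, 3, 20)
  pp <- phaseSpaceAvg(ens, grid, c("Preys", "Predators"))
  ref <- phaseSpace(ensembleMean(ens, grid), c("Preys", "Predators"))
  expect_identical(pathPoints(pp), pathPoints(ref))
  # single-run ensemble equals the run itself resampled
  one <- Ensemble(trajectories(ens)[1L])
  pp1 <- phaseSpaceAvg(one, grid, c("Preys", "Predators"))
  expect_identical(unname(pathPoints(pp1)),
                   unname(resample(ens[[1L]], grid)))
})

test_that("totalVariation is a metric on probability vectors", {
  expect_identical(totalVariation(c(1, 0), c(0, 1)), 1)
  expect_identical(totalVariation(c(0.5, 0.5), c(0.5, 0.5)), 0)
  expect_identical(totalVariation(c(0.5, 0.5), c(0.25, 0.25, 0.5)), 0.5)
})
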