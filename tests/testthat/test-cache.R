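test_that("identical keys are served from the cache without recomputation", {
  dir <- tempfile("cache")
  ens <- randomEnsemble(nRuns = 4, seed = 2)
  calls <- 0L
  thunk <- function() { calls <<- calls + 1L; pdfAt(ens, 2, "X") }
  key <- cacheKey("pdfAt", lapply(trajectories(ens), trajValues),
                  t = 2, var = "X", bins = "auto")
  r1 <- cacheGetOrCompute(key, thunk, cacheDir = dir)
  expect_false(cacheLastHit())
  r2 <- cacheGetOrCompute(key, thunk, cacheDir = dir)
  expect_true(cacheLastHit())
  expect_identical(calls, 1L)
  expect_equal(binMass(r2), binMass(r1))
  expect_identical(binEdges(r2), binEdges(r1))
})

test_that("keys derive from data content, not identity: edits force recomputation", {
  dir <- tempfile("cache")
  ens <- randomEnsemble(nRuns = 4, seed = 2)
  keyOf <- function(e) cacheKey("pdfAt", lapply(trajectories(e), trajValues),
                                t = 2, var = "X")
  k1 <- keyOf(ens)
  # edit one trajectory value
  tr <- ens[[1L]]
  v <- trajValues(tr); v[1L, 1L] <- v[1L, 1L] + 1
  ens2 <- Ensemble(c(list(Trajectory(trajTimes(tr), v, varNames(tr))),
                     trajectories(ens)[-1L]))
  expect_false(identical(keyOf(ens2), k1))
  # parameter changes also change the key
  expect_false(identical(
    cacheKey("pdfAt", lapply(trajectories(ens), trajValues), t = 2.5, var = "X"),
    k1))
})

test_that("caching is transparent: disabled and enabled runs agree", {
  dir <- tempfile("cache")
  ens <- randomEnsemble(nRuns = 4, seed = 8)
  key <- cacheKey("mean", lapply(trajectories(ens), trajValues), 0, 2, 5)
  thunk <- function() trajValues(ensembleMean(ens, timeGrid(0, 2, 5)))
  on <- cacheGetOrCompute(key, thunk, cacheDir = dir, enabled = TRUE)
  onAgain <- cacheGetOrCompute(key, thunk, cacheDir = dir, enabled = TRUE)
  off <- cacheGetOrCompute(key, thunk, cacheDir = dir, enabled = FALSE)
  expect_identical(on, off)
  expect_identical(onAgain, off)
})

test_that("corrupt cache entries trigger a warned recompute, never a wrong answer", {
  dir <- tempfile("cache"); dir.create(dir, recursive = TRUE)
  key <- cacheKey("op", 1:10)
  r1 <- cacheGetOrCompute(key, function() sum(1:10), cacheDir = dir)
  writeLines("garbage", file.path(dir, paste0(key, ".rds")))  # corrupt it
  expect_warning(r2 <- cacheGetOrCompute(key, function() sum(1:10), cacheDir = dir),
                 "corrupt cache entry")
  expect_identical(r2, 55L)
  # the store healed: next call hits
  r3 <- cacheGetOrCompute(key, function() stop("should not run"), cacheDir = dir)
  expect_identical(r3, 55L)
  expect_true(cacheLastHit())
})

test_that("the store is size-capped with LRU eviction", {
  dir <- tempfile("cache")
  for (i in 1:8) {
    cacheGetOrCompute(cacheKey("op", i), function() rnorm(1000),
                      cacheDir = dir, maxBytes = 20000)
    Sys.sleep(0.01)
  }
  info <- file.info(list.files(dir, full.names = TRUE))
  expect_lte(sum(info$size), 20000)
  expect_lt(nrow(info), 8L)
})
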