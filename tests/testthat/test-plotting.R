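renderedFile <- function(kind, data, ext = "png", ...) {
  out <- tempfile(fileext = paste0(".", ext))
  renderPlot(plotRequest(kind, out, ...), data)
  out
}

expect_image <- function(path) {
  expect_true(file.exists(path))
  expect_gt(file.info(path)$size, 0)
}

test_that("every plot kind renders a non-empty image from matching data", {
  ens <- randomEnsemble(nRuns = 8, seed = 12, tMax = 4)
  grid <- timeGrid(0, 4, 30)
  est <- masterEquation(ens, "X", 0, 4, nTimePoints = 12)
  lv <- ssaSimulate(lotkaVolterra(prey0 = 30L, pred0 = 30L, k2 = 0.03),
                    4, seed = 2)
  d <- pdfAt(ens, 3, "X", fit = TRUE)

  expect_image(renderedFile("traces", ens))
  expect_image(renderedFile("traces", lv, stop = 2))
  expect_image(renderedFile("mean", ens))
  expect_image(renderedFile("sd", ens))
  expect_image(renderedFile("mean_sd", ens))
  expect_image(renderedFile("pdf_bar", d, fit = TRUE))
  expect_image(renderedFile("pdf_3d", pdfMulti(ens, c(1, 2, 4), "X")))
  expect_image(renderedFile("meq_heatmap", est))
  expect_image(renderedFile("meq_surface", est))
  expect_image(renderedFile("phase2d", phaseSpace(lv, c("Preys", "Predators"))))
  tr3 <- Trajectory(0:9, cbind(A = rnorm(10), B = rnorm(10), C = rnorm(10)))
  expect_image(renderedFile("phase3d", phaseSpace(tr3, c("A", "B", "C"))))
  # all three formats work
  expect_image(renderedFile("mean", ens, ext = "svg"))
  expect_image(renderedFile("mean", ens, ext = "pdf"))
})

test_that("rendering never mutates the statistics objects", {
  ens <- randomEnsemble(nRuns = 5, seed = 3, tMax = 3)
  est <- masterEquation(ens, "X", 0, 3, nTimePoints = 8)
  before <- list(probMatrix(est), binEdges(est),
                 lapply(trajectories(ens), trajValues))
  renderedFile("meq_heatmap", est)
  renderedFile("traces", ens)
  after <- list(probMatrix(est), binEdges(est),
                lapply(trajectories(ens), trajValues))
  expect_identical(after, before)
})

test_that("identical requests give byte-stable SVG output", {
  ens <- randomEnsemble(nRuns = 5, seed = 8, tMax = 3)
  d <- pdfAt(ens, 2, "X", fit = TRUE)
  f1 <- renderedFile("pdf_bar", d, ext = "svg", fit = TRUE)
  f2 <- renderedFile("pdf_bar", d, ext = "svg", fit = TRUE)
  expect_identical(readBin(f1, "raw", file.info(f1)$size),
                   readBin(f2, "raw", file.info(f2)$size))
})

test_that("mismatched data, unknown variables and wrong flags are rejected", {
  ens <- randomEnsemble(nRuns = 3, seed = 1)
  est <- masterEquation(ens, "X", 0, 2, nTimePoints = 5)
  expect_error(renderPlot(plotRequest("pdf_bar", tempfile()), ens),
               "usage error")
  expect_error(renderPlot(plotRequest("meq_heatmap", tempfile()),
                          pdfAt(ens, 1, "X")), "usage error")
  expect_error(renderPlot(plotRequest("traces", tempfile(), columns = "Nope"),
                          ens), "unknown variable")
  expect_error(plotRequest("mean", tempfile(), fit = TRUE), "not meaningful")
  expect_error(plotRequest("nope", tempfile()), "unknown plot kind")
})

test_that("time windows filter data before drawing", {
  tr <- Trajectory(0:10, cbind(X = 0:10))
  out <- tempfile(fileext = ".svg")
  renderPlot(plotRequest("traces", out, start = 2, stop = 5), tr)
  expect_image(out)
})
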