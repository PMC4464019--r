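## Batch report runner: a declarative YAML config drives dataset loading (or
## fixture generation), a list of analysis steps, image and table export and
## a run log. Declarative configs rather than executable scripts: safer for
## batch generation, while the full library API stays available to script
## users.

.REPORT_STEP_KINDS <- c("traces", "mean", "sd", "mean_sd", "pdf", "meq",
                        "phase2d", "phase3d")

#' Run a batch analysis report
#'
#' Executes the pipeline described by a config (YAML file path or equivalent
#' named list): load a dataset folder (or generate one from a built-in model
#' first), run each analysis step in order, and write every product into the
#' output directory — `images/` for figures, `tables/` for exported
#' statistics, `run.log` for a log recording every parameter actually used
#' (including resolved defaults, dataset size, per-variable min/max and
#' Gaussian-fit mu/sigma2 where fits were requested) and a `MANIFEST` listing
#' the outputs. All steps are validated before any is executed; a failing
#' step aborts with a message naming it, retaining partial outputs with the
#' MANIFEST marked incomplete.
#'
#' Config schema (YAML):
#' ```yaml
#' dataset:
#'   path: runs/                 # folder of delimited run files
#'   col_names: [time, Preys, Predators]   # optional; first = time
#'   n_workers: 1                # optional
#' simulate:                     # optional: generate the folder first
#'   model: lotka_volterra       # lotka_volterra | immigration_death |
#'   params: {k1: 1, k2: 0.004, k3: 1, prey0: 250, pred0: 250}  # pure_death
#'   n_runs: 100
#'   t_max: 100
#'   seed: 1
#' steps:
#'   - kind: traces              # traces|mean|sd|mean_sd|pdf|meq|phase2d|phase3d
#'     columns: [Preys, Predators]
#'     stop: 1000
#'   - kind: pdf
#'     time: 100
#'     columns: [Preys, Predators]
#'     normed: true
#'     fit: true
#'   - kind: meq
#'     var: Preys
#'     start: 0
#'     stop: 100
#' output_dir: report/
#' format: png                   # optional: png|svg|pdf
#' ```
#'
#' @param config a YAML file path or a named list with the schema above.
#' @return The output directory path, invisibly.
#' @export
runReport <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- .validateReportConfig(config)
  outDir <- cfg$output_dir
  imgDir <- file.path(outDir, "images")
  tabDir <- file.path(outDir, "tables")
  for (d in c(outDir, imgDir, tabDir))
    dir.create(d, showWarnings = FALSE, recursive = TRUE)
  logPath <- file.path(outDir, "run.log")
  manifest <- file.path(outDir, "MANIFEST")
  logCon <- file(logPath, "w")
  on.exit(close(logCon))
  outputs <- character(0)
  logLine <- function(...) {
    line <- sprintf(...)
    writeLines(paste(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), line), logCon)
    message(line)
  }
  writeManifest <- function(status) {
    writeLines(c(sprintf("status: %s", status), outputs), manifest)
  }

  logLine("report started (EnsembleKinetics %s)",
          as.character(utils::packageVersion("EnsembleKinetics")))

  if (!is.null(cfg$simulate)) {
    sim <- cfg$simulate
    logLine("simulate: model=%s n_runs=%d t_max=%g seed=%d out=%s",
            sim$model, sim$n_runs, sim$t_max, sim$seed, cfg$dataset$path)
    model <- .buildModel(sim)
    generateEnsemble(model, sim$n_runs, sim$t_max, sim$seed,
                     outDir = cfg$dataset$path)
  }

  ds <- cfg$dataset
  logLine("load_dataset: path=%s pattern=%s n_workers=%d", ds$path,
          ds$pattern, ds$n_workers)
  ens <- loadDataset(ds$path, pattern = ds$pattern, colNames = ds$col_names,
                     nWorkers = ds$n_workers)
  logLine("dataset: %d runs, variables: %s", length(ens),
          paste(varNames(ens), collapse = ", "))
  summ <- ensembleSummary(ens)
  for (i in seq_len(nrow(summ)))
    logLine("summary: %s min=%g max=%g t_first=%g t_last=%g",
            summ$var[i], summ$min[i], summ$max[i], summ$tFirst[i], summ$tLast[i])

  fmt <- cfg$format
  for (si in seq_along(cfg$steps)) {
    step <- cfg$steps[[si]]
    stepName <- sprintf("step %d (%s)", si, step$kind)
    res <- tryCatch(
      .runReportStep(step, si, ens, imgDir, tabDir, fmt, logLine),
      error = function(e) {
        logLine("FAILED %s: %s", stepName, conditionMessage(e))
        writeManifest(sprintf("incomplete: failed at %s", stepName))
        stop(sprintf("%s failed: %s", stepName, conditionMessage(e)),
             call. = FALSE)
      })
    outputs <- c(outputs, res)
  }

  writeManifest("complete")
  logLine("report complete: %d outputs", length(outputs))
  invisible(outDir)
}

.buildModel <- function(sim) {
  params <- if (is.null(sim$params)) list() else sim$params
  switch(sim$model,
    lotka_volterra = do.call(lotkaVolterra, params),
    immigration_death = do.call(immigrationDeath, params),
    pure_death = do.call(pureDeath, params),
    stop(sprintf("unknown model '%s'", sim$model)))
}

.validateReportConfig <- function(cfg) {
  if (is.null(cfg$dataset) || is.null(cfg$dataset$path))
    stop("config error: dataset.path is required")
  if (is.null(cfg$steps) || !length(cfg$steps))
    stop("config error: at least one analysis step is required")
  if (is.null(cfg$output_dir)) stop("config error: output_dir is required")
  cfg$dataset$pattern <- cfg$dataset$pattern %||% "*"
  cfg$dataset$n_workers <- as.integer(cfg$dataset$n_workers %||% 1L)
  cfg$dataset$col_names <- if (!is.null(cfg$dataset$col_names))
    as.character(cfg$dataset$col_names)
  cfg$format <- cfg$format %||% "png"
  if (!cfg$format %in% c("png", "svg", "pdf"))
    stop("config error: format must be png, svg or pdf")
  if (!is.null(cfg$simulate)) {
    sim <- cfg$simulate
    for (f in c("model", "n_runs", "t_max", "seed"))
      if (is.null(sim[[f]])) stop(sprintf("config error: simulate.%s is required", f))
    cfg$simulate$n_runs <- as.integer(sim$n_runs)
    cfg$simulate$seed <- as.integer(sim$seed)
  }
  for (si in seq_along(cfg$steps)) {
    step <- cfg$steps[[si]]
    if (is.null(step$kind) || !step$kind %in% .REPORT_STEP_KINDS)
      stop(sprintf("config error in step %d: kind must be one of %s", si,
                   paste(.REPORT_STEP_KINDS, collapse = ", ")))
    if (step$kind == "pdf" && is.null(step$time))
      stop(sprintf("config error in step %d: pdf needs 'time'", si))
    if (step$kind == "meq" && (is.null(step$start) || is.null(step$stop)))
      stop(sprintf("config error in step %d: meq needs 'start' and 'stop'", si))
    if (step$kind %in% c("phase2d", "phase3d") && is.null(step$vars))
      stop(sprintf("config error in step %d: %s needs 'vars'", si, step$kind))
  }
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.runReportStep <- function(step, si, ens, imgDir, tabDir, fmt, logLine) {
  kind <- step$kind
  img <- function(suffix = "") file.path(
    imgDir, sprintf("%02d_%s%s.%s", si, kind, suffix, fmt))
  produced <- character(0)

  if (kind %in% c("traces", "mean", "sd", "mean_sd")) {
    req <- plotRequest(kind, img(), columns = step$columns,
                       start = step$start %||% NA, stop = step$stop %||% NA)
    logLine("step %d: kind=%s columns=%s start=%s stop=%s", si, kind,
            if (length(req@columns)) paste(req@columns, collapse = ",") else "all",
            format(req@start), format(req@stop))
    renderPlot(req, ens)
    produced <- req@outPath
  } else if (kind == "pdf") {
    cols <- step$columns %||% varNames(ens)
    normed <- isTRUE(step$normed %||% TRUE)
    fit <- isTRUE(step$fit %||% FALSE)
    nBins <- step$n_bins %||% "auto"
    for (v in cols) {
      d <- pdfAt(ens, step$time, v, bins = binningSpec(nBins),
                 normed = normed, fit = fit)
      logLine("step %d: pdf var=%s t=%g normed=%s fit=%s n_bins=%s min=%g max=%g",
              si, v, step$time, normed, fit, as.character(nBins),
              d@sampleMin, d@sampleMax)
      if (!is.null(d@fit))
        logLine("step %d: gaussian fit %s: mu=%.6g sigma2=%.6g", si, v,
                d@fit@mu, d@fit@sigma2)
      req <- plotRequest("pdf_bar", img(paste0("_", v)), normed = normed,
                         fit = fit)
      renderPlot(req, d)
      tab <- file.path(tabDir, sprintf("%02d_pdf_%s.tsv", si, v))
      writeDensityTable(d, tab)
      produced <- c(produced, req@outPath, tab)
    }
  } else if (kind == "meq") {
    cols <- step$var %||% step$columns %||% varNames(ens)
    nTime <- as.integer(step$n_time_points %||% 50L)
    nBins <- step$n_bins %||% "auto"
    for (v in cols) {
      est <- masterEquation(ens, v, step$start, step$stop, nTimePoints = nTime,
                            bins = binningSpec(nBins))
      logLine("step %d: meq var=%s start=%g stop=%g n_time_points=%d n_bins=%s",
              si, v, step$start, step$stop, nTime, as.character(nBins))
      surface <- isTRUE(step$surface %||% FALSE)
      req <- plotRequest(if (surface) "meq_surface" else "meq_heatmap",
                         img(paste0("_", v)))
      renderPlot(req, est)
      tab <- file.path(tabDir, sprintf("%02d_meq_%s.tsv", si, v))
      writeMasterEqTable(est, tab)
      produced <- c(produced, req@outPath, tab)
    }
  } else if (kind %in% c("phase2d", "phase3d")) {
    vars <- as.character(step$vars)
    tFirst <- max(vapply(trajectories(ens), function(tr) tr@times[1L], numeric(1)))
    tLast <- max(vapply(trajectories(ens),
                        function(tr) tr@times[length(tr@times)], numeric(1)))
    grid <- timeGrid(step$start %||% tFirst, step$stop %||% tLast,
                     as.integer(step$n_points %||% 200L))
    pp <- phaseSpaceAvg(ens, grid, vars)
    logLine("step %d: %s vars=%s grid=[%g, %g] x %d", si, kind,
            paste(vars, collapse = ","), grid@start, grid@stop, grid@nPoints)
    req <- plotRequest(kind, img())
    renderPlot(req, pp)
    produced <- req@outPath
  }
  produced
}
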