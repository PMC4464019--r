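## Rendering of every statistic to image files. Trajectories are drawn as
## step (post) functions, matching the zero-order-hold sampling semantics;
## only mean traces are drawn as smooth lines. Heatmaps use the viridis
## colour map with the probability scale anchored at [0, max mass] per plot.
## Rendering is side-effect-only: the statistics objects are never modified.

#' Render a plot request to an image file
#'
#' Draws one figure described by a [PlotRequest-class] from a matching data
#' object and writes it to the request's `outPath` (png, svg or pdf). The
#' `start`/`stop` window is applied to the data before drawing. Supported
#' pairings:
#'
#' * `traces` — [Trajectory-class] or [Ensemble-class]; step functions, one
#'   legend entry per variable (all runs overlaid for an ensemble).
#' * `mean`, `sd`, `mean_sd` — [Ensemble-class]; `mean_sd` shades mean ± SD.
#' * `pdf_bar` — a [DensityEstimate-class]; bars, with the Gaussian fit curve
#'   overlaid when the estimate carries one.
#' * `pdf_3d` — a list of [DensityEstimate-class] (from [pdfMulti()]); one
#'   panel per time point.
#' * `meq_heatmap`, `meq_surface` — a [MasterEqEstimate-class]; time on the
#'   horizontal axis, state bins on the vertical, colour (or height) =
#'   probability mass.
#' * `phase2d`, `phase3d` — a [PhasePath-class].
#'
#' @param req a [PlotRequest-class].
#' @param data the statistic object to draw (see pairings above).
#' @param gridPointsDefault grid resolution used when an ensemble must be
#'   resampled for mean/sd drawing (default 200).
#' @return The output path, invisibly.
#' @export
renderPlot <- function(req, data, gridPointsDefault = 200L) {
  stopifnot(is(req, "PlotRequest"))
  kind <- req@kind
  p <- switch(kind,
    traces = .plotTraces(req, data),
    mean = .plotMoment(req, data, gridPointsDefault, what = "mean"),
    sd = .plotMoment(req, data, gridPointsDefault, what = "sd"),
    mean_sd = .plotMoment(req, data, gridPointsDefault, what = "mean_sd"),
    pdf_bar = .plotPdfBar(req, data),
    pdf_3d = .plotPdfMulti(req, data),
    meq_heatmap = .plotMeqHeatmap(req, data),
    phase2d = .plotPhase2d(req, data),
    meq_surface = ,
    phase3d = NULL)

  if (kind %in% c("meq_surface", "phase3d")) {
    .withDevice(req, function() {
      if (kind == "meq_surface") .drawMeqSurface(req, data) else .drawPhase3d(req, data)
    })
  } else {
    .saveGG(req, p)
  }
  invisible(req@outPath)
}

.windowTimes <- function(times, req) {
  lo <- if (is.na(req@start)) -Inf else req@start
  hi <- if (is.na(req@stop)) Inf else req@stop
  times >= lo & times <= hi
}

.pickColumns <- function(vn, req) {
  if (!length(req@columns)) return(vn)
  missing <- setdiff(req@columns, vn)
  if (length(missing))
    stop(sprintf("unknown variable(s): %s", paste(missing, collapse = ", ")))
  req@columns
}

# Long-format frame for trace drawing. Traces longer than maxPoints are
# resampled (zero-order hold) onto a uniform grid of that many points: the
# drawn values are exact sample-path values, only the drawing resolution is
# capped.
.trajLong <- function(tr, req, run, maxPoints = 2000L) {
  cols <- .pickColumns(tr@varNames, req)
  keep <- .windowTimes(tr@times, req)
  tms <- tr@times[keep]
  vals <- tr@values[keep, , drop = FALSE]
  if (length(tms) > maxPoints) {
    grid <- seq(tms[1L], tms[length(tms)], length.out = maxPoints)
    idx <- findInterval(grid, tms)
    tms <- grid
    vals <- vals[idx, , drop = FALSE]
  }
  do.call(rbind, lapply(cols, function(v) data.frame(
    time = tms, value = vals[, match(v, tr@varNames)], var = v, run = run)))
}

.plotTraces <- function(req, data) {
  df <- if (is(data, "Trajectory")) .trajLong(data, req, run = 1L)
  else if (is(data, "Ensemble"))
    do.call(rbind, lapply(seq_along(data@trajectories), function(i)
      .trajLong(data@trajectories[[i]], req, run = i)))
  else stop("usage error: 'traces' needs a Trajectory or an Ensemble")
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$value, colour = .data$var,
                                   group = interaction(.data$run, .data$var))) +
    ggplot2::geom_step(alpha = if (max(df$run) > 1L) 0.35 else 1, linewidth = 0.3) +
    ggplot2::labs(x = "time", y = "value", colour = "variable") +
    .ekTheme()
}

.plotMoment <- function(req, data, gridPointsDefault, what) {
  if (!is(data, "Ensemble"))
    stop(sprintf("usage error: '%s' needs an Ensemble", what))
  tFirst <- max(vapply(data@trajectories, function(tr) tr@times[1L], numeric(1)))
  tLast <- max(vapply(data@trajectories,
                      function(tr) tr@times[length(tr@times)], numeric(1)))
  lo <- if (is.na(req@start)) tFirst else max(req@start, tFirst)
  hi <- if (is.na(req@stop)) tLast else min(req@stop, tLast)
  grid <- timeGrid(lo, hi, gridPointsDefault)
  cols <- .pickColumns(varNames(data), req)
  m <- ensembleMean(data, grid)
  s <- ensembleSD(data, grid)
  df <- do.call(rbind, lapply(cols, function(v) data.frame(
    time = m@times, mean = sampleAt(m, m@times, v), sd = sampleAt(s, s@times, v),
    var = v)))
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$time, colour = .data$var,
                                        fill = .data$var))
  if (what %in% c("mean_sd"))
    p <- p + ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                               ymax = .data$mean + .data$sd),
                                  alpha = 0.25, colour = NA)
  if (what %in% c("mean", "mean_sd"))
    p <- p + ggplot2::geom_line(ggplot2::aes(y = .data$mean))
  if (what == "sd")
    p <- p + ggplot2::geom_line(ggplot2::aes(y = .data$sd))
  p + ggplot2::labs(x = "time", y = if (what == "sd") "standard deviation" else "value",
                    colour = "variable", fill = "variable") + .ekTheme()
}

.pdfFrame <- function(d) {
  e <- d@binEdges
  data.frame(mid = (e[-1L] + e[-length(e)]) / 2, width = diff(e), mass = d@mass,
             time = d@time)
}

.plotPdfBar <- function(req, data) {
  if (!is(data, "DensityEstimate"))
    stop("usage error: 'pdf_bar' needs a DensityEstimate")
  df <- .pdfFrame(data)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$mid, .data$mass)) +
    ggplot2::geom_col(width = df$width, fill = "steelblue",
                      colour = "grey30", linewidth = 0.2) +
    ggplot2::labs(x = data@varName,
                  y = switch(data@normed, mass = "probability",
                             density = "density", count = "count"),
                  title = sprintf("%s at t = %g (n = %d)", data@varName,
                                  data@time, data@nSamples)) +
    .ekTheme()
  if (!is.null(data@fit)) {
    fit <- data@fit
    scale <- switch(data@normed,
                    mass = mean(diff(data@binEdges)),
                    density = 1,
                    count = mean(diff(data@binEdges)) * data@nSamples)
    xs <- seq(data@binEdges[1L], data@binEdges[length(data@binEdges)],
              length.out = 200L)
    curve <- data.frame(x = xs,
                        y = stats::dnorm(xs, fit@mu, sqrt(max(fit@sigma2, 1e-300))) * scale)
    p <- p + ggplot2::geom_line(data = curve, ggplot2::aes(.data$x, .data$y),
                                colour = "firebrick", linewidth = 0.6)
  }
  p
}

.plotPdfMulti <- function(req, data) {
  if (is(data, "DensityEstimate")) data <- list(data)
  if (!is.list(data) || !all(vapply(data, is, logical(1), "DensityEstimate")))
    stop("usage error: 'pdf_3d' needs a list of DensityEstimate objects")
  df <- do.call(rbind, lapply(data, .pdfFrame))
  ggplot2::ggplot(df, ggplot2::aes(.data$mid, .data$mass)) +
    ggplot2::geom_col(width = df$width, fill = "steelblue",
                      colour = "grey30", linewidth = 0.2) +
    ggplot2::facet_wrap(~time, labeller = ggplot2::label_both) +
    ggplot2::labs(x = data[[1L]]@varName, y = "probability") +
    .ekTheme()
}

.meqFrame <- function(est, req) {
  tms <- gridPoints(est@grid)
  keep <- .windowTimes(tms, req)
  e <- est@binEdges
  mids <- (e[-1L] + e[-length(e)]) / 2
  expand <- expand.grid(time = tms[keep], state = mids)
  expand$mass <- as.vector(est@prob[keep, , drop = FALSE])
  expand
}

.plotMeqHeatmap <- function(req, data) {
  if (!is(data, "MasterEqEstimate"))
    stop("usage error: 'meq_heatmap' needs a MasterEqEstimate")
  df <- .meqFrame(data, req)
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$state, fill = .data$mass)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, max(df$mass)), name = "P(x, t)") +
    ggplot2::labs(x = "time", y = data@varName) +
    .ekTheme()
}

.plotPhase2d <- function(req, data) {
  if (!is(data, "PhasePath") || length(data@varNames) != 2L)
    stop("usage error: 'phase2d' needs a 2-variable PhasePath")
  keep <- .windowTimes(data@times, req)
  df <- data.frame(x = data@points[keep, 1L], y = data@points[keep, 2L])
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_path(colour = "steelblue", linewidth = 0.4) +
    ggplot2::labs(x = data@varNames[1L], y = data@varNames[2L]) +
    .ekTheme()
}

.drawMeqSurface <- function(req, data) {
  if (!is(data, "MasterEqEstimate"))
    stop("usage error: 'meq_surface' needs a MasterEqEstimate")
  tms <- gridPoints(data@grid)
  keep <- .windowTimes(tms, req)
  e <- data@binEdges
  mids <- (e[-1L] + e[-length(e)]) / 2
  z <- data@prob[keep, , drop = FALSE]
  if (sum(keep) < 2L || length(mids) < 2L)
    stop("usage error: surface plot needs at least a 2x2 probability grid")
  graphics::persp(tms[keep], mids, z, theta = 35, phi = 30,
                  xlab = "time", ylab = data@varName, zlab = "P(x, t)",
                  col = "lightsteelblue", border = "grey40",
                  ticktype = "detailed")
}

.drawPhase3d <- function(req, data) {
  if (!is(data, "PhasePath") || length(data@varNames) != 3L)
    stop("usage error: 'phase3d' needs a 3-variable PhasePath")
  keep <- .windowTimes(data@times, req)
  pts <- data@points[keep, , drop = FALSE]
  lim <- function(v) grDevices::extendrange(v)
  pm <- graphics::persp(lim(pts[, 1L]), lim(pts[, 2L]),
                        matrix(min(pts[, 3L]), 2L, 2L),
                        zlim = lim(pts[, 3L]), theta = 35, phi = 25,
                        xlab = data@varNames[1L], ylab = data@varNames[2L],
                        zlab = data@varNames[3L], border = NA, col = NA,
                        ticktype = "detailed")
  xy <- grDevices::trans3d(pts[, 1L], pts[, 2L], pts[, 3L], pm)
  graphics::lines(xy, col = "steelblue")
}

.ekTheme <- function() {
  ggplot2::theme_bw(base_size = 10) +
    ggplot2::theme(panel.grid.minor = ggplot2::element_blank())
}

.openDevice <- function(req, width = 7, height = 5) {
  switch(req@format,
    png = grDevices::png(req@outPath, width = width, height = height,
                         units = "in", res = 150),
    svg = grDevices::svg(req@outPath, width = width, height = height),
    pdf = grDevices::pdf(req@outPath, width = width, height = height))
}

.withDevice <- function(req, drawFn) {
  .openDevice(req)
  on.exit(grDevices::dev.off())
  drawFn()
}

.saveGG <- function(req, p) {
  .openDevice(req)
  on.exit(grDevices::dev.off())
  print(p)
}
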