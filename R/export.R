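#' @importFrom rlang .data
NULL

## Delimited-text export of the statistics types, for downstream use.

#' Write a density estimate as a delimited table
#'
#' Three columns: lower and upper bin edge and the bin value (`mass`,
#' `density` or `count`, per the estimate), tab-separated with a header; a
#' leading comment line records the variable, time and sample size.
#'
#' @param d a [DensityEstimate-class].
#' @param path output file.
#' @param delimiter field delimiter (default tab).
#' @return `path`, invisibly.
#' @export
writeDensityTable <- function(d, path, delimiter = "\t") {
  stopifnot(is(d, "DensityEstimate"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# density of %s at t = %.17g (n = %d, %s)",
                     d@varName, d@time, d@nSamples, d@normed), con)
  if (!is.null(d@fit))
    writeLines(sprintf("# gaussian fit: mu = %.17g sigma2 = %.17g",
                       d@fit@mu, d@fit@sigma2), con)
  writeLines(paste(c("edge_lo", "edge_hi", d@normed), collapse = delimiter), con)
  e <- d@binEdges
  writeLines(paste(sprintf("%.17g", e[-length(e)]),
                   sprintf("%.17g", e[-1L]),
                   sprintf("%.17g", d@mass), sep = delimiter), con)
  invisible(path)
}

#' Write a master-equation estimate as a delimited table
#'
#' A grid-times x state-bins matrix with header rows: the first data column
#' holds the grid time, the remaining columns one probability mass per state
#' bin (headers give the bin midpoints); comment lines record the variable
#' and the bin edges.
#'
#' @param est a [MasterEqEstimate-class].
#' @param path output file.
#' @param delimiter field delimiter (default tab).
#' @return `path`, invisibly.
#' @export
writeMasterEqTable <- function(est, path, delimiter = "\t") {
  stopifnot(is(est, "MasterEqEstimate"))
  con <- file(path, "w")
  on.exit(close(con))
  e <- est@binEdges
  mids <- (e[-1L] + e[-length(e)]) / 2
  writeLines(sprintf("# master-equation estimate of %s", est@varName), con)
  writeLines(paste0("# bin edges: ", paste(sprintf("%.17g", e), collapse = " ")), con)
  writeLines(paste(c("time", sprintf("bin_%g", mids)), collapse = delimiter), con)
  tms <- gridPoints(est@grid)
  for (i in seq_along(tms))
    writeLines(paste(sprintf("%.17g", c(tms[i], est@prob[i, ])),
                     collapse = delimiter), con)
  invisible(path)
}
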