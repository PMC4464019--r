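## Delimited-text trajectory I/O. One file per run, first column time,
## remaining columns model variables. "#"-lines are comments.

.isNumericToken <- function(tok) {
  suppressWarnings(!is.na(as.numeric(tok))) |
    tok %in% c("NA", "NaN", "Inf", "-Inf")
}

.splitLine <- function(line, delim) {
  if (delim == " ") strsplit(trimws(line), "[ \t]+")[[1L]]
  else strsplit(line, delim, fixed = TRUE)[[1L]]
}

# Delimiter auto-detection on the first non-comment line: tab, comma,
# semicolon, whitespace, in that order.
.detectDelimiter <- function(line) {
  if (grepl("\t", line)) "\t"
  else if (grepl(",", line, fixed = TRUE)) ","
  else if (grepl(";", line, fixed = TRUE)) ";"
  else " "
}

#' Read a single trajectory from a delimited text file
#'
#' Loads the output of one simulation run: a text table whose time column
#' (first by default) must be strictly increasing, with the remaining columns
#' holding model-variable values. Delimiter and header handling follow the
#' rules documented in [LoadSpec-class]; malformed input (ragged rows,
#' non-numeric cells, non-monotone or duplicate times) raises a format error
#' naming the offending row.
#'
#' @param path a file path, or a [LoadSpec-class] carrying all options.
#' @param colNames optional names for all columns, first entry naming the
#'   time column (overrides any header).
#' @param delimiter `"auto"` or an explicit delimiter character.
#' @param hasHeader `"auto"`, `TRUE` or `FALSE`.
#' @param timeColumn 1-based index of the time column.
#' @return A [Trajectory-class].
#' @examples
#' f <- tempfile(fileext = ".txt")
#' writeLines(c("time\tPreys\tPredators", "0\t100\t100", "0.4\t101\t100"), f)
#' readTimeSeries(f)
#' @export
readTimeSeries <- function(path, colNames = NULL, delimiter = "auto",
                           hasHeader = "auto", timeColumn = 1L) {
  if (is(path, "LoadSpec")) {
    spec <- path
    return(readTimeSeries(spec@path,
                          colNames = if (length(spec@colNames)) spec@colNames,
                          delimiter = spec@delimiter,
                          hasHeader = switch(spec@hasHeader, yes = TRUE,
                                             no = FALSE, "auto"),
                          timeColumn = spec@timeColumn))
  }
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  fast <- .readTimeSeriesFast(path, colNames, delimiter, hasHeader, timeColumn)
  if (!is.null(fast)) return(fast)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!length(lines)) stop(sprintf("format error in %s: no data lines", path))

  delim <- if (identical(delimiter, "auto")) .detectDelimiter(lines[1L]) else delimiter
  first <- .splitLine(lines[1L], delim)
  header <- if (identical(hasHeader, "auto")) !all(.isNumericToken(first))
            else isTRUE(hasHeader)

  headerNames <- NULL
  if (header) { headerNames <- trimws(first); lines <- lines[-1L] }
  if (!length(lines)) stop(sprintf("format error in %s: header but no data", path))

  toks <- if (delim == " ") strsplit(trimws(lines), "[ \t]+")
          else strsplit(lines, delim, fixed = TRUE)
  ncols <- lengths(toks)
  if (length(unique(ncols)) != 1L)
    stop(sprintf("format error in %s: ragged rows (row %d has %d columns, expected %d)",
                 path, which(ncols != ncols[1L])[1L],
                 ncols[which(ncols != ncols[1L])[1L]], ncols[1L]))
  nc <- ncols[1L]
  vals <- suppressWarnings(matrix(as.numeric(unlist(toks)), ncol = nc, byrow = TRUE))
  if (anyNA(vals)) {
    bad <- which(rowSums(is.na(vals)) > 0)[1L]
    stop(sprintf("format error in %s: non-numeric cell in data row %d", path, bad))
  }

  if (!is.null(colNames)) {
    if (length(colNames) != nc)
      stop(sprintf("colNames has %d entries but %s has %d columns",
                   length(colNames), path, nc))
    names <- colNames
  } else if (!is.null(headerNames)) {
    names <- headerNames
  } else {
    names <- c(.RESERVED_TIME_NAME, paste0("V", seq_len(nc - 1L)))
    if (timeColumn != 1L)
      names <- append(paste0("V", seq_len(nc - 1L)), .RESERVED_TIME_NAME,
                      after = timeColumn - 1L)
  }

  if (timeColumn > nc) stop(sprintf("timeColumn %d out of range", timeColumn))
  times <- vals[, timeColumn]
  if (length(times) > 1L && any(diff(times) <= 0)) {
    bad <- which(diff(times) <= 0)[1L] + 1L
    stop(sprintf("format error in %s: times not strictly increasing at data row %d (t = %g)",
                 path, bad, times[bad]))
  }
  Trajectory(times, vals[, -timeColumn, drop = FALSE],
             varNames = names[-timeColumn])
}

#' Load a folder of trajectories as an Ensemble
#'
#' Reads every file in a directory matching a glob, one independent run per
#' file, in sorted-filename order. Loading can fan out over `nWorkers`
#' forked processes; the merge is by sorted filename, so the resulting
#' ensemble is bit-identical for every worker count. Files whose variable
#' names (or column counts) disagree abort the load with an error listing the
#' offenders.
#'
#' @param path a directory path, or a [LoadSpec-class] carrying all options.
#' @param pattern filename glob (default `"*"`).
#' @param nWorkers parallel worker processes (default 1).
#' @inheritParams readTimeSeries
#' @return An [Ensemble-class] with `provenance` set to the folder path.
#' @seealso [generateEnsemble()] to create such folders from built-in models.
#' @export
loadDataset <- function(path, pattern = "*", colNames = NULL, delimiter = "auto",
                        hasHeader = "auto", timeColumn = 1L, nWorkers = 1L) {
  if (is(path, "LoadSpec")) {
    spec <- path
    return(loadDataset(spec@path, pattern = spec@pattern,
                       colNames = if (length(spec@colNames)) spec@colNames,
                       delimiter = spec@delimiter,
                       hasHeader = switch(spec@hasHeader, yes = TRUE,
                                          no = FALSE, "auto"),
                       timeColumn = spec@timeColumn, nWorkers = spec@nWorkers))
  }
  if (!dir.exists(path)) stop(sprintf("directory not found: %s", path))
  files <- sort(list.files(path, pattern = utils::glob2rx(pattern),
                           full.names = TRUE))
  files <- files[!dir.exists(files)]
  if (!length(files))
    stop(sprintf("empty dataset: no files matching '%s' in %s", pattern, path))

  readOne <- function(f) readTimeSeries(f, colNames = colNames,
                                        delimiter = delimiter,
                                        hasHeader = hasHeader,
                                        timeColumn = timeColumn)
  trs <- if (nWorkers > 1L && .Platform$OS.type == "unix") {
    res <- parallel::mclapply(files, readOne, mc.cores = nWorkers)
    fail <- vapply(res, inherits, logical(1), "try-error")
    if (any(fail)) stop(attr(res[[which(fail)[1L]]], "condition"))
    res
  } else {
    lapply(files, readOne)
  }

  ref <- trs[[1L]]@varNames
  bad <- !vapply(trs, function(tr) identical(tr@varNames, ref), logical(1))
  if (any(bad))
    stop(sprintf("inconsistent dataset: variable names in %s differ from %s",
                 paste(basename(files[bad]), collapse = ", "),
                 basename(files[1L])))
  Ensemble(trs, provenance = path)
}

# Fast path for large well-formed files: delegate tokenising to
# data.table::fread after running the package's own delimiter and header
# detection on the first line. Anything unusual — comment lines, whitespace
# delimiters, non-numeric cells — returns NULL and the line-based parser
# (which owns the error reporting) takes over. The fast path may only ever
# fall back, never produce a different result.
.readTimeSeriesFast <- function(path, colNames, delimiter, hasHeader, timeColumn) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (!length(first) || grepl("^\\s*#", first) || !nzchar(trimws(first)))
    return(NULL)
  delim <- if (identical(delimiter, "auto")) .detectDelimiter(first) else delimiter
  if (!delim %in% c("\t", ",", ";")) return(NULL)
  toks <- .splitLine(first, delim)
  header <- if (identical(hasHeader, "auto")) !all(.isNumericToken(toks))
            else isTRUE(hasHeader)
  vals <- tryCatch({
    dt <- data.table::fread(path, sep = delim, header = FALSE,
                            skip = if (header) 1L else 0L,
                            colClasses = "numeric", showProgress = FALSE,
                            data.table = FALSE)
    as.matrix(dt)
  }, error = function(e) NULL, warning = function(w) NULL)
  if (is.null(vals) || !nrow(vals) || !is.numeric(vals) || anyNA(vals))
    return(NULL)  # mid-file comments or bad cells surface as NA/errors here
  if (timeColumn != 1L) return(NULL)
  nc <- ncol(vals)
  names <- if (!is.null(colNames)) {
    if (length(colNames) != nc)
      stop(sprintf("colNames has %d entries but %s has %d columns",
                   length(colNames), path, nc))
    colNames
  } else if (header) {
    trimws(toks)
  } else {
    c(.RESERVED_TIME_NAME, paste0("V", seq_len(nc - 1L)))
  }
  if (timeColumn > nc) stop(sprintf("timeColumn %d out of range", timeColumn))
  times <- vals[, timeColumn]
  if (length(times) > 1L && any(diff(times) <= 0)) {
    bad <- which(diff(times) <= 0)[1L] + 1L
    stop(sprintf("format error in %s: times not strictly increasing at data row %d (t = %g)",
                 path, bad, times[bad]))
  }
  Trajectory(times, vals[, -timeColumn, drop = FALSE],
             varNames = names[-timeColumn])
}

#' Write a trajectory as delimited text
#'
#' Emits the package's native dialect: a tab-separated table with a header
#' line (`time` plus the variable names) and values printed with 17
#' significant digits, enough to reproduce each double exactly, so the file
#' round-trips through [readTimeSeries()] without loss.
#'
#' @param traj a [Trajectory-class].
#' @param path output file path.
#' @param delimiter field delimiter (default tab).
#' @return `path`, invisibly.
#' @export
writeTrajectory <- function(traj, path, delimiter = "\t") {
  # %.17g round-trips IEEE doubles exactly; fwrite caps at 15 digits
  header <- paste(c(.RESERVED_TIME_NAME, traj@varNames), collapse = delimiter)
  cols <- lapply(seq_len(ncol(traj@values) + 1L), function(j)
    sprintf("%.17g", if (j == 1L) traj@times else traj@values[, j - 1L]))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(header, do.call(paste, c(cols, sep = delimiter))), con)
  invisible(path)
}
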