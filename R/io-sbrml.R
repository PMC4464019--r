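## SBRML (Systems Biology Results Markup Language) time-course subset.
##
## Supported layout, one <resultComponent> per trajectory:
##   <sbrml><operations><operation><result>
##     <resultComponent id="run_1">
##       <dimensionDescription>
##         <compositeDescription name="time" indexType="double">
##           <compositeDescription name="variable" indexType="string">
##             <atomicDescription name="value" valueType="double"/>
##       <dimension>
##         <compositeValue indexValue="0">            <- one per time point
##           <compositeValue indexValue="Preys">      <- one per variable
##             <atomicValue>100</atomicValue>
##
## The outer index is time, the inner index the variable name. Anything else
## (no time dimension, extra nesting) is rejected with an unsupported-dialect
## error naming the offending element rather than half-parsed.

.SBRML_NS <- "http://www.sbrml.org/sbrml/level1/version1"

#' Read an SBRML time-course file as an Ensemble
#'
#' Parses the time-course subset of SBRML described in the package vignette:
#' one `resultComponent` per trajectory, an outer composite dimension indexed
#' by time and an inner one indexed by variable name. Malformed XML raises a
#' parse error; any other result layout raises an unsupported-dialect error
#' naming the element.
#'
#' @param path an SBRML XML file.
#' @return An [Ensemble-class], one trajectory per result component.
#' @seealso [writeSBRML()]
#' @export
readSBRML <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop(sprintf("SBRML parse error in %s: %s",
                                                   path, conditionMessage(e))))
  xml2::xml_ns_strip(doc)
  comps <- xml2::xml_find_all(doc, ".//resultComponent")
  if (!length(comps))
    stop(sprintf("unsupported SBRML dialect in %s: no <resultComponent> found", path))

  trs <- lapply(comps, function(comp) {
    id <- xml2::xml_attr(comp, "id")
    dd <- xml2::xml_find_first(comp, "./dimensionDescription/compositeDescription")
    if (inherits(dd, "xml_missing") ||
        !identical(tolower(xml2::xml_attr(dd, "name")), "time"))
      stop(sprintf(paste0("unsupported SBRML dialect in result component '%s': ",
                          "outer <compositeDescription> must be the time dimension"),
                   id))
    rows <- xml2::xml_find_all(comp, "./dimension/compositeValue")
    if (!length(rows))
      stop(sprintf("unsupported SBRML dialect in result component '%s': empty <dimension>",
                   id))
    times <- as.numeric(xml2::xml_attr(rows, "indexValue"))
    if (anyNA(times))
      stop(sprintf("unsupported SBRML dialect in result component '%s': non-numeric time index",
                   id))
    vnames <- NULL
    vals <- lapply(seq_along(rows), function(i) {
      cells <- xml2::xml_find_all(rows[[i]], "./compositeValue")
      nm <- xml2::xml_attr(cells, "indexValue")
      if (is.null(vnames)) vnames <<- nm
      else if (!identical(nm, vnames))
        stop(sprintf("unsupported SBRML dialect in result component '%s': inconsistent variables at time row %d",
                     id, i))
      as.numeric(xml2::xml_text(xml2::xml_find_first(cells, "./atomicValue")))
    })
    Trajectory(times, do.call(rbind, vals), varNames = vnames)
  })
  Ensemble(trs, provenance = path)
}

#' Write an Ensemble as an SBRML time-course file
#'
#' Emits the same subset that [readSBRML()] consumes (one result component
#' per trajectory), with values printed at 17 significant digits so that the
#' write/read round-trip reproduces the ensemble exactly.
#'
#' @param ens a non-empty [Ensemble-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeSBRML <- function(ens, path) {
  stopifnot(is(ens, "Ensemble"))
  if (any(!nzchar(varNames(ens))))
    stop("cannot write SBRML: empty variable name in ensemble")
  doc <- xml2::xml_new_root("sbrml", xmlns = .SBRML_NS, level = "1", version = "1")
  result <- xml2::xml_add_child(
    xml2::xml_add_child(xml2::xml_add_child(doc, "operations"),
                        "operation", id = "op1", name = "timeCourseSimulation"),
    "result")
  num <- function(x) sprintf("%.17g", x)
  for (k in seq_along(ens@trajectories)) {
    tr <- ens@trajectories[[k]]
    comp <- xml2::xml_add_child(result, "resultComponent",
                                id = sprintf("run_%d", k))
    dd <- xml2::xml_add_child(comp, "dimensionDescription")
    cdTime <- xml2::xml_add_child(dd, "compositeDescription",
                                  name = "time", indexType = "double")
    cdVar <- xml2::xml_add_child(cdTime, "compositeDescription",
                                 name = "variable", indexType = "string")
    xml2::xml_add_child(cdVar, "atomicDescription",
                        name = "value", valueType = "double")
    dim <- xml2::xml_add_child(comp, "dimension")
    for (i in seq_along(tr@times)) {
      row <- xml2::xml_add_child(dim, "compositeValue",
                                 indexValue = num(tr@times[i]))
      for (j in seq_along(tr@varNames)) {
        cell <- xml2::xml_add_child(row, "compositeValue",
                                    indexValue = tr@varNames[j])
        xml2::xml_add_child(cell, "atomicValue", num(tr@values[i, j]))
      }
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}
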