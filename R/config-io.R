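## Serialize a SimulationConfig to a flat YAML key-value file and back,
## so a pipeline run is fully described by one small text file.

.configSlots <- function() {
  setdiff(slotNames("SimulationConfig"), "dropoutSamples")
}

#' Write a SimulationConfig as YAML
#' @param config a \linkS4class{SimulationConfig}.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeSimulationConfig <- function(config, path) {
  stopifnot(is(config, "SimulationConfig"))
  vals <- lapply(.configSlots(), function(s) slot(config, s))
  names(vals) <- .configSlots()
  dd <- config@dropoutSamples
  vals$dropoutSamples <- if (nrow(dd) > 0)
    lapply(seq_len(nrow(dd)), function(i)
      as.list(dd[i, c("individual_id", "treatment", "timepoint")]))
  else list()
  yaml::write_yaml(vals, path, precision = 15)
  invisible(path)
}

#' Read a SimulationConfig from YAML
#' @param path file written by \code{\link{writeSimulationConfig}} (or
#'   hand-edited; missing keys fall back to constructor defaults).
#' @return a validated \linkS4class{SimulationConfig}.
#' @export
readSimulationConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.list(vals))
    stop("not a configuration file (no key-value pairs): ", path)
  args <- vals[intersect(names(vals), .configSlots())]
  if ("dropoutSamples" %in% names(vals)) {
    args$dropoutSamples <- if (length(vals$dropoutSamples) > 0)
      do.call(rbind, lapply(vals$dropoutSamples, as.data.frame))
    else data.frame(individual_id = character(),
                    treatment = character(), timepoint = character())
  }
  if ("responderPenetrance" %in% names(args))
    args$responderPenetrance <- as.numeric(unlist(args$responderPenetrance))
  do.call(SimulationConfig, args)
}
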