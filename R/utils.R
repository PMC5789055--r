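#' Write a run manifest next to an analysis output
#'
#' Records everything needed to re-run an analysis bit-identically: the
#' step name, full parameter set, master seed, package version, output
#' paths and wall-clock start.
#'
#' @param path JSON file to write.
#' @param step name of the analysis step.
#' @param seed master seed used.
#' @param parameters named list of parameters (must be JSON-serialisable).
#' @param outputs character vector of output paths.
#' @return the manifest list, invisibly.
#' @export
write_run_manifest <- function(path, step, seed, parameters = list(),
                               outputs = character(0)) {
  manifest <- list(
    step = step,
    seed = seed,
    parameters = parameters,
    outputs = outputs,
    package = "spineclust",
    package_version = as.character(packageVersion("spineclust")),
    started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(manifest)
}
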