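#' Write a run manifest for a pipeline stage
#'
#' Provenance record accompanying every analysis output directory: stage
#' name, configuration, md5 hashes of the input files, seeds, package
#' version and a timestamp. Rerunning a deterministic stage with an
#' identical manifest reproduces identical outputs.
#'
#' @param out_dir Output directory (created if missing); the manifest is
#'   written as `manifest.json` inside it.
#' @param stage Stage name (e.g. "synth", "rdf", "activity", "optimize").
#' @param config Named list of stage parameters (must be JSON-serializable).
#' @param inputs Character vector of input file paths to hash. Default none.
#' @param seed Integer seed(s) used by the stage, or NULL.
#' @return The manifest as a list, invisibly.
#' @export
write_run_manifest <- function(out_dir, stage, config = list(),
                               inputs = character(0), seed = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hashes <- if (length(inputs)) {
    h <- tools::md5sum(inputs)
    stats::setNames(as.character(h), names(h))
  } else NULL
  manifest <- list(
    stage = stage,
    config = config,
    input_md5 = hashes,
    seed = seed,
    package_version = as.character(utils::packageVersion("kbff")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(manifest)
}
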