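SESSION_SCHEMA_VERSION <- "1.0"

#' Write a simulated session container
#'
#' Serializes an `fg_dataset` losslessly as a directory of plain-text
#' tables: `responses.csv` (neurons x trials), `trials.csv`, `neurons.csv`,
#' and `provenance.json` carrying the schema version, seeds, grid, and
#' generator configuration. The layout mirrors the logical content of an
#' archival recording deposit (per-neuron trial tables, responses, cell
#' metadata) in a language-neutral form.
#'
#' @param dataset an `fg_dataset`.
#' @param dir output directory (created if missing).
#' @export
write_session <- function(dataset, dir) {
  stopifnot(inherits(dataset, "fg_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(as.data.frame(dataset$responses),
                   file.path(dir, "responses.csv"), row.names = FALSE)
  utils::write.csv(dataset$trials, file.path(dir, "trials.csv"),
                   row.names = FALSE)
  utils::write.csv(dataset$neurons, file.path(dir, "neurons.csv"),
                   row.names = FALSE)
  prov <- dataset$provenance
  prov$schema_version <- SESSION_SCHEMA_VERSION
  prov$grid <- unclass(dataset$grid)
  jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a session container
#'
#' @param dir directory written by [write_session()].
#' @return an `fg_dataset`.
#' @export
read_session <- function(dir) {
  prov_path <- file.path(dir, "provenance.json")
  if (!file.exists(prov_path)) {
    stop("not a session container (missing provenance.json): ", dir)
  }
  prov <- jsonlite::read_json(prov_path, simplifyVector = TRUE)
  if (is.null(prov$schema_version)) {
    stop("corrupted session container: provenance lacks a schema version")
  }
  if (!identical(prov$schema_version, SESSION_SCHEMA_VERSION)) {
    stop(sprintf("session schema version mismatch: found %s, expected %s",
                 prov$schema_version, SESSION_SCHEMA_VERSION))
  }
  responses <- as.matrix(utils::read.csv(file.path(dir, "responses.csv")))
  dimnames(responses) <- NULL
  trials <- utils::read.csv(file.path(dir, "trials.csv"),
                            stringsAsFactors = FALSE)
  neurons <- utils::read.csv(file.path(dir, "neurons.csv"),
                             stringsAsFactors = FALSE)
  grid <- do.call(position_grid, prov$grid[c(
    "n_azimuth", "n_elevation", "azimuth_span_deg", "elevation_span_deg",
    "repeats_per_position", "dwell_ms")])
  prov$grid <- NULL
  structure(list(responses = responses, trials = trials, neurons = neurons,
                 grid = grid, provenance = prov),
            class = "fg_dataset")
}
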