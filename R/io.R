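## CSV/JSON readers and writers and run manifests.

#' Read an RT-qPCR time-series CSV
#'
#' Expects header `experiment,species,time_s,replicate,value`. Species names
#' must be the nine canonical names (see [canonical_species()]); times must be
#' non-negative.
#'
#' @param path CSV file path.
#' @return A validated `data.frame` of class `"timeseries_data"`.
#' @export
read_timeseries <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_timeseries(df, path = path)
}

validate_timeseries <- function(df, path = "<data>") {
  need <- c("experiment", "species", "time_s", "replicate", "value")
  if (!all(need %in% names(df))) {
    stop(path, ": missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  if (nrow(df) == 0L) stop(path, ": empty dataset")
  bad <- which(!df$species %in% canonical_species())
  if (length(bad)) {
    sug <- vapply(df$species[bad[1]], function(s) {
      d <- utils::adist(s, canonical_species())
      canonical_species()[which.min(d)]
    }, character(1))
    stop(path, ": unknown species at rows ",
         paste(utils::head(bad + 1L, 5L), collapse = ", "),
         " ('", df$species[bad[1]], "'; did you mean '", sug, "'?)")
  }
  if (any(!is.finite(df$time_s)) || any(df$time_s < 0)) {
    stop(path, ": time_s must be finite and non-negative")
  }
  if (any(!df$experiment %in% c("expt1", "expt2"))) {
    stop(path, ": experiment must be 'expt1' or 'expt2'")
  }
  class(df) <- c("timeseries_data", "data.frame")
  df
}

#' Write a time-series data frame as CSV
#' @param data A `timeseries_data` data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a pathway configuration file
#'
#' JSON configuration with optional blocks `variant`, `geometry`, `rates`,
#' whose field names match the arguments of [pathway_variant()],
#' [gene_geometry()] and [rate_set()].
#'
#' @param path JSON file path.
#' @return A list with validated `variant`, `geometry` and `rates` objects.
#' @export
read_pathway_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  variant <- do.call(pathway_variant, as.list(cfg$variant))
  geometry <- do.call(gene_geometry, as.list(cfg$geometry))
  rates_args <- as.list(cfg$rates)
  base <- unclass(default_rates(variant$mutant))
  unknown <- setdiff(names(rates_args), names(base))
  if (length(unknown)) stop("unknown rate fields: ",
                            paste(unknown, collapse = ", "))
  rates <- do.call(rate_set, utils::modifyList(base, rates_args))
  list(variant = variant, geometry = geometry, rates = rates)
}

#' Write a run manifest
#'
#' Records the command, seeds, parameters and package version of a run as
#' JSON, so any output can be reproduced.
#'
#' @param path Output JSON path.
#' @param command Name of the operation.
#' @param seeds Named list/vector of seeds used.
#' @param params Arbitrary JSON-encodable parameter echo.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, command, seeds, params = list()) {
  manifest <- list(
    command = command,
    seeds = seeds,
    params = params,
    package_version = as.character(utils::packageVersion("splicekin")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
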