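#' Load a configuration from file and/or overrides
#'
#' Resolution order: explicit overrides (e.g. command-line flags) take
#' precedence over file values, which take precedence over the package
#' defaults. Unknown keys are rejected with the offending names.
#'
#' @param path `NULL` or path to a YAML file whose keys are [sim_config()]
#'   argument names.
#' @param overrides Named list of [sim_config()] arguments.
#' @return A validated [sim_config()].
#' @export
load_config <- function(path = NULL, overrides = list()) {
  known <- names(formals(sim_config))
  vals <- list()
  if (!is.null(path)) {
    file_vals <- yaml::read_yaml(path)
    if (length(file_vals) && is.null(names(file_vals))) {
      stop("config file must be a mapping of parameter names to values",
           call. = FALSE)
    }
    extra <- setdiff(names(file_vals), known)
    if (length(extra)) {
      stop("unknown configuration key(s): ", paste(extra, collapse = ", "),
           call. = FALSE)
    }
    vals[names(file_vals)] <- file_vals
  }
  extra <- setdiff(names(overrides), known)
  if (length(extra)) {
    stop("unknown configuration key(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  vals[names(overrides)] <- overrides
  do.call(sim_config, vals)
}

#' Write a configuration to a YAML file
#'
#' Round-trips through [load_config()]: reading the file back yields an
#' identical configuration.
#'
#' @param config A [sim_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  config <- validate_sim_config(config)
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Write / read a per-hour evolution trace as CSV
#'
#' One row per simulated hour with the schema
#' `iteration,avg_power,crop_health_pct,alive_bugs_pct,pesticide_per_station,messages_this_hour,active_stations,alive_bugs`.
#'
#' @param sim A `pest_sim` from [run_simulation()].
#' @param path Output path.
#' @return `path` invisibly (writer); the trace data frame (reader).
#' @export
write_evolution_csv <- function(sim, path) {
  stopifnot(inherits(sim, "pest_sim"))
  utils::write.csv(sim$trace, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_evolution_csv
#' @export
read_evolution_csv <- function(path) {
  tr <- utils::read.csv(path)
  stopifnot(identical(names(tr), trace_columns()))
  tr
}

#' Write the final summary of a run as JSON
#'
#' The four final metrics plus diagnostics, a full echo of the configuration
#' and the seed, for machine consumption.
#'
#' @param sim A `pest_sim`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary_json <- function(sim, path) {
  stopifnot(inherits(sim, "pest_sim"))
  jsonlite::write_json(
    list(final = sim$final, config = unclass(sim$config),
         seed = sim$config$seed),
    path, auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(path)
}

#' Write / read a replicate batch as CSV
#'
#' Schema: `strategy,replicate,seed,power,crop_health,alive_bugs,pesticide`.
#'
#' @param batch A `pest_batch` from [run_batch()].
#' @param path Output path.
#' @return `path` invisibly (writer); a `pest_batch` (reader).
#' @export
write_batch_csv <- function(batch, path) {
  stopifnot(inherits(batch, "pest_batch"))
  utils::write.csv(as.data.frame(batch), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_batch_csv
#' @export
read_batch_csv <- function(path) {
  b <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("strategy", "replicate", "seed", "power", "crop_health",
            "alive_bugs", "pesticide")
  stopifnot(identical(names(b), need))
  class(b) <- c("pest_batch", "data.frame")
  b
}

#' Write a comparison report to a directory
#'
#' Emits `summary.csv`, `levene.csv`, `robust.csv`, `pairwise.csv`,
#' `effects.csv` and a human-readable `report.txt` with the significance-star
#' conventions.
#'
#' @param comparison A `pest_comparison` from [compare_strategies()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_comparison <- function(comparison, dir) {
  stopifnot(inherits(comparison, "pest_comparison"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in c("summary", "levene", "robust", "pairwise", "effects")) {
    utils::write.csv(comparison[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  txt <- utils::capture.output(print(comparison))
  writeLines(txt, file.path(dir, "report.txt"))
  invisible(dir)
}
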