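#' Scripted infestation scenario
#'
#' A scenario script makes a run fully deterministic for testing and
#' step-through analysis of the communication protocols: bugs are injected at
#' prescribed hours and zones, and the stochastic appearance draw and/or the
#' random walk can be switched off.
#'
#' @param spawns `NULL` or a data frame with integer columns `hour` (1-based
#'   simulation hour), `x`, `y` (0-based zone coordinates) and `count`.
#' @param disable_movement If `TRUE`, bugs never move.
#' @param disable_appearance If `TRUE`, the stochastic appearance draw is
#'   skipped (only scripted spawns occur).
#' @return An object of class `scenario_script`.
#' @export
scenario_script <- function(spawns = NULL,
                            disable_movement = FALSE,
                            disable_appearance = FALSE) {
  if (!is.null(spawns)) {
    spawns <- as.data.frame(spawns)
    need <- c("hour", "x", "y", "count")
    if (!all(need %in% names(spawns))) {
      stop("spawns must have columns ", paste(need, collapse = ", "),
           call. = FALSE)
    }
    if (any(spawns$hour < 1L) || any(spawns$count < 0L)) {
      stop("scenario spawns: hour must be >= 1 and count >= 0", call. = FALSE)
    }
  }
  structure(list(spawns = spawns,
                 disable_movement = isTRUE(disable_movement),
                 disable_appearance = isTRUE(disable_appearance)),
            class = "scenario_script")
}

# bounds checks that need the configuration
validate_scenario <- function(scenario, cfg) {
  if (is.null(scenario)) return(invisible(NULL))
  stopifnot(inherits(scenario, "scenario_script"))
  sp <- scenario$spawns
  if (!is.null(sp) && nrow(sp) > 0L) {
    if (any(sp$hour > cfg$hours)) {
      stop("scenario spawns: hour exceeds the simulated duration", call. = FALSE)
    }
    if (any(sp$x < 0L | sp$x >= cfg$columns | sp$y < 0L | sp$y >= cfg$rows)) {
      stop("scenario spawns: zone out of grid bounds", call. = FALSE)
    }
  }
  invisible(NULL)
}

#' Read a scenario script from a YAML file
#'
#' Expected keys: `spawns` (list of maps with `hour`, `x`, `y`, `count`),
#' `disable_movement`, `disable_appearance`; all optional.
#'
#' @param path Path to a YAML file.
#' @return A [scenario_script()].
#' @export
read_scenario <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("spawns", "disable_movement", "disable_appearance")
  extra <- setdiff(names(raw), known)
  if (length(extra)) {
    stop("unknown scenario key(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  spawns <- NULL
  if (!is.null(raw$spawns)) {
    spawns <- do.call(rbind, lapply(raw$spawns, function(s) {
      # YAML 1.1 parses a bare `y` key as the boolean TRUE; undo that
      names(s)[names(s) == "TRUE"] <- "y"
      missing <- setdiff(c("hour", "x", "y", "count"), names(s))
      if (length(missing)) {
        stop("scenario spawn entry lacks key(s): ",
             paste(missing, collapse = ", "), call. = FALSE)
      }
      as.data.frame(s[c("hour", "x", "y", "count")])
    }))
  }
  scenario_script(spawns = spawns,
                  disable_movement = isTRUE(raw$disable_movement),
                  disable_appearance = isTRUE(raw$disable_appearance))
}
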