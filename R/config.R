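#' Simulation configuration
#'
#' Builds and validates the full parameter set of a simulation run.  Defaults
#' reproduce the reference experimental scenario: a 10 x 16 sensor grid (one
#' sensor per 100 x 100 m zone), 2 initially infested zones, an hourly bug
#' appearance probability of 0.10 and a 48-hour horizon.  The remaining
#' constants calibrate the environment dynamics and are expressed in natural
#' units: crop-health percentages per hour, energy units per message and
#' millilitres of pesticide per fumigated sensor-hour.
#'
#' @param columns Number of grid columns `M` (positive integer).
#' @param rows Number of grid rows `N` (positive integer).
#' @param initial_affected_areas Number of distinct zones seeded with bugs at
#'   hour 0 (must not exceed `columns * rows`).
#' @param p_appear Probability, per simulated hour, that new bugs appear
#'   somewhere in the field (in `[0, 1]`).
#' @param max_new_bugs Upper bound of the uniform draw for the number of bugs
#'   appearing in one appearance event (positive integer).
#' @param hours Simulated duration `T` in hours (non-negative integer).
#' @param strategy Name of the communication strategy; one of
#'   `strategy_names()` (`"broadcast"`, `"neighbor"`, `"lowcost_neighbor"`).
#' @param fumigation_window Window `d` (hours) used by the low-cost neighbor
#'   strategy both to keep fumigating after a detection and to suppress
#'   redundant warnings.
#' @param bugs_per_initial_area Bugs placed in each initially affected zone.
#' @param exposure_hours_to_die Cumulative fumigated hours after which an
#'   exposed bug dies.
#' @param eat_rate Crop health (percentage points) eaten per bug per hour.
#' @param grow_rate Crop health (percentage points) regrown per hour; must be
#'   smaller than `eat_rate` (bugs eat much faster than the crop regrows).
#' @param energy_per_message Energy units accounted per sent message.
#' @param pesticide_per_fumigation Millilitres dispensed per sensor per
#'   fumigated hour.
#' @param seed Integer seed driving all randomness of the run.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @examples
#' cfg <- sim_config(seed = 1)
#' cfg$columns * cfg$rows  # 160 zones
#' @export
sim_config <- function(columns = 10L,
                       rows = 16L,
                       initial_affected_areas = 2L,
                       p_appear = 0.10,
                       max_new_bugs = 3L,
                       hours = 48L,
                       strategy = "neighbor",
                       fumigation_window = 3L,
                       bugs_per_initial_area = 1L,
                       exposure_hours_to_die = 3L,
                       eat_rate = 2.0,
                       grow_rate = 0.1,
                       energy_per_message = 1.0,
                       pesticide_per_fumigation = 1.0,
                       seed = 1L) {
  cfg <- list(
    columns = as.integer(columns),
    rows = as.integer(rows),
    initial_affected_areas = as.integer(initial_affected_areas),
    p_appear = as.numeric(p_appear),
    max_new_bugs = as.integer(max_new_bugs),
    hours = as.integer(hours),
    strategy = as.character(strategy),
    fumigation_window = as.integer(fumigation_window),
    bugs_per_initial_area = as.integer(bugs_per_initial_area),
    exposure_hours_to_die = as.integer(exposure_hours_to_die),
    eat_rate = as.numeric(eat_rate),
    grow_rate = as.numeric(grow_rate),
    energy_per_message = as.numeric(energy_per_message),
    pesticide_per_fumigation = as.numeric(pesticide_per_fumigation),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  fail <- function(msg) stop("invalid configuration: ", msg, call. = FALSE)
  scalars <- vapply(cfg, length, 0L)
  if (any(scalars != 1L)) {
    fail(sprintf("field(s) %s must be scalar",
                 paste(names(cfg)[scalars != 1L], collapse = ", ")))
  }
  if (anyNA(unlist(cfg, use.names = FALSE))) fail("NA values are not allowed")
  if (cfg$columns < 1L || cfg$rows < 1L) fail("grid dimensions must be >= 1")
  if (cfg$p_appear < 0 || cfg$p_appear > 1) {
    fail(sprintf("p_appear = %g must lie in [0, 1]", cfg$p_appear))
  }
  if (cfg$initial_affected_areas < 0L) fail("initial_affected_areas must be >= 0")
  if (cfg$initial_affected_areas > cfg$columns * cfg$rows) {
    fail("initial_affected_areas exceeds the number of zones")
  }
  if (cfg$max_new_bugs < 1L) fail("max_new_bugs must be >= 1")
  if (cfg$hours < 0L) fail("hours must be >= 0")
  if (!cfg$strategy %in% strategy_names()) {
    fail(sprintf("unknown strategy '%s'; registered strategies: %s",
                 cfg$strategy, paste(strategy_names(), collapse = ", ")))
  }
  if (cfg$fumigation_window < 1L) fail("fumigation_window must be >= 1")
  if (cfg$bugs_per_initial_area < 1L) fail("bugs_per_initial_area must be >= 1")
  if (cfg$exposure_hours_to_die < 1L) fail("exposure_hours_to_die must be >= 1")
  if (cfg$eat_rate < 0 || cfg$grow_rate < 0) fail("rates must be >= 0")
  if (cfg$grow_rate >= cfg$eat_rate) {
    fail("grow_rate must be smaller than eat_rate")
  }
  if (cfg$energy_per_message < 0) fail("energy_per_message must be >= 0")
  if (cfg$pesticide_per_fumigation < 0) fail("pesticide_per_fumigation must be >= 0")
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> %d x %d grid, %d h, strategy '%s', seed %d\n",
              x$columns, x$rows, x$hours, x$strategy, x$seed))
  cat(sprintf("  infestation: %d initial areas x %d bugs, p_appear %.3g/h, <= %d new bugs\n",
              x$initial_affected_areas, x$bugs_per_initial_area,
              x$p_appear, x$max_new_bugs))
  cat(sprintf("  dynamics: eat %.3g%%/h, grow %.3g%%/h, death after %d fumigated h, window d = %d h\n",
              x$eat_rate, x$grow_rate, x$exposure_hours_to_die, x$fumigation_window))
  cat(sprintf("  calibration: %.3g energy/message, %.3g mL pesticide/fumigated hour\n",
              x$energy_per_message, x$pesticide_per_fumigation))
  invisible(x)
}

# linear zone/sensor id for column x (0-based) and row y (0-based)
zone_id <- function(x, y, columns) x + columns * y + 1L

# inverse of zone_id: matrix with columns x, y (0-based)
zone_xy <- function(i, columns) {
  i0 <- i - 1L
  cbind(x = i0 %% columns, y = i0 %/% columns)
}
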