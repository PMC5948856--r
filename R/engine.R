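#' Initialise a simulation world
#'
#' Seeds the random number generator from `config$seed`, lays out the grid of
#' zones (all at 100% health) with one sensor per zone, picks the initially
#' affected zones uniformly at random without replacement, places the initial
#' bugs and resets every ledger. The world is a mutable environment advanced
#' in place by [run_iteration()].
#'
#' @param config A [sim_config()].
#' @param scenario Optional [scenario_script()].
#' @return A world environment.
#' @export
initialize_world <- function(config, scenario = NULL) {
  config <- validate_sim_config(config)
  validate_scenario(scenario, config)
  set.seed(config$seed)

  w <- new.env(parent = emptyenv())
  w$cfg <- config
  w$columns <- config$columns
  w$rows <- config$rows
  w$n_zones <- config$columns * config$rows
  w$scenario <- scenario
  w$t <- 0L
  w$t_cur <- 0L

  w$health <- rep(100, w$n_zones)
  w$fum_now <- rep(FALSE, w$n_zones)
  w$fum_prev <- rep(FALSE, w$n_zones)
  w$pesticide <- rep(0, w$n_zones)

  w$bug_x <- integer()
  w$bug_y <- integer()
  w$bug_alive <- logical()
  w$bug_exposure <- integer()
  w$bug_born <- integer()

  w$energy <- 0
  w$energy_sensor <- rep(0, w$n_zones)
  w$msg_hour <- 0L
  w$active <- rep(FALSE, w$n_zones)
  w$zone_bug_count <- integer(w$n_zones)

  hours <- config$hours
  w$hist_msgs <- integer(hours)
  w$hist_active <- integer(hours)
  w$trace_mat <- matrix(NA_real_, nrow = hours, ncol = 8L,
                        dimnames = list(NULL, trace_columns()))

  # boundary-clipped 8-neighborhoods and, for the last-warnings matrix, the
  # flattened local index under which each neighbor is filed
  xy <- zone_xy(seq_len(w$n_zones), w$columns)
  w$nbr <- vector("list", w$n_zones)
  w$nbr_loc <- vector("list", w$n_zones)
  for (i in seq_len(w$n_zones)) {
    x <- xy[[i, "x"]]; y <- xy[[i, "y"]]
    ids <- integer(); locs <- integer()
    for (ly in 0:2) for (lx in 0:2) {
      if (lx == 1L && ly == 1L) next
      gx <- x + lx - 1L; gy <- y + ly - 1L
      if (gx >= 0L && gx < w$columns && gy >= 0L && gy < w$rows) {
        ids <- c(ids, zone_id(gx, gy, w$columns))
        locs <- c(locs, lx + 3L * ly + 1L)
      }
    }
    w$nbr[[i]] <- ids
    w$nbr_loc[[i]] <- locs
  }

  st <- get_strategy(config$strategy)
  w$live_hook <- st$live
  w$manage_hook <- st$manage
  if (!is.null(st$init)) st$init(w)

  if (config$initial_affected_areas > 0L) {
    zones <- sample.int(w$n_zones, config$initial_affected_areas)
    per <- config$bugs_per_initial_area
    z <- rep(zones, each = per)
    pos <- zone_xy(z, w$columns)
    add_bugs(w, pos[, "x"], pos[, "y"])
  }
  w
}

trace_columns <- function() {
  c("iteration", "avg_power", "crop_health_pct", "alive_bugs_pct",
    "pesticide_per_station", "messages_this_hour", "active_stations",
    "alive_bugs")
}

#' Advance the world by one simulated hour
#'
#' Phases run in a fixed order so that equal seeds give bitwise-identical
#' traces: (1) the previous hour's fumigation flags shift into `fum_prev` and
#' the hourly ledgers reset; (2) stochastic appearance (and any scripted
#' spawns); (3) clamped random-walk movement of alive bugs; (4) every sensor's
#' periodic hook runs in raster order, with messages delivered synchronously;
#' (5) bugs in zones fumigated this hour accrue exposure and die at the
#' threshold; (6) surviving bugs eat unless the zone was fumigated the
#' previous hour; (7) all zones regrow; (8) the observer appends a metric
#' record.
#'
#' @param world A world environment.
#' @return The world, invisibly.
#' @export
run_iteration <- function(world) {
  cfg <- world$cfg
  if (world$t >= cfg$hours) {
    stop("run_iteration: the simulation horizon has been reached", call. = FALSE)
  }
  t <- world$t + 1L
  world$t_cur <- t

  # (1) roll fumigation flags, reset hourly ledgers
  world$fum_prev <- world$fum_now
  world$fum_now <- rep(FALSE, world$n_zones)
  world$active <- rep(FALSE, world$n_zones)
  world$msg_hour <- 0L

  # (2) bug appearance
  sc <- world$scenario
  if (is.null(sc) || !sc$disable_appearance) {
    db <- spawn_count(cfg$p_appear, cfg$max_new_bugs)
    place_new_bugs(world, db)
  }
  if (!is.null(sc) && !is.null(sc$spawns)) {
    due <- sc$spawns[sc$spawns$hour == t, , drop = FALSE]
    for (k in seq_len(nrow(due))) {
      n <- due$count[k]
      if (n > 0L) add_bugs(world, rep(due$x[k], n), rep(due$y[k], n))
    }
  }

  # (3) movement (creation order; one x-offset and one y-offset per bug)
  if (is.null(sc) || !sc$disable_movement) {
    alive <- which(world$bug_alive)
    if (length(alive)) {
      moved <- move_bug(world$bug_x[alive], world$bug_y[alive],
                        world$columns, world$rows)
      world$bug_x[alive] <- moved$x
      world$bug_y[alive] <- moved$y
    }
  }

  # (4) periodic hooks in raster order, synchronous message delivery
  alive <- world$bug_alive
  world$zone_bug_count <- if (any(alive)) {
    tabulate(zone_id(world$bug_x[alive], world$bug_y[alive], world$columns),
             nbins = world$n_zones)
  } else {
    integer(world$n_zones)
  }
  live <- world$live_hook
  for (i in seq_len(world$n_zones)) live(world, i, t)

  # (5) pesticide exposure and death
  apply_exposure(world)

  # (6) eating, (7) regrowth
  bug_eat(world)
  crop_grow(world)

  # (8) observer record
  world$hist_msgs[t] <- world$msg_hour
  world$hist_active[t] <- sum(world$active)
  world$t <- t
  rec <- compute_metrics(world, t)
  world$trace_mat[t, ] <- unlist(rec, use.names = FALSE)
  invisible(world)
}

#' Compute the observer metrics at an iteration
#'
#' A station is active in an hour if it sent at least one message or
#' fumigated. Instantaneous power of an hour with at least one active station
#' is `messages * energy_per_message / active_stations`; the reported average
#' power is the running mean of instantaneous power over all such hours up to
#' `t` (0 if there has been none). Crop health is the mean zone health,
#' alive-bug percentage is `100 * alive / total_ever` (100 when no bug has
#' ever existed), and pesticide per station is the cumulative dispensed volume
#' divided by the number of sensors.
#'
#' @param world A world environment.
#' @param t Iteration to report (defaults to the current one).
#' @return A named list (one metric record).
#' @export
compute_metrics <- function(world, t = world$t) {
  cfg <- world$cfg
  if (t > 0L) {
    msgs <- world$hist_msgs[seq_len(t)]
    act <- world$hist_active[seq_len(t)]
    defined <- act > 0L
    avg_power <- if (any(defined)) {
      mean(msgs[defined] * cfg$energy_per_message / act[defined])
    } else 0
    messages_this_hour <- world$hist_msgs[t]
    active_stations <- world$hist_active[t]
  } else {
    avg_power <- 0
    messages_this_hour <- 0L
    active_stations <- 0L
  }
  total_ever <- length(world$bug_alive)
  n_alive <- sum(world$bug_alive)
  list(
    iteration = t,
    avg_power = avg_power,
    crop_health_pct = mean(world$health),
    alive_bugs_pct = if (total_ever == 0L) 100 else 100 * n_alive / total_ever,
    pesticide_per_station = sum(world$pesticide) / world$n_zones,
    messages_this_hour = messages_this_hour,
    active_stations = active_stations,
    alive_bugs = n_alive
  )
}

#' Run a full simulation
#'
#' Initialises the world from the configuration (seeding the RNG from
#' `config$seed`) and advances it hour by hour, collecting one metric record
#' per hour.
#'
#' @param config A [sim_config()].
#' @param scenario Optional [scenario_script()].
#' @param keep_world Keep the final world environment in the result (useful
#'   for inspection; off by default).
#' @return An object of class `pest_sim`: a list with the `config`, the
#'   per-hour `trace` data frame (one row per hour, columns `iteration`,
#'   `avg_power`, `crop_health_pct`, `alive_bugs_pct`,
#'   `pesticide_per_station`, `messages_this_hour`, `active_stations`,
#'   `alive_bugs`) and `final`, the last record as a named list (`NULL` for a
#'   zero-hour run).
#' @examples
#' sim <- run_simulation(sim_config(hours = 6, seed = 42))
#' sim$final$crop_health_pct
#' @export
run_simulation <- function(config, scenario = NULL, keep_world = FALSE) {
  world <- initialize_world(config, scenario)
  for (h in seq_len(config$hours)) run_iteration(world)
  trace <- as.data.frame(world$trace_mat)
  final <- if (config$hours > 0L) {
    as.list(trace[nrow(trace), ])
  } else {
    NULL
  }
  out <- list(config = config, scenario = scenario, trace = trace,
              final = final)
  if (keep_world) out$world <- world
  class(out) <- "pest_sim"
  out
}

#' @export
print.pest_sim <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<pest_sim> strategy '%s', %d x %d grid, %d h, seed %d\n",
              cfg$strategy, cfg$columns, cfg$rows, cfg$hours, cfg$seed))
  if (is.null(x$final)) {
    cat("  (zero-hour run: empty trace)\n")
    return(invisible(x))
  }
  f <- x$final
  cat(sprintf("  final: power/active station %.4g, crop health %.2f%%, alive bugs %.2f%%, pesticide/station %.4g mL\n",
              f$avg_power, f$crop_health_pct, f$alive_bugs_pct,
              f$pesticide_per_station))
  invisible(x)
}
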