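#' @title Strategy framework
#' @description A communication strategy is a pair of behavioural hooks run by
#' every sensor: a periodic hook (`live`), invoked once per sensor per hour in
#' row-major raster order, and a reactive hook (`manage`), invoked whenever the
#' sensor receives a message. Messages are delivered synchronously: the
#' receiver's reactive hook runs inline during the sender's turn, so a warning
#' sent at hour `t` takes effect at hour `t`. Reactive hooks never emit
#' messages, hence there are no cascades. Strategies interact with the world
#' only through the sensor capability set: [sense_bugs()], [fumigate()],
#' [send_message()], [broadcast_message()], [send_neighbors()] and the current
#' iteration passed to the hooks.
#' @name strategy-framework
NULL

.strategy_registry <- new.env(parent = emptyenv())
.strategy_registry$order <- character()

#' Register a communication strategy
#'
#' Third-party strategies plug into the engine by registering a periodic hook,
#' a reactive hook and an optional state initialiser.
#'
#' @param name Strategy name used in [sim_config()].
#' @param live Periodic hook `function(world, sensor, t)` called for every
#'   sensor (1-based linear id, raster order) every hour.
#' @param manage Reactive hook `function(world, sensor, msg)` called on message
#'   delivery; `msg` has fields `kind`, `sender` (linear id), `sender_x`,
#'   `sender_y` (0-based grid position) and `iteration`.
#' @param init Optional `function(world)` preparing per-sensor strategy state.
#' @param overwrite Allow replacing an existing registration.
#' @return The name, invisibly.
#' @export
register_strategy <- function(name, live, manage, init = NULL,
                              overwrite = FALSE) {
  stopifnot(is.character(name), length(name) == 1L,
            is.function(live), is.function(manage),
            is.null(init) || is.function(init))
  if (name %in% .strategy_registry$order && !overwrite) {
    stop("strategy '", name, "' is already registered", call. = FALSE)
  }
  .strategy_registry[[name]] <- list(live = live, manage = manage, init = init)
  if (!name %in% .strategy_registry$order) {
    .strategy_registry$order <- c(.strategy_registry$order, name)
  }
  invisible(name)
}

#' Names of the registered strategies
#' @return Character vector in registration order.
#' @export
strategy_names <- function() .strategy_registry$order

get_strategy <- function(name) {
  if (!name %in% .strategy_registry$order) {
    stop("unknown strategy '", name, "'; registered strategies: ",
         paste(strategy_names(), collapse = ", "), call. = FALSE)
  }
  .strategy_registry[[name]]
}

## ---- sensor capabilities ----------------------------------------------------

#' Does a sensor currently detect alive bugs?
#'
#' Detection is perfect: `TRUE` iff at least one alive bug occupies the
#' sensor's zone this hour. Dead bugs are never detected.
#'
#' @param world A world environment (see [initialize_world()]).
#' @param sensor 1-based linear sensor id.
#' @return Logical scalar.
#' @export
sense_bugs <- function(world, sensor) {
  world$zone_bug_count[sensor] > 0L
}

#' Fumigate a sensor's zone for the current hour
#'
#' Idempotent within the hour: no matter how often a strategy calls it, the
#' zone is fumigated once and exactly one dose of pesticide is metered. The
#' sensor counts as active for the hour.
#'
#' @inheritParams sense_bugs
#' @return The world, invisibly.
#' @export
fumigate <- function(world, sensor) {
  if (!world$fum_now[sensor]) {
    world$fum_now[sensor] <- TRUE
    world$pesticide[sensor] <- world$pesticide[sensor] +
      world$cfg$pesticide_per_fumigation
  }
  world$active[sensor] <- TRUE
  invisible(world)
}

#' Send a message from one sensor to another
#'
#' The engine stamps the message with the sender's grid position and the
#' current iteration, accrues the per-message energy to the sender and the
#' global ledger, counts the sender as active, and delivers synchronously to
#' the receiver's reactive hook.
#'
#' @inheritParams sense_bugs
#' @param from,to 1-based linear sensor ids; `to` must be a valid sensor other
#'   than `from`.
#' @param kind Message kind; currently `"WARN_BUGS"`.
#' @return The world, invisibly.
#' @export
send_message <- function(world, from, to, kind = "WARN_BUGS") {
  if (to < 1L || to > world$n_zones || to == from) {
    stop("send_message: invalid target sensor ", to, call. = FALSE)
  }
  world$energy <- world$energy + world$cfg$energy_per_message
  world$energy_sensor[from] <- world$energy_sensor[from] +
    world$cfg$energy_per_message
  world$msg_hour <- world$msg_hour + 1L
  world$active[from] <- TRUE
  xy <- zone_xy(from, world$columns)
  msg <- list(kind = kind, sender = from,
              sender_x = xy[[1L, "x"]], sender_y = xy[[1L, "y"]],
              iteration = world$t_cur)
  world$manage_hook(world, to, msg)
  invisible(world)
}

#' Send a message to every other sensor
#'
#' Exactly `M * N - 1` sends, one per sensor other than the sender, regardless
#' of state.
#'
#' @inheritParams send_message
#' @return The world, invisibly.
#' @export
broadcast_message <- function(world, from, kind = "WARN_BUGS") {
  for (to in seq_len(world$n_zones)) {
    if (to != from) send_message(world, from, to, kind)
  }
  invisible(world)
}

#' Send a message to the boundary-clipped 8-neighborhood
#'
#' One send per in-bounds grid cell at Chebyshev distance exactly 1 from the
#' sender: 8 for interior sensors, 5 on edges, 3 in corners.
#'
#' @inheritParams send_message
#' @return The world, invisibly.
#' @export
send_neighbors <- function(world, from, kind = "WARN_BUGS") {
  for (to in world$nbr[[from]]) send_message(world, from, to, kind)
  invisible(world)
}

## ---- local/global coordinate transforms -------------------------------------

#' Map a neighbor's global position to a 3 x 3 local index
#'
#' The local position is the target position minus the reference position,
#' shifted by `(1, 1)` so the reference sensor sits at the matrix centre.
#' Defined only for positions within Chebyshev distance 1 of the reference.
#'
#' @param target,reference Length-2 integer vectors `c(x, y)` of 0-based grid
#'   positions.
#' @return Length-2 integer vector in `{0, 1, 2}^2`.
#' @export
global_to_local <- function(target, reference) {
  off <- as.integer(target) - as.integer(reference)
  if (max(abs(off)) > 1L) {
    stop("global_to_local: target is not within Chebyshev distance 1 of reference",
         call. = FALSE)
  }
  off + 1L
}

#' Map a 3 x 3 local index back to a global position
#'
#' Inverse of [global_to_local()]: `(local - (1, 1)) + reference`.
#'
#' @param reference Length-2 integer vector `c(x, y)`, 0-based.
#' @param local Length-2 integer vector in `{0, 1, 2}^2`.
#' @return Length-2 integer vector of the global position.
#' @export
local_to_global <- function(reference, local) {
  local <- as.integer(local)
  stopifnot(all(local %in% 0:2))
  (local - 1L) + as.integer(reference)
}

# column of the flattened 3 x 3 last-warnings matrix for a local offset
local_index <- function(local) local[[1L]] + 3L * local[[2L]] + 1L

## ---- built-in strategies -----------------------------------------------------

check_warn_kind <- function(msg) {
  if (!identical(msg$kind, "WARN_BUGS")) {
    stop("unknown message kind '", msg$kind, "'", call. = FALSE)
  }
}

# Shared reactive hook of the broadcast and neighbor strategies: a warned
# sensor fumigates unconditionally and does nothing else.
warn_fumigate_manage <- function(world, sensor, msg) {
  check_warn_kind(msg)
  fumigate(world, sensor)
}

broadcast_live <- function(world, sensor, t) {
  if (sense_bugs(world, sensor)) {
    fumigate(world, sensor)
    broadcast_message(world, sensor, "WARN_BUGS")
  }
}

neighbor_live <- function(world, sensor, t) {
  if (sense_bugs(world, sensor)) {
    fumigate(world, sensor)
    send_neighbors(world, sensor, "WARN_BUGS")
  }
}

lowcost_init <- function(world) {
  # b: last own detection; W: flattened 3x3 last-warnings matrix per sensor.
  # Sentinel -Inf ("never") guarantees the first detection/warning is never
  # suppressed by the window tests.
  world$strat_b <- rep(-Inf, world$n_zones)
  world$W <- matrix(-Inf, nrow = world$n_zones, ncol = 9L)
  invisible(world)
}

#' Warn only the neighbors that have not warned recently
#'
#' Sends `WARN_BUGS` to each in-bounds neighbor whose last-warnings entry `w`
#' satisfies `t - w > d` (the sentinel "never" always does); neighbors that
#' warned within the last `d` hours are still fumigating and are skipped. The
#' recipient set is always a subset of [send_neighbors()]'s.
#'
#' @inheritParams sense_bugs
#' @param t Current iteration (hour index).
#' @return The world, invisibly.
#' @export
send_neighbors_smartly <- function(world, sensor, t) {
  d <- world$cfg$fumigation_window
  nb <- world$nbr[[sensor]]
  keep <- (t - world$W[sensor, world$nbr_loc[[sensor]]]) > d
  for (to in nb[keep]) send_message(world, sensor, to, "WARN_BUGS")
  invisible(world)
}

lowcost_live <- function(world, sensor, t) {
  d <- world$cfg$fumigation_window
  if (t - world$strat_b[sensor] <= d) {
    # inside the fumigation window opened by an earlier detection: keep
    # fumigating, never re-warn (the window test guards sending)
    fumigate(world, sensor)
  } else if (sense_bugs(world, sensor)) {
    # fresh detection: warn the neighbors that are not already fumigating,
    # open the window at t, and fumigate this very hour
    send_neighbors_smartly(world, sensor, t)
    world$strat_b[sensor] <- t
    fumigate(world, sensor)
  }
}

lowcost_manage <- function(world, sensor, msg) {
  check_warn_kind(msg)
  fumigate(world, sensor)
  loc <- global_to_local(c(msg$sender_x, msg$sender_y),
                         zone_xy(sensor, world$columns)[1L, ])
  world$W[sensor, local_index(loc)] <- msg$iteration
  invisible(world)
}

register_builtin_strategies <- function() {
  if (!"broadcast" %in% .strategy_registry$order) {
    register_strategy("broadcast", broadcast_live, warn_fumigate_manage)
    register_strategy("neighbor", neighbor_live, warn_fumigate_manage)
    register_strategy("lowcost_neighbor", lowcost_live, lowcost_manage,
                      init = lowcost_init)
  }
  invisible(NULL)
}

.onLoad <- function(libname, pkgname) {
  register_builtin_strategies()
}
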