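#' Number of bugs appearing in one hour
#'
#' Implements the nondeterministic appearance decision: with probability
#' `p_appear` an appearance event happens and the number of new bugs is drawn
#' uniformly from `{0, 1, ..., max_new_bugs}`; otherwise no bug appears.
#' Consumes one uniform draw, plus one more when the event fires.
#'
#' @param p_appear Appearance probability per hour, in `[0, 1]`.
#' @param max_new_bugs Inclusive upper bound of the uniform bug-count draw.
#' @return Integer number of bugs appearing this hour.
#' @export
spawn_count <- function(p_appear, max_new_bugs) {
  if (!is.numeric(p_appear) || length(p_appear) != 1L ||
      is.na(p_appear) || p_appear < 0 || p_appear > 1) {
    stop("invalid configuration: p_appear must be a probability in [0, 1]",
         call. = FALSE)
  }
  if (!is.numeric(max_new_bugs) || length(max_new_bugs) != 1L ||
      is.na(max_new_bugs) || max_new_bugs < 1) {
    stop("invalid configuration: max_new_bugs must be >= 1", call. = FALSE)
  }
  if (stats::runif(1L) < p_appear) {
    sample.int(as.integer(max_new_bugs) + 1L, 1L) - 1L
  } else {
    0L
  }
}

# Add `count` bugs at uniformly random zones of the grid (world mutated).
place_new_bugs <- function(world, count) {
  stopifnot(count >= 0)
  if (count == 0L) return(invisible(world))
  ids <- sample.int(world$n_zones, count, replace = TRUE)
  xy <- zone_xy(ids, world$columns)
  add_bugs(world, xy[, "x"], xy[, "y"])
  invisible(world)
}

# Register new alive bugs at given 0-based coordinates (world mutated).
add_bugs <- function(world, x, y) {
  k <- length(x)
  stopifnot(length(y) == k)
  world$bug_x <- c(world$bug_x, as.integer(x))
  world$bug_y <- c(world$bug_y, as.integer(y))
  world$bug_alive <- c(world$bug_alive, rep(TRUE, k))
  world$bug_exposure <- c(world$bug_exposure, rep(0L, k))
  world$bug_born <- c(world$bug_born, rep(world$t + 1L, k))
  invisible(world)
}

#' Clamped random-walk step of a bug
#'
#' Each coordinate is shifted independently by an integer drawn uniformly from
#' `{-1, 0, 1}` and then clamped to its own valid index range, so the result
#' stays within Chebyshev distance 1 of the input and never leaves the grid.
#'
#' @param x,y 0-based column and row of the bug (vectors of equal length).
#' @param columns,rows Grid dimensions.
#' @return A list with integer vectors `x` and `y` of the new positions.
#' @export
move_bug <- function(x, y, columns, rows) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (n == 0L) return(list(x = integer(), y = integer()))
  dx <- sample(-1:1, n, replace = TRUE)
  dy <- sample(-1:1, n, replace = TRUE)
  list(x = pmin(pmax(x + dx, 0L), columns - 1L),
       y = pmin(pmax(y + dy, 0L), rows - 1L))
}

# One hour of pesticide exposure for the alive bugs sitting in zones fumigated
# this hour; a bug dies when its cumulative exposure reaches the threshold.
apply_exposure <- function(world) {
  alive <- world$bug_alive
  if (!any(alive)) return(invisible(world))
  zone <- zone_id(world$bug_x, world$bug_y, world$columns)
  hit <- alive & world$fum_now[zone]
  if (any(hit)) {
    world$bug_exposure[hit] <- world$bug_exposure[hit] + 1L
    dead <- hit & world$bug_exposure >= world$cfg$exposure_hours_to_die
    world$bug_alive[dead] <- FALSE
  }
  invisible(world)
}

# Surviving bugs eat the crop of their zone unless the zone was fumigated in
# the previous hour; health is floored at 0.
bug_eat <- function(world) {
  alive <- world$bug_alive
  if (!any(alive)) return(invisible(world))
  zone <- zone_id(world$bug_x[alive], world$bug_y[alive], world$columns)
  counts <- tabulate(zone, nbins = world$n_zones)
  eats <- counts > 0L & !world$fum_prev
  if (any(eats)) {
    world$health[eats] <- pmax(0,
      world$health[eats] - world$cfg$eat_rate * counts[eats])
  }
  invisible(world)
}

# Hourly regrowth of every zone, capped at 100% health.
crop_grow <- function(world) {
  world$health <- pmin(100, world$health + world$cfg$grow_rate)
  invisible(world)
}
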