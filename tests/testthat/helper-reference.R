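# Straightforward reference implementation of the simulator, written
# independently of the package internals: 2-D matrices indexed [x+1, y+1],
# explicit nested loops, direct transcription of each strategy's rules.
# Supports fully scripted runs (scripted spawns, no random appearance, no
# movement), which is how the oracle-equality tests use it.

ref_simulation <- function(cfg, spawns) {
  M <- cfg$columns; N <- cfg$rows
  d <- cfg$fumigation_window
  health <- matrix(100, nrow = M, ncol = N)
  fum_now <- matrix(FALSE, M, N)
  fum_prev <- matrix(FALSE, M, N)
  pesticide <- matrix(0, M, N)
  # bugs: data frame of x, y (0-based), alive, expo
  bugs <- data.frame(x = integer(), y = integer(), alive = logical(),
                     expo = integer())
  b_last <- matrix(-Inf, M, N)                  # low-cost: last own detection
  W <- array(-Inf, dim = c(M, N, 3, 3))         # low-cost: last warnings
  power_defined <- c(); trace <- NULL
  energy <- 0

  in_bounds <- function(i, j) i >= 0 && i < M && j >= 0 && j < N

  for (t in seq_len(cfg$hours)) {
    fum_prev <- fum_now
    fum_now <- matrix(FALSE, M, N)
    active <- matrix(FALSE, M, N)
    msgs <- 0L

    due <- spawns[spawns$hour == t, , drop = FALSE]
    for (k in seq_len(nrow(due))) {
      if (due$count[k] > 0L) {
        bugs <- rbind(bugs, data.frame(x = rep(due$x[k], due$count[k]),
                                       y = rep(due$y[k], due$count[k]),
                                       alive = TRUE, expo = 0L))
      }
    }

    cnt <- matrix(0L, M, N)
    for (b in seq_len(nrow(bugs))) {
      if (bugs$alive[b]) {
        cnt[bugs$x[b] + 1L, bugs$y[b] + 1L] <-
          cnt[bugs$x[b] + 1L, bugs$y[b] + 1L] + 1L
      }
    }

    do_fumigate <- function(i, j) {
      if (!fum_now[i + 1L, j + 1L]) {
        fum_now[i + 1L, j + 1L] <<- TRUE
        pesticide[i + 1L, j + 1L] <<- pesticide[i + 1L, j + 1L] +
          cfg$pesticide_per_fumigation
      }
      active[i + 1L, j + 1L] <<- TRUE
    }
    count_send <- function(x, y) {
      msgs <<- msgs + 1L
      energy <<- energy + cfg$energy_per_message
      active[x + 1L, y + 1L] <<- TRUE
    }

    # periodic hooks in raster order (x fastest within each row y)
    for (y in 0:(N - 1L)) for (x in 0:(M - 1L)) {
      sensing <- cnt[x + 1L, y + 1L] > 0L
      if (cfg$strategy == "broadcast") {
        if (sensing) {
          do_fumigate(x, y)
          for (j in 0:(N - 1L)) for (i in 0:(M - 1L)) {
            if (i == x && j == y) next
            count_send(x, y)
            do_fumigate(i, j)      # receiver reacts: fumigate
          }
        }
      } else if (cfg$strategy == "neighbor") {
        if (sensing) {
          do_fumigate(x, y)
          for (j in (y - 1L):(y + 1L)) for (i in (x - 1L):(x + 1L)) {
            if ((i == x && j == y) || !in_bounds(i, j)) next
            count_send(x, y)
            do_fumigate(i, j)
          }
        }
      } else if (cfg$strategy == "lowcost_neighbor") {
        if (t - b_last[x + 1L, y + 1L] <= d) {
          do_fumigate(x, y)
        } else if (sensing) {
          for (j in (y - 1L):(y + 1L)) for (i in (x - 1L):(x + 1L)) {
            if ((i == x && j == y) || !in_bounds(i, j)) next
            # local position of neighbor (i, j) in the sender's W matrix
            li <- i - x + 1L; lj <- j - y + 1L
            if (t - W[x + 1L, y + 1L, li + 1L, lj + 1L] > d) {
              count_send(x, y)
              # receiver reacts: fumigate and file the warning under the
              # sender's local position in its own matrix
              do_fumigate(i, j)
              ri <- x - i + 1L; rj <- y - j + 1L
              W[i + 1L, j + 1L, ri + 1L, rj + 1L] <- t
            }
          }
          b_last[x + 1L, y + 1L] <- t
          do_fumigate(x, y)
        }
      } else {
        stop("ref_simulation: unknown strategy")
      }
    }

    # exposure and death
    for (b in seq_len(nrow(bugs))) {
      if (bugs$alive[b] && fum_now[bugs$x[b] + 1L, bugs$y[b] + 1L]) {
        bugs$expo[b] <- bugs$expo[b] + 1L
        if (bugs$expo[b] >= cfg$exposure_hours_to_die) bugs$alive[b] <- FALSE
      }
    }
    # eating (blocked only by previous-hour fumigation)
    for (b in seq_len(nrow(bugs))) {
      if (bugs$alive[b] && !fum_prev[bugs$x[b] + 1L, bugs$y[b] + 1L]) {
        i <- bugs$x[b] + 1L; j <- bugs$y[b] + 1L
        health[i, j] <- max(0, health[i, j] - cfg$eat_rate)
      }
    }
    # regrowth
    health <- pmin(health + cfg$grow_rate, 100)  # first arg keeps the dims

    n_active <- sum(active)
    if (n_active > 0L) {
      power_defined <- c(power_defined,
                         msgs * cfg$energy_per_message / n_active)
    }
    total <- nrow(bugs)
    trace <- rbind(trace, data.frame(
      iteration = t,
      avg_power = if (length(power_defined)) mean(power_defined) else 0,
      crop_health_pct = mean(health),
      alive_bugs_pct = if (total == 0L) 100 else 100 * sum(bugs$alive) / total,
      pesticide_per_station = sum(pesticide) / (M * N),
      messages_this_hour = msgs,
      active_stations = n_active,
      alive_bugs = sum(bugs$alive)
    ))
  }
  trace
}
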