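# Shared fixtures: small configurations and scripted scenarios.

tiny_cfg <- function(columns = 3L, rows = 3L, strategy = "neighbor",
                     hours = 10L, ...) {
  sim_config(columns = columns, rows = rows, strategy = strategy,
             hours = hours, initial_affected_areas = 0L, p_appear = 0,
             ...)
}

# a world with no bugs and a live current hour, for direct capability calls
scripted_world <- function(cfg, t = 1L) {
  w <- initialize_world(cfg)
  w$t_cur <- t
  w
}

spawn_df <- function(...) {
  # spawn_df(c(hour, x, y, count), ...)
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(hour = r[1], x = r[2], y = r[3], count = r[4])
  }))
}

# deterministic scripted scenario shared by the oracle-equality tests
oracle_cases <- function() {
  list(
    list(
      cfg = list(columns = 2L, rows = 2L, hours = 10L),
      spawns = spawn_df(c(1, 0, 0, 1), c(5, 1, 1, 2), c(6, 0, 1, 1))
    ),
    list(
      cfg = list(columns = 3L, rows = 3L, hours = 12L),
      spawns = spawn_df(c(1, 1, 1, 1), c(2, 0, 2, 2), c(7, 2, 0, 1),
                        c(8, 1, 2, 1))
    )
  )
}
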