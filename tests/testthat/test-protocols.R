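test_that("sense_bugs reports only alive bugs in the sensor's own zone", {
  w <- scripted_world(tiny_cfg())
  w$zone_bug_count <- integer(9)
  expect_false(sense_bugs(w, 5L))
  w$zone_bug_count[5] <- 1L
  expect_true(sense_bugs(w, 5L))
  # dead bugs never trigger detection: the per-hour count only tallies alive ones
  w2 <- scripted_world(tiny_cfg())
  add_bugs(w2, 1L, 1L)
  w2$bug_alive[1] <- FALSE
  alive <- w2$bug_alive
  w2$zone_bug_count <- if (any(alive)) {
    tabulate(zone_id(w2$bug_x[alive], w2$bug_y[alive], 3L), nbins = 9L)
  } else integer(9L)
  expect_false(sense_bugs(w2, zone_id(1L, 1L, 3L)))
})

test_that("fumigation is idempotent within the hour and meters one dose", {
  w <- scripted_world(tiny_cfg())
  fumigate(w, 5L)
  fumigate(w, 5L)
  expect_equal(w$pesticide[5], 1.0)       # q, not 2q
  expect_true(w$active[5])
  expect_equal(sum(w$pesticide), 1.0)
})

test_that("send stamps sender position and iteration, and accrues energy", {
  w <- scripted_world(tiny_cfg(strategy = "lowcost_neighbor"), t = 7L)
  east <- zone_id(2L, 1L, 3L)
  center <- zone_id(1L, 1L, 3L)
  send_message(w, from = east, to = center)
  expect_equal(w$energy, 1.0)
  expect_equal(w$msg_hour, 1L)
  expect_true(w$active[east])
  # the delivered stamp reached the receiver's last-warnings matrix:
  # east neighbor sits at local position (2, 1)
  expect_equal(w$W[center, 2L + 3L * 1L + 1L], 7)
  expect_error(send_message(w, from = east, to = east), "invalid target")
  expect_error(send_message(w, from = east, to = 100L), "invalid target")
})

test_that("broadcast reaches exactly all other sensors", {
  counts <- list(c(10L, 16L, 159L), c(1L, 1L, 0L), c(2L, 2L, 3L))
  for (cc in counts) {
    w <- scripted_world(tiny_cfg(columns = cc[1], rows = cc[2]))
    broadcast_message(w, 1L)
    expect_equal(w$msg_hour, cc[3])
    expect_equal(w$energy, cc[3] * 1.0)
  }
})

test_that("neighbor sends cover the boundary-clipped 8-neighborhood", {
  w <- scripted_world(tiny_cfg(columns = 10L, rows = 16L))
  cases <- list(list(zone_id(0L, 0L, 10L), 3L),    # corner
                list(zone_id(5L, 0L, 10L), 5L),    # edge
                list(zone_id(5L, 5L, 10L), 8L))    # interior
  for (cs in cases) {
    w$msg_hour <- 0L
    send_neighbors(w, cs[[1]])
    expect_equal(w$msg_hour, cs[[2]])
    expect_setequal(w$nbr[[cs[[1]]]], which(w$fum_now))  # receivers fumigated
    w$fum_now[] <- FALSE
  }
})

test_that("local/global transforms are mutually inverse over all 9 offsets", {
  R <- c(4L, 4L)
  expect_equal(global_to_local(R, R), c(1L, 1L))
  expect_equal(global_to_local(c(5L, 4L), R), c(2L, 1L))
  expect_equal(local_to_global(R, c(1L, 1L)), R)
  expect_equal(local_to_global(R, c(2L, 1L)), c(5L, 4L))
  for (dx in -1:1) for (dy in -1:1) {
    G <- R + c(dx, dy)
    expect_equal(local_to_global(R, global_to_local(G, R)), G)
  }
  expect_error(global_to_local(c(6L, 4L), R), "Chebyshev")
})

test_that("a warned sensor fumigates even with no bugs of its own", {
  w <- scripted_world(tiny_cfg(strategy = "broadcast"), t = 3L)
  center <- zone_id(1L, 1L, 3L)
  send_message(w, from = 1L, to = center)
  expect_true(w$fum_now[center])
  send_message(w, from = 1L, to = center)   # warned twice: still one dose
  expect_equal(w$pesticide[center], 1.0)
  msg <- list(kind = "UNKNOWN", sender = 1L, sender_x = 0L, sender_y = 0L,
              iteration = 3L)
  expect_error(w$manage_hook(w, center, msg), "unknown message kind")
})

test_that("low-cost warnings update W with the later hour on repeats", {
  w <- scripted_world(tiny_cfg(strategy = "lowcost_neighbor"), t = 7L)
  east <- zone_id(2L, 1L, 3L)
  center <- zone_id(1L, 1L, 3L)
  send_message(w, east, center)
  w$t_cur <- 9L
  send_message(w, east, center)
  expect_equal(w$W[center, 2L + 3L * 1L + 1L], 9)
  expect_true(w$fum_now[center])            # receiver fumigates the current hour
})

test_that("smart sends suppress recent warners and stay a subset of the neighborhood", {
  cfg <- tiny_cfg(strategy = "lowcost_neighbor", fumigation_window = 3L)
  w <- scripted_world(cfg, t = 10L)
  center <- zone_id(1L, 1L, 3L)

  # all W at the "never" sentinel: identical to send_neighbors
  send_neighbors_smartly(w, center, 10L)
  expect_equal(w$msg_hour, 8L)
  expect_setequal(which(w$fum_now), w$nbr[[center]])

  # east neighbor warned at t - 1: east omitted, the other 7 sent
  w2 <- scripted_world(cfg, t = 10L)
  east <- zone_id(2L, 1L, 3L)
  w2$W[center, 2L + 3L * 1L + 1L] <- 9
  send_neighbors_smartly(w2, center, 10L)
  expect_equal(w2$msg_hour, 7L)
  expect_false(east %in% which(w2$fum_now))

  # all 8 neighbors warned within d: no sends at all
  w3 <- scripted_world(cfg, t = 10L)
  w3$W[center, ] <- 8
  send_neighbors_smartly(w3, center, 10L)
  expect_equal(w3$msg_hour, 0L)

  # property: under random W states the recipients are always a subset of the
  # plain neighborhood, which is a subset of all sensors minus the sender
  set.seed(99)
  for (k in 1:25) {
    wk <- scripted_world(cfg, t = 10L)
    s <- sample.int(9L, 1L)
    wk$W[s, ] <- sample(c(-Inf, 5:10), 9L, replace = TRUE)
    send_neighbors_smartly(wk, s, 10L)
    rec <- which(wk$fum_now)
    expect_true(all(rec %in% wk$nbr[[s]]))
    expect_false(s %in% rec)
  }
})

test_that("the low-cost window keeps a detecting sensor fumigating d+1 hours", {
  # one bug dropped at the center of a 3x3 grid at hour 10; no movement, no
  # random appearance; d = 3 => the center fumigates at hours 10..13 only
  cfg <- tiny_cfg(strategy = "lowcost_neighbor", hours = 16L,
                  fumigation_window = 3L)
  sc <- scenario_script(spawns = spawn_df(c(10, 1, 1, 1)),
                        disable_movement = TRUE, disable_appearance = TRUE)
  sim <- run_simulation(cfg, sc, keep_world = TRUE)
  tr <- sim$trace
  expect_equal(tr$messages_this_hour, c(rep(0L, 9), 8L, rep(0L, 6)))
  # 9 zones dosed at hour 10, then one more dose per window hour 11..13
  expect_equal(tr$pesticide_per_station * 9,
               c(rep(0, 9), 9, 10, 11, 12, 12, 12, 12))
  # bugs persisting inside the window never trigger re-warning or a b reset
  expect_equal(sim$world$strat_b[zone_id(1L, 1L, 3L)], 10)
})

test_that("each strategy's periodic hook composes detection, fumigation and sends", {
  # broadcast: one detector on 10x16 => 159 messages, all 160 zones fumigated
  cfg_b <- tiny_cfg(columns = 10L, rows = 16L, strategy = "broadcast",
                    hours = 1L)
  sc <- scenario_script(spawns = spawn_df(c(1, 4, 7, 1)),
                        disable_movement = TRUE, disable_appearance = TRUE)
  tr <- run_simulation(cfg_b, sc)$trace
  expect_equal(tr$messages_this_hour, 159L)
  expect_equal(tr$active_stations, 160L)
  expect_equal(tr$pesticide_per_station, 1.0)

  # two detectors each broadcast: 318 messages
  sc2 <- scenario_script(spawns = spawn_df(c(1, 0, 0, 1), c(1, 9, 15, 1)),
                         disable_movement = TRUE, disable_appearance = TRUE)
  tr2 <- run_simulation(cfg_b, sc2)$trace
  expect_equal(tr2$messages_this_hour, 318L)

  # neighbor: interior detector => 8 messages, 9 fumigated zones
  cfg_n <- tiny_cfg(columns = 10L, rows = 16L, strategy = "neighbor",
                    hours = 1L)
  tr3 <- run_simulation(cfg_n, sc)$trace
  expect_equal(tr3$messages_this_hour, 8L)
  expect_equal(tr3$active_stations, 9L)
  expect_equal(tr3$pesticide_per_station * 160, 9)

  # neighbor: corner detector => 3 messages, 4 fumigated zones
  sc4 <- scenario_script(spawns = spawn_df(c(1, 0, 0, 1)),
                         disable_movement = TRUE, disable_appearance = TRUE)
  tr4 <- run_simulation(cfg_n, sc4)$trace
  expect_equal(tr4$messages_this_hour, 3L)
  expect_equal(tr4$pesticide_per_station * 160, 4)

  # no detection anywhere: no messages, no pesticide
  sc0 <- scenario_script(disable_movement = TRUE, disable_appearance = TRUE)
  tr0 <- run_simulation(cfg_b, sc0)$trace
  expect_true(all(tr0$messages_this_hour == 0L))
  expect_true(all(tr0$pesticide_per_station == 0))
})

test_that("third-party strategies can be registered and run", {
  nm <- "test_passive"
  if (!nm %in% strategy_names()) {
    register_strategy(nm,
                      live = function(world, sensor, t) NULL,
                      manage = function(world, sensor, msg) NULL)
  }
  expect_true(nm %in% strategy_names())
  cfg <- tiny_cfg(strategy = nm, hours = 3L)
  sc <- scenario_script(spawns = spawn_df(c(1, 1, 1, 1)),
                        disable_movement = TRUE, disable_appearance = TRUE)
  tr <- run_simulation(cfg, sc)$trace
  expect_true(all(tr$messages_this_hour == 0L))   # passive: nothing happens
  expect_true(all(tr$pesticide_per_station == 0))
  expect_equal(tr$alive_bugs[3], 1L)              # and the bug survives
})
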