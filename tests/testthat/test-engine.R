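test_that("placement respects walls, bodies and determinism", {
  cfg <- staghunt_config()
  w <- place_agents(cfg, make_rng(3, "place"))
  r <- cfg$body$diameter / 2
  expect_equal(nrow(w$agents), 20L)
  expect_true(all(w$agents$x >= r & w$agents$x <= cfg$arena$width - r))
  expect_true(all(w$agents$y >= r & w$agents$y <= cfg$arena$height - r))
  d <- as.matrix(stats::dist(cbind(w$agents$x, w$agents$y)))
  diag(d) <- Inf
  expect_true(all(d >= cfg$body$diameter - 1e-9))
  w2 <- place_agents(cfg, make_rng(3, "place"))
  expect_identical(w$agents, w2$agents)
  expect_error(place_agents(tiny_config(n_hares = 200L, n_stags = 200L,
                                        arena = 100), make_rng(1, "x")),
               "too crowded")
})

test_that("placed coordinates are uniform over arena quadrants", {
  cfg <- tiny_config(n_hares = 0L, n_stags = 0L, arena = 800)
  rng <- make_rng(11, "uniformity")
  n <- 10000
  xs <- numeric(n)
  ys <- numeric(n)
  for (i in seq_len(n)) {
    w <- place_agents(cfg, rng)
    xs[i] <- w$agents$x[1]
    ys[i] <- w$agents$y[1]
  }
  quadrant <- 1 + (xs > 400) + 2 * (ys > 400)
  p <- stats::chisq.test(tabulate(quadrant, 4))$p.value
  expect_gt(p, 0.01)
})

test_that("differential-drive kinematics match the closed form", {
  cfg <- staghunt_config()
  # equal wheels: straight motion along the heading
  expect_equal(step_hunter(c(100, 100, 0), c(1, 1), cfg), c(101, 100, 0))
  # opposite wheels: pure rotation by 2 v / diameter
  p <- step_hunter(c(100, 100, 0.3), c(-0.7, 0.7), cfg)
  expect_equal(p[1:2], c(100, 100))
  expect_equal(p[3], 0.3 + 2 * 0.7 / 14)
  # motion into a wall clamps the centre at one body radius
  p <- step_hunter(c(8, 400, pi), c(2, 2), cfg)
  expect_equal(p[1], 7)
  expect_equal(p[2], 400)
  expect_equal(p[3], pi)
})

test_that("collision resolution projects to exact contact", {
  cfg <- staghunt_config()
  w <- world_state(tibble::tibble(kind = c("hunter", "hunter"),
                                  x = c(400, 410), y = c(400, 400),
                                  heading = c(0, 0)), cfg)
  w2 <- resolve_collisions(w, moving_id = 1)
  expect_equal(w2$agents$x[1], 410 - 14)   # pushed to centre distance 14
  expect_equal(w2$agents$x[2], 410)        # stationary agent never moves
  # corner trap: both axis clamps leave the centre at (radius, radius)
  w3 <- world_state(tibble::tibble(kind = c("hunter", "hunter"),
                                   x = c(2, 400), y = c(-3, 400),
                                   heading = c(0, 0)), cfg)
  w4 <- resolve_collisions(w3, moving_id = 1)
  expect_equal(c(w4$agents$x[1], w4$agents$y[1]), c(7, 7))
})

test_that("driving into the corner settles at one radius from both walls", {
  cfg <- staghunt_config()
  w <- build_fixture("corner-trap", cfg)
  g <- stationary_genome(cfg)
  # a genome whose forward drive is maximal: all-positive output weights
  # would still depend on inputs, so instead step the surface ops directly
  pose <- c(w$agents$x[1], w$agents$y[1], w$agents$heading[1])
  for (i in 1:50) pose <- step_hunter(pose, c(2, 2), cfg, w, 1)
  expect_equal(pose[1:2], c(7, 7))
})

test_that("cast_ray matches closed-form geometry on crafted scenes", {
  cfg <- staghunt_config()
  # disk dead ahead: distance = centre distance - radius
  w <- world_state(tibble::tibble(kind = c("hunter", "hunter", "hare"),
                                  x = c(200, 700, 300), y = c(200, 700, 200),
                                  heading = c(0, 0, NA)), cfg)
  hit <- cast_ray(c(200, 200), 0, w, exclude_id = 1)
  expect_equal(hit$kind, "hare")
  expect_equal(hit$distance, 100 - 7)
  # agent-free direction terminates on the wall
  miss <- cast_ray(c(200, 200), pi, w, exclude_id = 1)
  expect_equal(miss$kind, "none")
  expect_equal(miss$distance, 200)
  # two disks on the same ray: the nearer one wins
  w2 <- world_state(tibble::tibble(kind = c("hunter", "hunter", "hare", "stag"),
                                   x = c(100, 700, 150, 180),
                                   y = c(100, 700, 100, 100),
                                   heading = c(0, 0, NA, NA)), cfg)
  hit2 <- cast_ray(c(100, 100), 0, w2, exclude_id = 1)
  expect_equal(hit2$kind, "hare")
  expect_equal(hit2$distance, 50 - 7)
})

test_that("cast_ray agrees with the exhaustive oracle on random scenes", {
  cfg <- staghunt_config()
  rng <- make_rng(5, "scenes")
  for (i in seq_len(1000)) {
    n <- 2 + floor(rng_runif(rng, 1) * 8)
    agents <- tibble::tibble(
      kind = c("hunter", "hunter",
               sample(c("hare", "stag"), n - 2, replace = TRUE)),
      x = 7 + rng_runif(rng, n) * (800 - 14),
      y = 7 + rng_runif(rng, n) * (800 - 14),
      heading = c(0, 0, rep(NA_real_, n - 2)))
    w <- world_state(agents, cfg)
    angle <- rng_runif(rng, 1) * 2 * pi
    got <- cast_ray(c(agents$x[1], agents$y[1]), angle, w, exclude_id = 1)
    want <- oracle_cast_ray(agents$x[1], agents$y[1], angle, agents, 7,
                            800, 800, exclude = 1L)
    expect_identical(got$kind, want$kind)
    expect_lt(abs(got$distance - want$distance), 1e-6)
  }
})

test_that("capture counters follow the consecutive-presence rule", {
  cfg <- tiny_config(n_hares = 1L, n_stags = 0L, capture_steps = 800L)
  rng <- make_rng(2, "caps")
  in_range <- function(w) {
    w$agents$x[1] <- w$agents$x[3] - 20
    w$agents$y[1] <- w$agents$y[3]
    w
  }
  out_of_range <- function(w) {
    w$agents$x[1] <- w$agents$x[3] - 200
    w
  }
  w <- world_state(tibble::tibble(kind = c("hunter", "hunter", "hare"),
                                  x = c(130, 280, 150), y = c(150, 20, 150),
                                  heading = c(0, 0, NA)), cfg)
  # one hunter in range, alone throughout: solitary capture at step 800
  for (i in 1:799) w <- update_captures(w, cfg$rewards, rng)$world
  expect_equal(w$counters[1], 799L)
  upd <- update_captures(w, cfg$rewards, rng)
  expect_equal(nrow(upd$events), 1L)
  expect_false(upd$events$cooperative)
  expect_equal(upd$events$reward, 50)
  # leaving range resets the counter to zero
  w2 <- world_state(tibble::tibble(kind = c("hunter", "hunter", "hare"),
                                   x = c(130, 280, 150), y = c(150, 20, 150),
                                   heading = c(0, 0, NA)), cfg)
  for (i in 1:400) w2 <- update_captures(w2, cfg$rewards, rng)$world
  w2 <- update_captures(out_of_range(w2), cfg$rewards, rng)$world
  expect_equal(w2$counters[1], 0L)
})

test_that("a partner arriving at the final step makes the hunt cooperative", {
  cfg <- staghunt_config(evo = evo_config(n_hares = 0L, n_stags = 1L))
  rng <- make_rng(4, "caps")
  w <- world_state(tibble::tibble(kind = c("hunter", "hunter", "stag"),
                                  x = c(380, 700, 400), y = c(400, 700, 400),
                                  heading = c(0, 0, NA)), cfg)
  for (i in 1:799) w <- update_captures(w, cfg$rewards, rng)$world
  # second hunter steps into catching distance exactly at the 800th step
  w$agents$x[2] <- 420
  w$agents$y[2] <- 400
  upd <- update_captures(w, cfg$rewards, rng)
  expect_equal(nrow(upd$events), 1L)
  expect_true(upd$events$cooperative)
  expect_equal(upd$events$reward, 500)
  expect_true(upd$events$hunter1 && upd$events$hunter2)
})

test_that("episodes are deterministic and conserve the payoff ledger", {
  cfg <- desk_profile(staghunt_config())
  arch <- cfg$controller
  g1 <- random_genome(arch, make_rng(21, "g1"))
  g2 <- random_genome(arch, make_rng(22, "g2"))
  ep <- run_episode(g1, g2, cfg, rng = 9)
  ep2 <- run_episode(g1, g2, cfg, rng = 9)
  expect_identical(ep$payoff, ep2$payoff)
  expect_identical(ep$events, ep2$events)
  expect_identical(ep$final, ep2$final)
  # ledger: each hunter's payoff equals the sum of its event rewards
  for (i in 1:20) {
    e <- run_episode(random_genome(arch, make_rng(i, "a")),
                     random_genome(arch, make_rng(i, "b")), cfg, rng = i)
    expect_equal(e$payoff[1], sum(e$events$reward[e$events$hunter1]))
    expect_equal(e$payoff[2], sum(e$events$reward[e$events$hunter2]))
    counts <- table(factor(e$events$prey_kind, c("hare", "stag")),
                    factor(e$events$cooperative, c(FALSE, TRUE)))
    expect_equal(unname(e$counts[["hares"]]), sum(counts["hare", ]))
    expect_equal(unname(e$counts[["coop_stags"]]), counts["stag", "TRUE"])
    expect_equal(unname(e$counts[["solo_stags"]]), counts["stag", "FALSE"])
  }
})

test_that("prey count and composition are conserved across an episode", {
  cfg <- desk_profile(staghunt_config())
  arch <- cfg$controller
  e <- run_episode(random_genome(arch, make_rng(31, "a")),
                   random_genome(arch, make_rng(32, "b")), cfg, rng = 1)
  expect_equal(table(e$final$kind), table(e$initial$kind))
  expect_equal(sum(e$final$kind == "hare"), cfg$evo$n_hares)
  expect_equal(sum(e$final$kind == "stag"), cfg$evo$n_stags)
})

test_that("an episode with no prey yields zero payoff and no events", {
  cfg <- tiny_config(n_hares = 0L, n_stags = 0L)
  g <- stationary_genome(cfg)
  e <- run_episode(g, g, cfg, rng = 1)
  expect_equal(e$payoff, c(0, 0))
  expect_equal(nrow(e$events), 0L)
})

test_that("hunters never interpenetrate or leave the arena", {
  cfg <- desk_profile(staghunt_config())
  arch <- cfg$controller
  r <- cfg$body$diameter / 2
  for (i in 1:5) {
    e <- run_episode(random_genome(arch, make_rng(40 + i, "a")),
                     random_genome(arch, make_rng(50 + i, "b")),
                     cfg, rng = i, record_trajectories = TRUE)
    tr <- tidyr::pivot_wider(e$trajectories, id_cols = "step",
                             names_from = "hunter", values_from = c("x", "y"))
    gap <- sqrt((tr$x_1 - tr$x_2)^2 + (tr$y_1 - tr$y_2)^2)
    expect_true(all(gap >= cfg$body$diameter - 1e-9))
    expect_true(all(e$trajectories$x >= r - 1e-9 &
                      e$trajectories$x <= cfg$arena$width - r + 1e-9))
    expect_true(all(e$trajectories$y >= r - 1e-9 &
                      e$trajectories$y <= cfg$arena$height - r + 1e-9))
    # final state: all pairwise distances at contact or more
    d <- as.matrix(stats::dist(cbind(e$final$x, e$final$y)))
    diag(d) <- Inf
    expect_true(all(d >= cfg$body$diameter - 1e-9))
  }
})

test_that("the C++ episode loop matches the R module-surface loop", {
  cfg <- tiny_config(n_hares = 1L, n_stags = 1L, episode_steps = 300L,
                     capture_steps = 1000L)  # no captures: geometry only
  arch <- cfg$controller
  g1 <- random_genome(arch, make_rng(61, "a"))
  g2 <- random_genome(arch, make_rng(62, "b"))
  w <- world_state(tibble::tibble(
    kind = c("hunter", "hunter", "hare", "stag"),
    x = c(100, 200, 60, 240), y = c(150, 150, 60, 240),
    heading = c(0.4, 2.5, NA, NA)), cfg)
  cpp <- run_episode(g1, g2, cfg, rng = 1, record_trajectories = TRUE,
                     init_world = w)
  ref <- r_episode_loop(g1, g2, w, cfg$evo$episode_steps)
  tr <- tidyr::pivot_wider(cpp$trajectories, id_cols = "step",
                           names_from = "hunter",
                           values_from = c("x", "y", "heading"))
  expect_equal(as.matrix(tr[, c("x_1", "x_2", "y_1", "y_2",
                                "heading_1", "heading_2")]),
               ref$traj, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("flanked prey produce the expected capture events end to end", {
  cfg <- tiny_config(n_hares = 1L, n_stags = 0L, episode_steps = 205L,
                     capture_steps = 200L)
  g <- stationary_genome(cfg)
  w <- build_fixture("two-hunters-flanking-prey", cfg)
  e <- run_episode(g, g, cfg, rng = 1, init_world = w)
  expect_equal(nrow(e$events), 1L)
  expect_equal(e$events$time, 200L)
  expect_true(e$events$cooperative)
  expect_equal(e$payoff, c(50, 50))
  # same geometry around a stag: full cooperative reward for both
  ws <- build_fixture("two-hunters-flanking-stag", cfg)
  es <- run_episode(g, g, cfg, rng = 1, init_world = ws)
  expect_equal(es$payoff, c(500, 500))
  expect_equal(unname(es$counts[["coop_stags"]]), 1L)
  # a single hunter in range: solitary hunt, stag pays nothing
  wh <- build_fixture("one-hunter-near-hare", cfg)
  eh <- run_episode(g, g, cfg, rng = 1, init_world = wh)
  expect_equal(eh$payoff, c(50, 0))
  expect_false(eh$events$cooperative)
})
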