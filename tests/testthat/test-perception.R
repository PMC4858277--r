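test_that("the input vector has the documented layout and range", {
  cfg <- staghunt_config()
  w <- place_agents(cfg, make_rng(1, "w"))
  v <- build_input_vector(w, 1)
  expect_length(v, 61)
  expect_equal(v[61], 1)  # bias input always 1
  expect_true(all(v >= 0 & v <= 1))
  # a hunter alone at the arena centre: every proximity sensor silent
  w2 <- world_state(tibble::tibble(kind = c("hunter", "hunter"),
                                   x = c(400, 700), y = c(400, 700),
                                   heading = c(1.1, 0)), cfg)
  expect_equal(build_input_vector(w2, 1)[1:12], rep(0, 12))
})

test_that("proximity activation is linear in surface distance", {
  cfg <- staghunt_config()
  place_at <- function(gap) {
    # obstacle surface `gap` units from the hunter's surface, dead ahead
    world_state(tibble::tibble(kind = c("hunter", "hunter", "hare"),
                               x = c(400, 700, 400 + 14 + gap),
                               y = c(400, 700, 400),
                               heading = c(0, 0, NA)), cfg)
  }
  expect_equal(proximity_activation(place_at(0), 1, 1), 1)
  expect_equal(proximity_activation(place_at(14), 1, 1), 0.5)
  expect_equal(proximity_activation(place_at(30), 1, 1), 0)
  # sensors detect walls too: surface 14 from the wall, sensor 1 aimed at it
  ww <- world_state(tibble::tibble(kind = c("hunter", "hunter"),
                                   x = c(800 - 7 - 14, 400),
                                   y = c(400, 700),
                                   heading = c(0, 0)), cfg)
  expect_equal(proximity_activation(ww, 1, 1), 0.5)
})

test_that("camera rays encode type, proximity and presence", {
  cfg <- staghunt_config()
  diag_len <- sqrt(800^2 + 800^2)
  # wall hit: no type bits, no presence, wall proximity carried
  w <- world_state(tibble::tibble(kind = c("hunter", "hunter"),
                                  x = c(400, 40), y = c(400, 40),
                                  heading = c(0, 0)), cfg)
  for (k in 1:12) {
    quad <- camera_ray_values(w, 1, k)
    expect_equal(unname(quad[c(1, 2, 4)]), c(0, 0, 0))
    expect_gt(quad[3], 0)
  }
  # a stag dead ahead: both type bits set, proximity from the closed form
  offs <- camera_ray_offsets(cfg$body)
  wstag <- world_state(tibble::tibble(kind = c("hunter", "hunter", "stag"),
                                      x = c(100, 700, 100 + 300), y = c(400, 40, 400),
                                      heading = c(-offs[6], 0, NA)), cfg)
  # heading cancels ray 6's offset so that ray aims exactly at the centre
  quad <- camera_ray_values(wstag, 1, 6)
  expect_equal(unname(quad), c(1, 1, 1 - (300 - 7) / diag_len, 1))
  # point-blank partner hunter: type (0,1), proximity near 1, presence 1
  wh <- world_state(tibble::tibble(kind = c("hunter", "hunter"),
                                   x = c(400, 414.000001), y = c(400, 400),
                                   heading = c(-offs[6], 0)), cfg)
  quadh <- camera_ray_values(wh, 1, 6)
  expect_equal(unname(quadh[c(1, 2, 4)]), c(0, 1, 1))
  expect_gt(quadh[3], 1 - 8 / diag_len)
  # a stag whose surface sits at half the arena diagonal: proximity 0.5
  whalf <- world_state(tibble::tibble(kind = c("hunter", "hunter", "stag"),
                                      x = c(50, 700, 50 + diag_len / 2 + 7),
                                      y = c(400, 40, 400),
                                      heading = c(-offs[6], 0, NA)), cfg)
  expect_equal(unname(camera_ray_values(whalf, 1, 6)),
               c(1, 1, 0.5, 1), tolerance = 1e-12)
  # a hare: type (1, 0)
  whare <- world_state(tibble::tibble(kind = c("hunter", "hunter", "hare"),
                                      x = c(100, 700, 200), y = c(400, 40, 400),
                                      heading = c(-offs[6], 0, NA)), cfg)
  expect_equal(unname(camera_ray_values(whare, 1, 6)[1:2]), c(1, 0))
})

test_that("fixture: the central camera rays see the stag 50 units ahead", {
  cfg <- staghunt_config()
  w <- build_fixture("hunter-facing-stag-at-50", cfg)
  offs <- camera_ray_offsets(cfg$body)
  diag_len <- sqrt(800^2 + 800^2)
  for (k in 6:7) {
    quad <- camera_ray_values(w, 1, k)
    # closed-form intersection of the off-axis ray with the stag disk
    want_d <- 50 * cos(offs[k]) - sqrt(49 - (50 * sin(offs[k]))^2)
    expect_equal(unname(quad),
                 c(1, 1, 1 - want_d / diag_len, 1), tolerance = 1e-9)
  }
})

test_that("camera type bits always match the exhaustive ray oracle", {
  cfg <- staghunt_config()
  rng <- make_rng(8, "camscenes")
  offs <- camera_ray_offsets(cfg$body)
  bits_for <- c(none = "00", hunter = "01", hare = "10", stag = "11")
  for (i in 1:200) {
    n <- 3 + floor(rng_runif(rng, 1) * 6)
    agents <- tibble::tibble(
      kind = c("hunter", "hunter",
               sample(c("hare", "stag"), n - 2, replace = TRUE)),
      x = 7 + rng_runif(rng, n) * (800 - 14),
      y = 7 + rng_runif(rng, n) * (800 - 14),
      heading = c(rng_runif(rng, 2) * 2 * pi, rep(NA_real_, n - 2)))
    w <- world_state(agents, cfg)
    k <- 1 + floor(rng_runif(rng, 1) * 12)
    quad <- camera_ray_values(w, 1, k)
    want <- oracle_cast_ray(agents$x[1], agents$y[1],
                            agents$heading[1] + offs[k], agents, 7,
                            800, 800, exclude = 1L)
    expect_equal(paste0(quad[1], quad[2]), unname(bits_for[want$kind]))
    expect_equal(unname(quad[4]), as.numeric(want$kind != "none"))
  }
})

test_that("perception is equivariant under global rotation", {
  # Scenes built so that no wall is ever the nearest hit: a dense ring of
  # prey surrounds the hunter inside the camera cone and within proximity
  # range, so rotating the whole scene about the hunter must leave all 61
  # inputs unchanged.
  cfg <- staghunt_config()
  rng <- make_rng(13, "rot")
  for (rep in 1:20) {
    base_heading <- rng_runif(rng, 1) * 2 * pi
    # ring of 14 agents at radius 22 (inside proximity reach) plus a far
    # ring blocking every camera ray
    ring1 <- seq(0, 2 * pi, length.out = 15)[-15]
    ring2 <- ring1 + 0.1
    kinds <- sample(c("hare", "stag"), 28, replace = TRUE)
    mk_world <- function(rot) {
      a1 <- ring1 + rot
      a2 <- ring2 + rot
      world_state(tibble::tibble(
        kind = c("hunter", "hunter", kinds[1:14], kinds[15:28]),
        x = c(400, 400 + 60 * cos(0.3 + rot), 400 + 22 * cos(a1),
              400 + 48 * cos(a2)),
        y = c(400, 400 + 60 * sin(0.3 + rot), 400 + 22 * sin(a1),
              400 + 48 * sin(a2)),
        heading = c(base_heading + rot, 0, rep(NA_real_, 28))), cfg)
    }
    rot <- rng_runif(rng, 1) * 2 * pi
    v0 <- build_input_vector(mk_world(0), 1)
    v1 <- build_input_vector(mk_world(rot), 1)
    expect_equal(v1, v0, tolerance = 1e-9)
    # every camera ray is blocked by an agent: full presence
    expect_equal(v0[12 + 4 * (0:11) + 4], rep(1, 12))
  }
})
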