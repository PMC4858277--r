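kind_levels <- c("hunter", "hare", "stag")

kind_to_code <- function(kind) match(kind, kind_levels) - 1L

code_to_kind <- function(code) kind_levels[code + 1L]

# Flat configuration list handed to the C++ engine.
cpp_config <- function(config) {
  stopifnot(inherits(config, "staghunt_config"))
  list(arena_w = config$arena$width,
       arena_h = config$arena$height,
       diameter = config$body$diameter,
       n_proximity = config$body$n_proximity,
       proximity_range = config$body$proximity_range,
       n_camera = config$body$n_camera_rays,
       camera_fov_rad = config$body$camera_fov * pi / 180,
       v_max = config$body$v_max,
       w_max = config$controller$w_max,
       n_hidden = config$controller$n_hidden,
       n_outputs = config$controller$n_outputs,
       episode_steps = config$evo$episode_steps,
       capture_steps = config$evo$capture_steps,
       catch_distance = config$evo$catch_distance,
       n_hares = config$evo$n_hares,
       n_stags = config$evo$n_stags,
       rewards = c(config$rewards$hare_solo, config$rewards$hare_coop,
                   config$rewards$stag_solo, config$rewards$stag_coop),
       cumulative_capture = config$evo$cumulative_capture)
}

#' Construct a world state
#'
#' A world holds the arena, the poses of the two hunters and all prey, and
#' one capture counter per prey. Agents are solid disks; prey never move.
#'
#' @param agents A data frame with columns `kind` (`"hunter"`, `"hare"` or
#'   `"stag"`), `x`, `y` and `heading` (radians; `NA` for prey). The two
#'   hunters must come first.
#' @param config A [staghunt_config()] providing arena and body geometry.
#' @return A list of class `world_state` with elements `agents` (a tibble
#'   gaining an `id` column), `counters`, `step` and the configuration.
#' @export
world_state <- function(agents, config = staghunt_config()) {
  agents <- tibble::as_tibble(agents)
  stopifnot(all(c("kind", "x", "y") %in% names(agents)))
  if (!"heading" %in% names(agents)) agents$heading <- NA_real_
  if (nrow(agents) < 2 || any(agents$kind[1:2] != "hunter")) {
    stop("a world needs its two hunters in rows 1 and 2", call. = FALSE)
  }
  if (any(!agents$kind %in% kind_levels)) {
    stop("agent kind must be one of: ", paste(kind_levels, collapse = ", "),
         call. = FALSE)
  }
  agents <- dplyr::mutate(agents, id = dplyr::row_number(),
                          .before = 1)
  n_prey <- nrow(agents) - 2L
  structure(list(agents = agents,
                 counters = integer(n_prey),
                 step = 0L,
                 config = config),
            class = "world_state")
}

#' @export
print.world_state <- function(x, ...) {
  cat("<world_state step=", x$step, ">\n", sep = "")
  print(x$agents)
  invisible(x)
}

#' Place hunters and prey uniformly at random
#'
#' Positions are rejection-sampled uniformly over the arena interior so
#' that no body overlaps another and every centre stays at least one body
#' radius from each wall; hunter headings are uniform on `[0, 2*pi)`. The
#' same sampler is used to respawn captured prey.
#'
#' @param config A [staghunt_config()].
#' @param rng A [make_rng()] stream (or an integer seed).
#' @return A [world_state()] with 2 hunters, then `n_hares` hares, then
#'   `n_stags` stags.
#' @export
place_agents <- function(config, rng) {
  rng <- as_rng(rng, "place")
  n_prey <- config$evo$n_hares + config$evo$n_stags
  kinds <- c("hunter", "hunter",
             rep("hare", config$evo$n_hares),
             rep("stag", config$evo$n_stags))
  n <- length(kinds)
  xs <- numeric(n)
  ys <- numeric(n)
  radius <- config$body$diameter / 2
  for (i in seq_len(n)) {
    pos <- sample_free_position(config, xs[seq_len(i - 1)],
                                ys[seq_len(i - 1)], rng)
    xs[i] <- pos[1]
    ys[i] <- pos[2]
  }
  headings <- c(rng_runif(rng, 2) * 2 * pi, rep(NA_real_, n_prey))
  world_state(tibble::tibble(kind = kinds, x = xs, y = ys,
                             heading = headings),
              config)
}

sample_free_position <- function(config, xs, ys, rng, max_tries = 10000L) {
  radius <- config$body$diameter / 2
  diam2 <- config$body$diameter^2
  for (try in seq_len(max_tries)) {
    u <- rng_runif(rng, 2)
    x <- radius + u[1] * (config$arena$width - 2 * radius)
    y <- radius + u[2] * (config$arena$height - 2 * radius)
    if (length(xs) == 0 || all((x - xs)^2 + (y - ys)^2 >= diam2)) {
      return(c(x, y))
    }
  }
  stop("agent placement failed: arena too crowded", call. = FALSE)
}

#' Differential-drive kinematics for one hunter step
#'
#' The two wheel speeds set the turn first and the advance second:
#' `heading' = heading + (v_right - v_left) / wheel_base` with the wheel
#' base equal to the body diameter, then the centre advances by the mean
#' wheel speed along the new heading. If `world` is supplied, collisions
#' with walls and other agents are then resolved (the moved hunter is
#' pushed back; nothing else moves).
#'
#' @param pose Numeric `c(x, y, heading)`.
#' @param wheel_speeds Numeric `c(v_left, v_right)` in length-units per
#'   step; magnitudes are capped at the body's `v_max`.
#' @param config A [staghunt_config()].
#' @param world Optional [world_state()] whose agents (other than
#'   `hunter_id`) act as obstacles.
#' @param hunter_id Row index of the moving hunter in `world`.
#' @return The new pose `c(x, y, heading)`.
#' @export
step_hunter <- function(pose, wheel_speeds, config = staghunt_config(),
                        world = NULL, hunter_id = 1L) {
  v <- pmin(pmax(wheel_speeds, -config$body$v_max), config$body$v_max)
  heading <- pose[3] + (v[2] - v[1]) / config$body$diameter
  speed <- mean(v)
  x <- pose[1] + speed * cos(heading)
  y <- pose[2] + speed * sin(heading)
  if (!is.null(world)) {
    world$agents$x[hunter_id] <- x
    world$agents$y[hunter_id] <- y
    world <- resolve_collisions(world, hunter_id)
    x <- world$agents$x[hunter_id]
    y <- world$agents$y[hunter_id]
  } else {
    radius <- config$body$diameter / 2
    x <- min(max(x, radius), config$arena$width - radius)
    y <- min(max(y, radius), config$arena$height - radius)
  }
  c(x, y, heading)
}

#' Push a moved agent out of walls and other bodies
#'
#' The moving agent is clamped inside the walls (per-axis) and displaced
#' along the centre-to-centre axis to exact contact with any overlapped
#' agent disk; all other agents stay put. Hunters move sequentially in id
#' order, so at most one agent is ever resolved per call.
#'
#' @param world A [world_state()].
#' @param moving_id Row index of the agent that just moved.
#' @return The world with the moving agent's position corrected.
#' @export
resolve_collisions <- function(world, moving_id = 1L) {
  res <- cpp_resolve_collisions(world$agents$x, world$agents$y,
                                as.integer(moving_id) - 1L,
                                cpp_config(world$config))
  world$agents$x <- res$x
  world$agents$y <- res$y
  world
}

#' Cast a ray through the world
#'
#' Finds the first agent disk intersected by the ray from `origin` at
#' `angle`, excluding the casting agent's own body. If no agent is hit the
#' ray terminates on the arena wall and the kind is `"none"`.
#'
#' @param origin Numeric `c(x, y)` inside the arena.
#' @param angle Ray direction, radians.
#' @param world A [world_state()].
#' @param exclude_id Row index of the casting agent (`0` to exclude
#'   nothing).
#' @return A list with `kind` (`"none"`, `"hunter"`, `"hare"` or
#'   `"stag"`), `distance` from the origin to the first surface hit, and
#'   `agent_id` (`NA` for a wall hit).
#' @export
cast_ray <- function(origin, angle, world, exclude_id = 0L) {
  res <- cpp_cast_ray(origin[1], origin[2], angle,
                      world$agents$x, world$agents$y,
                      kind_to_code(world$agents$kind),
                      world$config$body$diameter / 2,
                      as.integer(exclude_id) - 1L,
                      world$config$arena$width, world$config$arena$height)
  list(kind = c("none", kind_levels)[res[1] + 1],
       distance = res[2],
       agent_id = if (res[3] > 0) as.integer(res[3]) else NA_integer_)
}

#' Advance capture counters and resolve captures
#'
#' Each prey keeps one counter: it increments on any step where at least
#' one hunter's centre is within `catch_distance`, and (by default) resets
#' to zero on a step with no hunter in range. When the counter reaches
#' `capture_steps` the prey is captured; the capture is cooperative iff
#' both hunters are in range at that very step. Every participant receives
#' the full reward-table entry for the prey kind and cooperation flag —
#' rewards are not split. The prey is immediately respawned at a random
#' free position with the same kind and a zeroed counter.
#'
#' @param world A [world_state()].
#' @param rewards A [reward_table()].
#' @param rng A [make_rng()] stream used for respawn positions.
#' @return A list with the updated `world` and `events`, a tibble with one
#'   row per capture (`time`, `prey_kind`, `cooperative`, `hunter1`,
#'   `hunter2`, `reward`).
#' @export
update_captures <- function(world, rewards = world$config$rewards,
                            rng = make_rng(0, "respawn")) {
  cfg <- world$config
  world$step <- world$step + 1L
  hx <- world$agents$x[1:2]
  hy <- world$agents$y[1:2]
  n_prey <- nrow(world$agents) - 2L
  events <- list()
  for (p in seq_len(n_prey)) {
    a <- p + 2L
    d2 <- (hx - world$agents$x[a])^2 + (hy - world$agents$y[a])^2
    in_range <- d2 <= cfg$evo$catch_distance^2
    if (any(in_range)) {
      world$counters[p] <- world$counters[p] + 1L
    } else if (!cfg$evo$cumulative_capture) {
      world$counters[p] <- 0L
    }
    if (world$counters[p] >= cfg$evo$capture_steps) {
      coop <- all(in_range)
      kind <- world$agents$kind[a]
      reward <- if (kind == "hare") {
        if (coop) rewards$hare_coop else rewards$hare_solo
      } else {
        if (coop) rewards$stag_coop else rewards$stag_solo
      }
      events[[length(events) + 1]] <- tibble::tibble(
        time = world$step, prey_kind = kind, cooperative = coop,
        hunter1 = in_range[1], hunter2 = in_range[2], reward = reward)
      pos <- sample_free_position(cfg, world$agents$x[-a],
                                  world$agents$y[-a], rng)
      world$agents$x[a] <- pos[1]
      world$agents$y[a] <- pos[2]
      world$counters[p] <- 0L
    }
  }
  events <- if (length(events) > 0) {
    dplyr::bind_rows(events)
  } else {
    tibble::tibble(time = integer(), prey_kind = character(),
                   cooperative = logical(), hunter1 = logical(),
                   hunter2 = logical(), reward = numeric())
  }
  list(world = world, events = events)
}

#' Simulate one full episode
#'
#' Runs `episode_steps` steps of perceive, control, move, resolve
#' collisions and update captures for a pair of genomes in a freshly
#' placed (or supplied) world, and returns the payoff ledger.
#'
#' @param genome_a,genome_b Gene vectors in `[0, 1]` of the configured
#'   length (506 for the default 61-8-2 architecture); `genome_a` drives
#'   hunter 1.
#' @param config A [staghunt_config()].
#' @param rng A [make_rng()] stream (or integer seed) controlling
#'   placement and respawns.
#' @param record_trajectories If `TRUE`, per-step hunter poses are
#'   returned.
#' @param init_world Optional [world_state()] fixing the initial
#'   placement (used by fixtures and replays).
#' @return A list of class `episode_result`: `payoff` (length 2), `counts`
#'   (hares, coop_stags, solo_stags), `events` (tibble), optional
#'   `trajectories` (tibble of step, hunter, x, y, heading), and the
#'   initial/final world snapshots.
#' @export
run_episode <- function(genome_a, genome_b, config = staghunt_config(),
                        rng = config$evo$seed, record_trajectories = FALSE,
                        init_world = NULL) {
  rng <- as_rng(rng, "episode")
  seed <- rng_int(rng, 1)
  init <- NULL
  if (!is.null(init_world)) {
    init <- list(x = init_world$agents$x, y = init_world$agents$y,
                 heading = init_world$agents$heading[1:2],
                 kind = kind_to_code(init_world$agents$kind))
  }
  raw <- cpp_run_episode(genome_a, genome_b, cpp_config(config),
                         seed, record_trajectories, init)
  events <- tibble::tibble(
    time = raw$events$time,
    prey_kind = code_to_kind(raw$events$kind),
    cooperative = raw$events$cooperative == 1L,
    hunter1 = raw$events$hunter1 == 1L,
    hunter2 = raw$events$hunter2 == 1L,
    reward = raw$events$reward)
  res <- list(payoff = raw$payoff,
              counts = raw$counts,
              events = events,
              initial = tibble::tibble(
                kind = code_to_kind(raw$init_kind),
                x = raw$init_x, y = raw$init_y,
                heading = c(raw$init_heading,
                            rep(NA_real_, length(raw$init_x) - 2))),
              final = tibble::tibble(
                kind = code_to_kind(raw$init_kind),
                x = raw$final_x, y = raw$final_y,
                heading = c(raw$final_heading,
                            rep(NA_real_, length(raw$final_x) - 2))))
  if (record_trajectories) {
    tr <- raw$trajectories
    res$trajectories <- tibble::tibble(
      step = rep(as.integer(tr[, 1]), 2),
      hunter = rep(1:2, each = nrow(tr)),
      x = c(tr[, 2], tr[, 5]),
      y = c(tr[, 3], tr[, 6]),
      heading = c(tr[, 4], tr[, 7]))
  }
  class(res) <- "episode_result"
  res
}

#' @export
print.episode_result <- function(x, ...) {
  cat("<episode_result>\n")
  cat("  payoff:", x$payoff[1], "/", x$payoff[2], "\n")
  cat("  hunted:", x$counts[["hares"]], "hares,",
      x$counts[["coop_stags"]], "coop stags,",
      x$counts[["solo_stags"]], "solo stags\n")
  invisible(x)
}
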