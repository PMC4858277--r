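# Independent oracles and small builders shared across the test files.
# Everything here is deliberately written from first principles (closed
# forms, exhaustive enumeration) and never calls the code paths it checks.

# Exhaustive line-circle ray cast: distance from origin to the first
# surface of any agent disk along the ray, else the wall, using the
# quadratic closed form on every disk.
oracle_cast_ray <- function(ox, oy, angle, agents, radius, arena_w, arena_h,
                            exclude = 0L) {
  dx <- cos(angle)
  dy <- sin(angle)
  twall <- Inf
  if (dx > 0) twall <- min(twall, (arena_w - ox) / dx)
  if (dx < 0) twall <- min(twall, -ox / dx)
  if (dy > 0) twall <- min(twall, (arena_h - oy) / dy)
  if (dy < 0) twall <- min(twall, -oy / dy)
  best <- Inf
  best_kind <- "none"
  for (j in seq_len(nrow(agents))) {
    if (j == exclude) next
    mx <- agents$x[j] - ox
    my <- agents$y[j] - oy
    b <- mx * dx + my * dy
    cc <- mx^2 + my^2 - radius^2
    t <- if (cc <= 0) {
      0
    } else {
      disc <- b^2 - cc
      if (disc < 0) NA_real_ else {
        root <- b - sqrt(disc)
        if (root < 0) NA_real_ else root
      }
    }
    if (!is.na(t) && t < best) {
      best <- t
      best_kind <- agents$kind[j]
    }
  }
  if (best < twall) list(kind = best_kind, distance = best)
  else list(kind = "none", distance = twall)
}

# Exact two-sided Mann-Whitney p-value by full enumeration of all
# C(na + nb, na) rank assignments (untied samples only).
oracle_mw_exact <- function(a, b) {
  na <- length(a)
  nb <- length(b)
  r <- rank(c(a, b))
  U_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  n <- na + nb
  splits <- utils::combn(n, na)
  U_all <- apply(splits, 2, function(idx) sum(idx) - na * (na + 1) / 2)
  lower <- mean(U_all <= U_obs)
  upper <- mean(U_all >= U_obs)
  list(U = U_obs, p_value = min(1, 2 * min(lower, upper)))
}

# Two points orbiting a common centre, diametrically opposed.
oracle_orbit_pair <- function(omega, steps, r = 30, centre = c(100, 100)) {
  t <- seq_len(steps) - 1
  a <- data.frame(x = centre[1] + r * cos(omega * t),
                  y = centre[2] + r * sin(omega * t))
  b <- data.frame(x = centre[1] - r * cos(omega * t),
                  y = centre[2] - r * sin(omega * t))
  list(a = a, b = b)
}

# Small configurations used throughout; prey counts chosen per test.
tiny_config <- function(n_hares = 2L, n_stags = 2L, episode_steps = 400L,
                        capture_steps = 100L, arena = 300, ...) {
  staghunt_config(
    arena = arena_config(arena, arena),
    evo = evo_config(n_hares = n_hares, n_stags = n_stags,
                     episode_steps = episode_steps,
                     capture_steps = capture_steps, ...))
}

# Genome whose decoded weights are all zero: the controller holds still.
stationary_genome <- function(config = staghunt_config()) {
  rep(0.5, config$controller$genome_length)
}

# Forward pass with the same accumulation order as the engine's inner
# loop, so reference trajectories match to machine precision.
r_forward_ordered <- function(wt, x) {
  H <- ncol(wt$W_ih)
  hidden <- numeric(H)
  for (i in seq_along(x)) {
    xi <- x[i]
    if (xi == 0) next
    hidden <- hidden + wt$W_ih[i, ] * xi
  }
  hidden <- 1 / (1 + exp(-hidden))
  out <- wt$W_ho[H + 1, ]
  for (j in seq_len(H)) out <- out + wt$W_ho[j, ] * hidden[j]
  1 / (1 + exp(-out))
}

# Reference episode loop composed from the R-level module surface
# (kinematics, collision resolution, capture bookkeeping in R), used to
# cross-check the C++ loop step by step. Captures respawn via `rng`.
r_episode_loop <- function(genome_a, genome_b, world, steps,
                           rng = make_rng(0, "r-loop")) {
  config <- world$config
  genomes <- list(genome_a, genome_b)
  weights <- lapply(genomes, decode_genome, arch = config$controller)
  payoff <- c(0, 0)
  events <- list()
  traj <- vector("list", steps)
  for (s in seq_len(steps)) {
    for (h in 1:2) {
      iv <- build_input_vector(world, h)
      o <- nn_forward(weights[[h]], iv, config$controller)
      v <- wheels_from_outputs(o, config$body)
      pose <- c(world$agents$x[h], world$agents$y[h], world$agents$heading[h])
      pose <- step_hunter(pose, v, config, world, h)
      world$agents$x[h] <- pose[1]
      world$agents$y[h] <- pose[2]
      world$agents$heading[h] <- pose[3]
    }
    upd <- update_captures(world, config$rewards, rng)
    world <- upd$world
    if (nrow(upd$events) > 0) {
      events[[length(events) + 1]] <- upd$events
      for (i in seq_len(nrow(upd$events))) {
        if (upd$events$hunter1[i]) payoff[1] <- payoff[1] + upd$events$reward[i]
        if (upd$events$hunter2[i]) payoff[2] <- payoff[2] + upd$events$reward[i]
      }
    }
    traj[[s]] <- c(world$agents$x[1:2], world$agents$y[1:2],
                   world$agents$heading[1:2])
  }
  list(world = world,
       payoff = payoff,
       events = if (length(events)) dplyr::bind_rows(events) else NULL,
       traj = do.call(rbind, traj))
}
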