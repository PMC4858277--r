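#' Arena geometry
#'
#' The hunting ground is an axis-aligned square arena with four solid walls
#' and no internal obstacles. Distances are in abstract length-units; one
#' simulation tick is one time-step.
#'
#' @param width,height Arena side lengths in length-units (default 800).
#' @return A list of class `arena_config`.
#' @export
arena_config <- function(width = 800, height = 800) {
  stopifnot(is.numeric(width), width > 0, is.numeric(height), height > 0)
  structure(list(width = width, height = height), class = "arena_config")
}

#' Agent body and sensor layout
#'
#' Every agent (hunter or prey) is a solid disk. Hunters additionally carry
#' 12 short-range proximity sensors evenly spaced around the body and a
#' forward camera of 12 infinite-range rays spread over a 90 degree cone
#' centred on the heading.
#'
#' @param diameter Body diameter, length-units.
#' @param n_proximity Number of proximity sensors (evenly spaced over 360
#'   degrees).
#' @param proximity_range Proximity sensor range from the body surface;
#'   defaults to twice the diameter.
#' @param n_camera_rays Number of camera rays.
#' @param camera_fov Camera field of view in degrees.
#' @param v_max Maximum wheel speed, length-units per step.
#' @return A list of class `body_spec`.
#' @export
body_spec <- function(diameter = 14, n_proximity = 12L,
                      proximity_range = 2 * diameter,
                      n_camera_rays = 12L, camera_fov = 90,
                      v_max = 2) {
  stopifnot(diameter > 0, n_proximity >= 1, proximity_range > 0,
            n_camera_rays >= 1, camera_fov > 0, camera_fov <= 360, v_max > 0)
  structure(list(diameter = diameter,
                 n_proximity = as.integer(n_proximity),
                 proximity_range = proximity_range,
                 n_camera_rays = as.integer(n_camera_rays),
                 camera_fov = camera_fov,
                 v_max = v_max),
            class = "body_spec")
}

#' Food rewards for hunting each prey type alone or cooperatively
#'
#' A hare rewards every participant the same whether hunted alone or
#' together. A stag rewards 500 per hunter only when captured cooperatively;
#' under the baseline preset a stag killed by a single hunter is removed but
#' rewards nothing (a failed hunt). Rewards are never split between
#' cooperators.
#'
#' @param hare_solo,hare_coop,stag_solo,stag_coop Food-units awarded to each
#'   participating hunter.
#' @return A list of class `reward_table`.
#' @export
reward_table <- function(hare_solo = 50, hare_coop = 50,
                         stag_solo = 0, stag_coop = 500) {
  vals <- c(hare_solo, hare_coop, stag_solo, stag_coop)
  stopifnot(is.numeric(vals), all(vals >= 0))
  structure(list(hare_solo = hare_solo, hare_coop = hare_coop,
                 stag_solo = stag_solo, stag_coop = stag_coop),
            class = "reward_table")
}

#' @rdname reward_table
#' @param preset `"baseline"` (no reward for a stag hunted alone) or
#'   `"stag-alone-reward"` (a solitary stag pays as much as a hare).
#' @export
reward_preset <- function(preset = c("baseline", "stag-alone-reward")) {
  preset <- match.arg(preset)
  switch(preset,
         "baseline" = reward_table(50, 50, 0, 500),
         "stag-alone-reward" = reward_table(50, 50, 50, 500))
}

#' Evolutionary-algorithm and episode parameters
#'
#' Defaults reproduce the published experimental scale: a constant
#' population of 20 hunters evolved for 3000 generations under
#' fitness-proportionate (Wright-Fisher) selection, each individual
#' evaluated over 25 episodes (5 random partners, 5 episodes per pair) of
#' 20,000 time-steps, per-gene Gaussian mutation with probability 5e-3 and
#' standard deviation 0.1, and 18 stationary prey (9 hares + 9 stags)
#' captured by remaining within 28 units for 800 consecutive steps.
#'
#' @param population_size Number of individuals (constant across
#'   generations).
#' @param generations Generations of the main experiment.
#' @param n_partners Partner draws per evaluation (each excludes self, with
#'   replacement across draws).
#' @param sims_per_pair Episodes per partner draw.
#' @param gene_mutation_prob Per-gene mutation probability.
#' @param mutation_sigma Standard deviation of the Gaussian mutation added
#'   to a mutated gene (genes clipped back to \[0, 1\]).
#' @param clonal If `TRUE`, every episode pairs an individual with an exact
#'   clone of itself (genetic relatedness 1).
#' @param episode_steps Time-steps per episode.
#' @param capture_steps Consecutive steps a prey must be attended before
#'   capture.
#' @param catch_distance Centre-to-centre catching distance, length-units.
#' @param n_hares,n_stags Prey composition (prey count is held constant by
#'   same-kind respawn).
#' @param pre_generations Generations of hare-only pre-evolution used by the
#'   pre-evolved initialisation.
#' @param cumulative_capture If `TRUE` the capture counter accumulates
#'   across interruptions instead of resetting when no hunter is in range.
#' @param partner_replacement If `FALSE`, the partner draws within one
#'   evaluation are distinct individuals.
#' @param seed Master seed recorded with the configuration.
#' @return A list of class `evo_config`.
#' @export
evo_config <- function(population_size = 20L, generations = 3000L,
                       n_partners = 5L, sims_per_pair = 5L,
                       gene_mutation_prob = 5e-3, mutation_sigma = 0.1,
                       clonal = FALSE, episode_steps = 20000L,
                       capture_steps = 800L, catch_distance = 28,
                       n_hares = 9L, n_stags = 9L,
                       pre_generations = 1000L,
                       cumulative_capture = FALSE,
                       partner_replacement = TRUE,
                       seed = 1L) {
  cfg <- list(population_size = as.integer(population_size),
              generations = as.integer(generations),
              n_partners = as.integer(n_partners),
              sims_per_pair = as.integer(sims_per_pair),
              gene_mutation_prob = gene_mutation_prob,
              mutation_sigma = mutation_sigma,
              clonal = isTRUE(clonal),
              episode_steps = as.integer(episode_steps),
              capture_steps = as.integer(capture_steps),
              catch_distance = catch_distance,
              n_hares = as.integer(n_hares),
              n_stags = as.integer(n_stags),
              pre_generations = as.integer(pre_generations),
              cumulative_capture = isTRUE(cumulative_capture),
              partner_replacement = isTRUE(partner_replacement),
              seed = as.integer(seed))
  validate_evo_config(cfg)
  structure(cfg, class = "evo_config")
}

validate_evo_config <- function(cfg) {
  if (cfg$population_size < 2) stop("population_size must be >= 2", call. = FALSE)
  if (!cfg$clonal && cfg$n_partners > cfg$population_size - 1) {
    stop("n_partners must be <= population_size - 1", call. = FALSE)
  }
  if (cfg$gene_mutation_prob < 0 || cfg$gene_mutation_prob > 1) {
    stop("gene_mutation_prob must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$mutation_sigma < 0) stop("mutation_sigma must be >= 0", call. = FALSE)
  if (cfg$n_hares < 0 || cfg$n_stags < 0) stop("prey counts must be >= 0", call. = FALSE)
  if (cfg$capture_steps < 1) stop("capture_steps must be >= 1", call. = FALSE)
  if (cfg$episode_steps < 0) stop("episode_steps must be >= 0", call. = FALSE)
  if (cfg$catch_distance <= 0) stop("catch_distance must be > 0", call. = FALSE)
  invisible(cfg)
}

#' Controller architecture
#'
#' The hunter controller is a fully connected multi-layer perceptron with a
#' single hidden layer: sensory inputs (12 proximity activations, 4 values
#' per camera ray, and a constant bias input of 1) map through `n_hidden`
#' sigmoid units to two sigmoid outputs that drive the wheels. Genes in
#' \[0, 1\] map linearly onto weights in `[-w_max, w_max]`.
#'
#' The genome length follows from the layer sizes:
#' `n_inputs * n_hidden + (n_hidden + 1) * n_outputs` — the hidden layer
#' feeds the outputs through an additional bias weight per output. With the
#' default 61-8-2 architecture this gives 506 genes.
#'
#' @param body A [body_spec()] determining the number of sensory inputs.
#' @param n_hidden Hidden-layer width.
#' @param n_outputs Number of outputs (two wheel speeds).
#' @param w_max Weight magnitude bound; gene g maps to `(2g - 1) * w_max`.
#' @return A list of class `controller_arch`.
#' @export
controller_arch <- function(body = body_spec(), n_hidden = 8L,
                            n_outputs = 2L, w_max = 5) {
  n_inputs <- body$n_proximity + 4L * body$n_camera_rays + 1L
  structure(list(n_inputs = as.integer(n_inputs),
                 n_hidden = as.integer(n_hidden),
                 n_outputs = as.integer(n_outputs),
                 w_max = w_max,
                 genome_length = as.integer(n_inputs * n_hidden +
                                              (n_hidden + 1L) * n_outputs)),
            class = "controller_arch")
}

#' Full run configuration
#'
#' Bundles arena, body, controller, evolutionary parameters, reward table
#' and the experimental condition name into one validated object. With no
#' arguments this is the baseline condition: Table-style rewards
#' (50, 50, 0, 500), 9 hares + 9 stags, population 20.
#'
#' @param condition Name of the experimental condition (see
#'   [condition_preset()]); fields the condition fixes are applied first and
#'   explicit arguments override the rest.
#' @param arena An [arena_config()].
#' @param body A [body_spec()].
#' @param controller A [controller_arch()].
#' @param evo An [evo_config()].
#' @param rewards A [reward_table()].
#' @return A list of class `staghunt_config`.
#' @export
staghunt_config <- function(condition = "baseline",
                            arena = arena_config(),
                            body = body_spec(),
                            controller = controller_arch(body),
                            evo = evo_config(),
                            rewards = reward_table()) {
  stopifnot(inherits(arena, "arena_config"), inherits(body, "body_spec"),
            inherits(controller, "controller_arch"),
            inherits(evo, "evo_config"), inherits(rewards, "reward_table"))
  structure(list(condition = condition, arena = arena, body = body,
                 controller = controller, evo = evo, rewards = rewards),
            class = "staghunt_config")
}

#' @export
print.staghunt_config <- function(x, ...) {
  cat("<staghunt_config>\n")
  cat("  condition:", x$condition, "\n")
  cat("  arena:", x$arena$width, "x", x$arena$height, "\n")
  cat("  prey:", x$evo$n_hares, "hares +", x$evo$n_stags, "stags\n")
  cat("  rewards (hare solo/coop, stag solo/coop):",
      x$rewards$hare_solo, x$rewards$hare_coop,
      x$rewards$stag_solo, x$rewards$stag_coop, "\n")
  cat("  population:", x$evo$population_size,
      " generations:", x$evo$generations, "\n")
  invisible(x)
}

config_field_names <- list(
  arena = c("width", "height"),
  body = c("diameter", "n_proximity", "proximity_range", "n_camera_rays",
           "camera_fov", "v_max"),
  controller = c("n_hidden", "n_outputs", "w_max"),
  evo = c("population_size", "generations", "n_partners", "sims_per_pair",
          "gene_mutation_prob", "mutation_sigma", "clonal", "episode_steps",
          "capture_steps", "catch_distance", "n_hares", "n_stags",
          "pre_generations", "cumulative_capture", "partner_replacement",
          "seed"),
  rewards = c("hare_solo", "hare_coop", "stag_solo", "stag_coop")
)

#' Read a run configuration from YAML
#'
#' The document is a nested key-value mapping with top-level sections
#' `condition`, `arena`, `body`, `controller`, `evo` and `rewards`; any
#' omitted key takes its default, so an empty document with
#' `condition: baseline` reproduces the baseline experiment. Unknown keys
#' and out-of-range values raise an error naming the offending key.
#'
#' @param path_or_text Path to a YAML file, or a YAML string.
#' @return A validated [staghunt_config()].
#' @seealso [serialize_config()] for the inverse.
#' @export
load_config <- function(path_or_text) {
  doc <- if (length(path_or_text) == 1 && file.exists(path_or_text)) {
    yaml::read_yaml(path_or_text)
  } else {
    yaml::yaml.load(paste(path_or_text, collapse = "\n"))
  }
  if (is.null(doc)) doc <- list()
  known_top <- c("condition", names(config_field_names))
  unknown <- setdiff(names(doc), known_top)
  if (length(unknown) > 0) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  condition <- doc$condition %||% "baseline"
  preset <- condition_preset(condition)  # errors on unknown condition

  build_section <- function(section, constructor, base_args = list()) {
    supplied <- doc[[section]] %||% list()
    unknown <- setdiff(names(supplied), config_field_names[[section]])
    if (length(unknown) > 0) {
      stop("unknown key(s) in section '", section, "': ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    args <- utils::modifyList(base_args, supplied)
    do.call(constructor, args)
  }

  arena <- build_section("arena", arena_config)
  body <- build_section("body", body_spec)
  controller <- build_section("controller", function(...) {
    controller_arch(body = body, ...)
  })
  evo <- build_section("evo", evo_config, preset$evo_overrides)
  rewards <- build_section("rewards", reward_table,
                           unclass(preset$rewards))
  staghunt_config(condition = condition, arena = arena, body = body,
                  controller = controller, evo = evo, rewards = rewards)
}

#' Serialise a configuration to YAML text
#'
#' @param config A [staghunt_config()].
#' @return A YAML string; `load_config()` of this string returns an
#'   identical configuration.
#' @export
serialize_config <- function(config) {
  stopifnot(inherits(config, "staghunt_config"))
  doc <- list(condition = config$condition,
              arena = unclass(config$arena),
              body = unclass(config$body),
              controller = unclass(config$controller)[config_field_names$controller],
              evo = unclass(config$evo),
              rewards = unclass(config$rewards))
  yaml::as.yaml(doc)
}

#' Shrink a configuration to desk scale
#'
#' The published experimental scale (30 runs x 3000 generations x 25
#' episodes x 20,000 steps) is a cluster workload. The desk profile is a
#' documented miniature used for smoke tests and examples: a 200 x 200
#' arena, 2000-step episodes, 200-step captures, 6 prey (prey-type ratio
#' preserved), population 10 and 50 generations (also 50 generations of
#' hare-only pre-evolution).
#'
#' @param config A [staghunt_config()].
#' @return The shrunk configuration.
#' @export
desk_profile <- function(config = staghunt_config()) {
  stopifnot(inherits(config, "staghunt_config"))
  total_prey <- config$evo$n_hares + config$evo$n_stags
  frac_hare <- if (total_prey > 0) config$evo$n_hares / total_prey else 0.5
  n_hares <- as.integer(round(6 * frac_hare))
  config$arena <- arena_config(200, 200)
  config$evo$episode_steps <- 2000L
  config$evo$capture_steps <- 200L
  config$evo$n_hares <- n_hares
  config$evo$n_stags <- 6L - n_hares
  config$evo$population_size <- 10L
  config$evo$generations <- 50L
  config$evo$pre_generations <- 50L
  validate_evo_config(config$evo)
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a
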