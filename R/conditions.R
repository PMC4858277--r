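#' Named experimental conditions
#'
#' The seven presets reproduce the published experimental conditions. Each
#' differs from `baseline` only in the fields its description states:
#'
#' * `baseline` — embodied model, rewards (50, 50, 0, 500), 9 hares + 9
#'   stags, population pre-evolved on hares only.
#' * `gt-baseline` — the single-binary-locus game-theoretic model under the
#'   same evolutionary regime, all individuals starting with the hare
#'   allele.
#' * `random-init` — embodied model started from uniformly random genomes
#'   instead of pre-evolved hare hunters.
#' * `stag-alone-reward` — a stag hunted alone rewards 50 (like a hare).
#' * `clonal` — every individual is paired with a clone of itself
#'   (genetic relatedness 1).
#' * `density-6` — prey density lowered to 3 hares + 3 stags.
#' * `density-30` — prey density raised to 15 hares + 15 stags.
#'
#' @param name Condition name.
#' @return A list with elements `name`, `model` (`"robotic"` or `"gt"`),
#'   `init` (`"pre-evolved-hare"`, `"random"` or `"all-hare"`), `rewards`
#'   (a [reward_table()]) and `evo_overrides` (named list applied over
#'   [evo_config()] defaults).
#' @export
condition_preset <- function(name) {
  presets <- list(
    "baseline" = list(model = "robotic", init = "pre-evolved-hare",
                      rewards = reward_preset("baseline"),
                      evo_overrides = list()),
    "gt-baseline" = list(model = "gt", init = "all-hare",
                         rewards = reward_preset("baseline"),
                         evo_overrides = list()),
    "random-init" = list(model = "robotic", init = "random",
                         rewards = reward_preset("baseline"),
                         evo_overrides = list()),
    "stag-alone-reward" = list(model = "robotic", init = "pre-evolved-hare",
                               rewards = reward_preset("stag-alone-reward"),
                               evo_overrides = list()),
    "clonal" = list(model = "robotic", init = "pre-evolved-hare",
                    rewards = reward_preset("baseline"),
                    evo_overrides = list(clonal = TRUE)),
    "density-6" = list(model = "robotic", init = "pre-evolved-hare",
                       rewards = reward_preset("baseline"),
                       evo_overrides = list(n_hares = 3L, n_stags = 3L)),
    "density-30" = list(model = "robotic", init = "pre-evolved-hare",
                        rewards = reward_preset("baseline"),
                        evo_overrides = list(n_hares = 15L, n_stags = 15L))
  )
  if (!name %in% names(presets)) {
    stop("unknown condition '", name, "'; known conditions: ",
         paste(names(presets), collapse = ", "), call. = FALSE)
  }
  c(list(name = name), presets[[name]])
}

#' @rdname condition_preset
#' @export
condition_names <- function() {
  c("baseline", "gt-baseline", "random-init", "stag-alone-reward",
    "clonal", "density-6", "density-30")
}

#' Build the full configuration for a named condition
#'
#' @param name Condition name, see [condition_preset()].
#' @param profile `"paper"` for the published scale or `"desk"` for the
#'   miniature smoke-test scale (see [desk_profile()]).
#' @param seed Master seed stored in the configuration.
#' @return A [staghunt_config()].
#' @export
condition_config <- function(name, profile = c("paper", "desk"), seed = 1L) {
  profile <- match.arg(profile)
  preset <- condition_preset(name)
  evo <- do.call(evo_config, c(preset$evo_overrides, list(seed = seed)))
  cfg <- staghunt_config(condition = name, evo = evo, rewards = preset$rewards)
  if (profile == "desk") cfg <- desk_profile(cfg)
  cfg
}
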