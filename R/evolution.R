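#' Construct a population
#'
#' A population is a fixed-size collection of genomes with their (possibly
#' not yet evaluated) fitnesses and a generation index.
#'
#' @param genomes List of genome vectors (or, in the game-theoretic model,
#'   allele labels).
#' @param fitness Numeric fitness per individual; `NA` before evaluation.
#' @param generation Generation index of the snapshot.
#' @return A list of class `population`.
#' @export
new_population <- function(genomes, fitness = rep(NA_real_, length(genomes)),
                           generation = 0L) {
  structure(list(genomes = genomes, fitness = fitness,
                 generation = as.integer(generation)),
            class = "population")
}

#' @export
print.population <- function(x, ...) {
  cat("<population generation=", x$generation, " size=", length(x$genomes),
      ">\n", sep = "")
  invisible(x)
}

#' Evaluate the fitness of one individual
#'
#' The focal individual is successively paired with `n_partners` partners
#' drawn uniformly among the other individuals (a fresh draw each time, so
#' the same partner can recur; never itself), and `sims_per_pair` episodes
#' are simulated per pairing — 25 episodes under the defaults. Fitness is
#' the focal individual's summed food payoff divided by the number of
#' episodes; the partner's payoff counts only toward its own evaluation.
#' In clonal mode every episode instead pairs the individual with an exact
#' copy of itself.
#'
#' @param index Focal individual's position in the population.
#' @param population A `population` object (list of genomes).
#' @param config A [staghunt_config()].
#' @param pair_rng,episode_rng [make_rng()] streams for partner draws and
#'   episode worlds.
#' @return A list: `fitness` (mean food per episode) and `episodes`, a
#'   matrix with one row per episode and columns `hares`, `coop_stags`,
#'   `solo_stags`, `payoff`.
#' @export
evaluate_fitness <- function(index, population, config,
                             pair_rng = make_rng(config$evo$seed, "pairing"),
                             episode_rng = make_rng(config$evo$seed, "episodes")) {
  evo <- config$evo
  n <- length(population$genomes)
  if (!evo$clonal && n < 2) {
    stop("non-clonal evaluation needs a population of at least 2",
         call. = FALSE)
  }
  partners <- if (evo$clonal) {
    rep(index, evo$n_partners)
  } else if (evo$partner_replacement) {
    draws <- rng_sample_int(pair_rng, n - 1L, evo$n_partners, replace = TRUE)
    ifelse(draws >= index, draws + 1L, draws)
  } else {
    draws <- rng_sample_int(pair_rng, n - 1L, evo$n_partners, replace = FALSE)
    ifelse(draws >= index, draws + 1L, draws)
  }
  n_ep <- evo$n_partners * evo$sims_per_pair
  ep <- matrix(0, nrow = n_ep, ncol = 4,
               dimnames = list(NULL, c("hares", "coop_stags", "solo_stags",
                                       "payoff")))
  cfg_flat <- cpp_config(config)
  focal <- population$genomes[[index]]
  row <- 1L
  for (p in partners) {
    partner_genome <- population$genomes[[p]]
    for (s in seq_len(evo$sims_per_pair)) {
      seed <- rng_int(episode_rng, 1)
      raw <- cpp_run_episode(focal, partner_genome, cfg_flat, seed,
                             FALSE, NULL)
      ep[row, 1:3] <- raw$counts
      ep[row, 4] <- raw$payoff[1]
      row <- row + 1L
    }
  }
  list(fitness = sum(ep[, "payoff"]) / n_ep, episodes = ep)
}

#' Wright-Fisher (fitness-proportionate) parent sampling
#'
#' Draws one parent per offspring slot independently, with the probability
#' of picking parent `i` proportional to its fitness. When every fitness
#' is zero the draw falls back to uniform.
#'
#' @param fitnesses Non-negative fitness vector.
#' @param rng A [make_rng()] stream.
#' @param n_offspring Number of slots to fill (defaults to the population
#'   size).
#' @return Integer vector of parent indices.
#' @export
wright_fisher_select <- function(fitnesses, rng,
                                 n_offspring = length(fitnesses)) {
  if (any(fitnesses < 0)) stop("fitnesses must be non-negative", call. = FALSE)
  prob <- if (sum(fitnesses) == 0) NULL else fitnesses
  rng_sample_int(rng, length(fitnesses), n_offspring, replace = TRUE,
                 prob = prob)
}

#' Gaussian per-gene mutation
#'
#' Independently for each gene, with probability `gene_mutation_prob`, a
#' draw from `Normal(0, mutation_sigma^2)` is added and the result clipped
#' back into `[0, 1]`. The parent genome is never modified in place.
#'
#' @param genome Gene vector in `[0, 1]`.
#' @param config A [staghunt_config()] (or an [evo_config()]).
#' @param rng A [make_rng()] stream.
#' @return The mutated copy.
#' @export
mutate_genome <- function(genome, config, rng) {
  evo <- if (inherits(config, "staghunt_config")) config$evo else config
  hit <- rng_runif(rng, length(genome)) < evo$gene_mutation_prob
  k <- sum(hit)
  if (k > 0) {
    genome[hit] <- pmin(pmax(genome[hit] +
                               rng_rnorm(rng, k, 0, evo$mutation_sigma),
                             0), 1)
  }
  genome
}

#' Run an evolutionary experiment of the embodied model
#'
#' Loops for `generations` generations: every individual is evaluated over
#' its 25 episodes, the next generation is sampled by Wright-Fisher
#' selection, and each offspring is a mutated clone of its parent (no
#' recombination, no elitism). Per-generation means of fitness, prey
#' counts and the successful-stag percentage are recorded; the last
#' generation additionally keeps its per-episode count table.
#'
#' @param config A [staghunt_config()].
#' @param seed Master seed (all substreams derive from it); defaults to
#'   the seed stored in the config.
#' @param initial_population Optional `population` (e.g. from
#'   [pre_evolve_hare_only()]); otherwise genomes are initialised
#'   uniformly at random over `[0, 1]`.
#' @param progress Print a line every `progress` generations (0 for
#'   silence).
#' @return A `stag_run` object; see [tidy.stag_run()], [glance.stag_run()]
#'   and [autoplot.stag_run()].
#' @export
evolve <- function(config = staghunt_config(), seed = config$evo$seed,
                   initial_population = NULL, progress = 0) {
  evo <- config$evo
  arch <- config$controller
  init_rng <- make_rng(seed, "init")
  pair_rng <- make_rng(seed, "pairing")
  episode_rng <- make_rng(seed, "episodes")
  wf_rng <- make_rng(seed, "wf")
  mut_rng <- make_rng(seed, "mut")

  pop <- if (is.null(initial_population)) {
    new_population(lapply(seq_len(evo$population_size), function(i) {
      rng_runif(init_rng, arch$genome_length)
    }))
  } else {
    stopifnot(inherits(initial_population, "population"))
    if (length(initial_population$genomes) != evo$population_size) {
      stop("initial population size does not match the configuration",
           call. = FALSE)
    }
    new_population(initial_population$genomes)
  }

  n <- evo$population_size
  gens <- evo$generations
  rec <- matrix(NA_real_, nrow = gens, ncol = 6,
                dimnames = list(NULL, c("generation", "mean_fitness",
                                        "stag_pct", "hares", "coop_stags",
                                        "solo_stags")))
  last_gen_episodes <- NULL

  for (g in seq_len(gens)) {
    fitness <- numeric(n)
    totals <- matrix(0, nrow = n, ncol = 3)
    ep_sum <- c(0, 0, 0)
    n_ep_total <- 0L
    gen_episodes <- if (g == gens) vector("list", n) else NULL
    for (i in seq_len(n)) {
      ev <- evaluate_fitness(i, pop, config, pair_rng, episode_rng)
      fitness[i] <- ev$fitness
      totals[i, ] <- colSums(ev$episodes[, 1:3, drop = FALSE])
      ep_sum <- ep_sum + totals[i, ]
      n_ep_total <- n_ep_total + nrow(ev$episodes)
      if (!is.null(gen_episodes)) {
        gen_episodes[[i]] <- tibble::tibble(
          individual = i,
          episode = seq_len(nrow(ev$episodes)),
          hares = ev$episodes[, "hares"],
          coop_stags = ev$episodes[, "coop_stags"],
          solo_stags = ev$episodes[, "solo_stags"],
          payoff = ev$episodes[, "payoff"])
      }
    }
    pop$fitness <- fitness
    rec[g, ] <- c(g, mean(fitness),
                  mean(stag_proportion(totals[, 1], totals[, 2],
                                       totals[, 3])),
                  ep_sum / n_ep_total)
    if (!is.null(gen_episodes)) {
      last_gen_episodes <- dplyr::bind_rows(gen_episodes)
    }
    if (progress > 0 && g %% progress == 0) {
      message(sprintf("generation %d/%d: mean fitness %.1f, stags %.1f%%",
                      g, gens, rec[g, "mean_fitness"], rec[g, "stag_pct"]))
    }
    if (g < gens) {
      parents <- wright_fisher_select(fitness, wf_rng)
      pop <- new_population(lapply(parents, function(p) {
        mutate_genome(pop$genomes[[p]], config, mut_rng)
      }), generation = g)
    }
  }

  new_stag_run(record = tibble::as_tibble(as.data.frame(rec)),
               last_generation = last_gen_episodes,
               population = pop,
               config = config, model = "robotic", seed = seed)
}

new_stag_run <- function(record, last_generation, population, config,
                         model, seed) {
  structure(list(record = record, last_generation = last_generation,
                 population = population, config = config, model = model,
                 seed = seed),
            class = "stag_run")
}

#' @export
print.stag_run <- function(x, ...) {
  g <- nrow(x$record)
  cat("<stag_run model=", x$model, " condition=", x$config$condition,
      " generations=", g, ">\n", sep = "")
  if (g > 0) {
    final <- x$record[g, ]
    cat(sprintf("  final: mean fitness %.1f, %.1f%% stags hunted successfully\n",
                final$mean_fitness, final$stag_pct))
  }
  invisible(x)
}

#' Pre-evolve solitary hare hunters
#'
#' Before the stag-hunt experiments that start from efficient solitary
#' hunters, the population is first evolved in an environment composed
#' solely of hares (same total prey count), driving it to the solitary
#' (risk-dominant) equilibrium. The returned population seeds [evolve()]
#' unchanged.
#'
#' @param config A [staghunt_config()]; the prey composition is replaced
#'   by all-hares and the generation count by `pre_generations` for the
#'   duration of this phase.
#' @param seed Master seed for the pre-evolution phase.
#' @param progress See [evolve()].
#' @return The final `population`, with the pre-evolution `stag_run`
#'   attached as attribute `"run"`.
#' @export
pre_evolve_hare_only <- function(config = staghunt_config(),
                                 seed = config$evo$seed, progress = 0) {
  pre_cfg <- config
  pre_cfg$evo$n_hares <- config$evo$n_hares + config$evo$n_stags
  pre_cfg$evo$n_stags <- 0L
  pre_cfg$evo$generations <- config$evo$pre_generations
  run <- evolve(pre_cfg, seed = seed, progress = progress)
  pop <- run$population
  attr(pop, "run") <- run
  pop
}
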