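#' Focal-payoff kernel of the one-locus stag hunt
#'
#' Row = focal strategy, column = partner strategy (order hare, stag). A
#' hare hunter always earns the solitary hare reward; a stag hunter earns
#' the cooperative stag reward iff the partner also hunts stag, and the
#' solitary stag reward otherwise (the stag is still removed — a failed
#' hunt under the baseline rewards).
#'
#' @param rewards A [reward_table()].
#' @return A 2 x 2 numeric matrix.
#' @export
gt_payoff_matrix <- function(rewards = reward_table()) {
  matrix(c(rewards$hare_solo, rewards$hare_solo,
           rewards$stag_solo, rewards$stag_coop),
         nrow = 2, byrow = TRUE,
         dimnames = list(focal = c("hare", "stag"),
                         partner = c("hare", "stag")))
}

#' One bout of the single-locus stag hunt
#'
#' @param strategy_a,strategy_b `"hare"` or `"stag"`.
#' @param rewards A [reward_table()].
#' @return A tibble with one row per player: `player`, `strategy`,
#'   `prey_kind`, `cooperative`, `success` and `payoff`. Swapping the two
#'   players swaps the rows.
#' @export
gt_bout <- function(strategy_a, strategy_b, rewards = reward_table()) {
  stopifnot(strategy_a %in% c("hare", "stag"),
            strategy_b %in% c("hare", "stag"))
  P <- gt_payoff_matrix(rewards)
  strat <- c(strategy_a, strategy_b)
  other <- rev(strat)
  coop <- strat == "stag" & other == "stag"
  tibble::tibble(player = 1:2,
                 strategy = strat,
                 prey_kind = strat,
                 cooperative = coop,
                 success = strat == "hare" | coop,
                 payoff = P[cbind(strat, other)])
}

#' Evolve the single-binary-locus stag hunt
#'
#' The game-theoretic comparison model: each individual carries one binary
#' locus (hare or stag allele) and plays the stag hunt under exactly the
#' same evolutionary regime as the embodied model — 5 random partners
#' (never itself) times 5 bouts per pairing, fitness = mean bout payoff,
#' Wright-Fisher selection over a constant population, and mutation that
#' flips the locus with probability `gene_mutation_prob` per individual
#' per generation. The recorded metric is the percentage of stags hunted
#' successfully (cooperatively) out of all prey hunted across the
#' generation's bouts, with failed solitary stag attempts in the
#' denominator — the same convention as the embodied metric.
#'
#' Selection and metric computations go through the same
#' [wright_fisher_select()] and [stag_proportion()] code paths as
#' [evolve()].
#'
#' @param config A [staghunt_config()]; only the evolutionary parameters
#'   and reward table are used.
#' @param seed Master seed.
#' @param init `"all-hare"`, `"all-stag"` or `"random"` (each allele
#'   uniform), or a numeric initial stag-allele frequency in `[0, 1]`
#'   (deterministically rounded to counts).
#' @return A `stag_run` with `model = "gt"`; the per-generation record
#'   additionally carries the stag-allele frequency.
#' @export
gt_evolve <- function(config = staghunt_config("gt-baseline"),
                      seed = config$evo$seed, init = "all-hare") {
  evo <- config$evo
  n <- evo$population_size
  np <- evo$n_partners
  ns <- evo$sims_per_pair
  P <- gt_payoff_matrix(config$rewards)
  init_rng <- make_rng(seed, "init")
  pair_rng <- make_rng(seed, "pairing")
  wf_rng <- make_rng(seed, "wf")
  mut_rng <- make_rng(seed, "mut")

  s <- if (is.numeric(init)) {
    stopifnot(init >= 0, init <= 1)
    k <- round(init * n)
    c(rep(1L, k), rep(0L, n - k))
  } else {
    switch(match.arg(init, c("all-hare", "all-stag", "random")),
           "all-hare" = rep(0L, n),
           "all-stag" = rep(1L, n),
           "random" = as.integer(rng_runif(init_rng, n) < 0.5))
  }

  gens <- evo$generations
  rec <- matrix(NA_real_, nrow = gens, ncol = 7,
                dimnames = list(NULL, c("generation", "mean_fitness",
                                        "stag_pct", "hares", "coop_stags",
                                        "solo_stags", "stag_freq")))
  last_gen <- NULL
  fitness <- rep(NA_real_, n)

  for (g in seq_len(gens)) {
    # One partner draw per pairing; the ns bouts of a pairing are
    # identical, so payoffs enter fitness once per draw and counts enter
    # the metric ns times.
    draws <- matrix(rng_sample_int(pair_rng, n - 1L, n * np, replace = TRUE),
                    nrow = n)
    partner <- draws + (draws >= seq_len(n))
    ps <- matrix(s[partner], nrow = n)
    pay <- matrix(P[cbind(s + 1L, as.vector(ps) + 1L)], nrow = n)
    fitness <- rowMeans(pay)
    coop <- (s == 1L) & ps == 1L
    n_coop <- rowSums(coop) * ns
    n_solo_stag <- rowSums((s == 1L) & ps == 0L) * ns
    n_hare <- (s == 0L) * np * ns
    rec[g, ] <- c(g, mean(fitness),
                  mean(stag_proportion(n_hare, n_coop, n_solo_stag)),
                  c(sum(n_hare), sum(n_coop), sum(n_solo_stag)) / (n * np * ns),
                  mean(s))
    if (g == gens) {
      last_gen <- tibble::tibble(
        individual = seq_len(n),
        hares = n_hare, coop_stags = n_coop, solo_stags = n_solo_stag,
        payoff = fitness)
    }
    if (g < gens) {
      parents <- wright_fisher_select(fitness, wf_rng)
      s <- s[parents]
      flip <- rng_runif(mut_rng, n) < evo$gene_mutation_prob
      s[flip] <- 1L - s[flip]
    }
  }

  pop <- new_population(as.list(ifelse(s == 1L, "stag", "hare")),
                        fitness = fitness, generation = gens)
  new_stag_run(record = tibble::as_tibble(as.data.frame(rec)),
               last_generation = last_gen,
               population = pop,
               config = config, model = "gt", seed = seed)
}

#' Replicator-dynamics invasion threshold
#'
#' Under random matching, the stag-allele frequency `p*` at which the
#' expected payoff of a stag hunter equals the (frequency-independent)
#' hare payoff:
#' `p* = (hare_solo - stag_solo) / (stag_coop - stag_solo)`.
#' Below `p*` selection removes cooperators; above it, it fixes them. For
#' the baseline rewards (50, 0, 500) this is 0.1; once a solitary stag
#' pays as much as a hare the threshold collapses to 0 (stag hunting is
#' weakly dominant).
#'
#' @param rewards A [reward_table()].
#' @return The threshold frequency in `[0, 1]`.
#' @export
replicator_threshold <- function(rewards = reward_table()) {
  with(rewards, {
    if (!(stag_coop > hare_solo && hare_solo >= stag_solo)) {
      stop("no interior invasion threshold: need stag_coop > hare_solo >= stag_solo",
           call. = FALSE)
    }
    (hare_solo - stag_solo) / (stag_coop - stag_solo)
  })
}
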