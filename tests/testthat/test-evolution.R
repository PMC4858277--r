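test_that("an evaluation runs exactly n_partners x sims_per_pair episodes", {
  cfg <- tiny_config(n_hares = 1L, n_stags = 0L, episode_steps = 50L,
                     capture_steps = 30L)
  pop <- new_population(lapply(1:4, function(i) stationary_genome(cfg)))
  ev <- evaluate_fitness(1, pop, cfg, make_rng(1, "p"), make_rng(1, "e"))
  expect_equal(nrow(ev$episodes), 25L)
  expect_equal(ev$fitness, sum(ev$episodes[, "payoff"]) / 25)
})

test_that("partner draws exclude self and clonal mode pairs with a clone", {
  cfg <- tiny_config(n_hares = 0L, n_stags = 0L, episode_steps = 0L)
  pop <- new_population(lapply(1:6, function(i) stationary_genome(cfg)))
  # with episode_steps 0, evaluation is pure plumbing: probe the partner
  # stream by reproducing its draws
  rng <- make_rng(5, "p")
  draws <- rng_sample_int(make_rng(5, "p"), 5L, cfg$evo$n_partners,
                          replace = TRUE)
  partners <- ifelse(draws >= 3L, draws + 1L, draws)
  expect_true(all(partners != 3L))
  expect_true(all(partners >= 1 & partners <= 6))
  # clonal flag: a population of one is legal and pairs with itself
  ccfg <- cfg
  ccfg$evo$clonal <- TRUE
  pop1 <- new_population(list(stationary_genome(cfg)))
  ev <- evaluate_fitness(1, pop1, ccfg, make_rng(1, "p"), make_rng(1, "e"))
  expect_equal(nrow(ev$episodes), 25L)
  # non-clonal evaluation of a single individual is an error
  expect_error(evaluate_fitness(1, pop1, cfg, make_rng(1, "p"),
                                make_rng(1, "e")), "at least 2")
})

test_that("Wright-Fisher selection is fitness-proportionate", {
  # all mass on one parent
  expect_true(all(wright_fisher_select(c(7, 0, 0, 0), make_rng(1, "wf")) == 1L))
  # equal fitnesses: uniform over 20 parents (chi-square, 1e5 draws)
  draws <- wright_fisher_select(rep(3, 20), make_rng(2, "wf"),
                                n_offspring = 1e5)
  expect_gt(stats::chisq.test(tabulate(draws, 20))$p.value, 0.01)
  # fitnesses 1:3 -> parent 2 frequency 0.75 within 3 binomial s.e.
  draws2 <- wright_fisher_select(c(1, 3), make_rng(3, "wf"),
                                 n_offspring = 1e5)
  se <- sqrt(0.75 * 0.25 / 1e5)
  expect_lt(abs(mean(draws2 == 2L) - 0.75), 3 * se)
  # zero total fitness: uniform fallback, never an error
  expect_true(all(wright_fisher_select(c(0, 0, 0), make_rng(4, "wf")) %in% 1:3))
  expect_error(wright_fisher_select(c(-1, 2), make_rng(5, "wf")),
               "non-negative")
})

test_that("mutation touches the binomial share of genes and clips", {
  cfg <- staghunt_config()
  g <- rng_runif(make_rng(6, "g"), 506)
  # zero probability: identity
  zcfg <- cfg
  zcfg$evo$gene_mutation_prob <- 0
  expect_identical(mutate_genome(g, zcfg, make_rng(7, "m")), g)
  # touch rate ~ Binomial(506, 0.005) over 10,000 mutants
  rng <- make_rng(8, "m")
  touched <- vapply(1:10000, function(i) {
    sum(mutate_genome(g, cfg, rng) != g)
  }, numeric(1))
  expected <- 506 * 0.005
  se <- sqrt(506 * 0.005 * 0.995 / 10000)
  expect_lt(abs(mean(touched) - expected), 3 * se)
  # clipping keeps genes in [0, 1] even from the boundary
  edge <- rep(c(0, 1), length.out = 506)
  bigcfg <- cfg
  bigcfg$evo$gene_mutation_prob <- 1
  bigcfg$evo$mutation_sigma <- 5
  m <- mutate_genome(edge, bigcfg, make_rng(9, "m"))
  expect_true(all(m >= 0 & m <= 1))
  expect_false(identical(m, edge))
})

test_that("a short evolutionary run is reproducible and well-formed", {
  cfg <- tiny_config(n_hares = 2L, n_stags = 1L, episode_steps = 200L,
                     capture_steps = 80L,
                     population_size = 4L, generations = 3L, n_partners = 2L,
                     sims_per_pair = 2L)
  run1 <- evolve(cfg, seed = 42)
  run2 <- evolve(cfg, seed = 42)
  expect_identical(run1$record, run2$record)
  expect_identical(run1$population$genomes, run2$population$genomes)
  expect_equal(nrow(run1$record), 3L)
  expect_equal(length(run1$population$genomes), 4L)
  expect_true(all(run1$record$stag_pct >= 0 & run1$record$stag_pct <= 100))
  expect_equal(nrow(run1$last_generation), 4L * 2L * 2L)
  # offspring are mutated copies, never the same object by reference
  run3 <- evolve(cfg, seed = 43)
  expect_false(identical(run1$record, run3$record))
})

test_that("zero generations returns only the initial snapshot", {
  cfg <- tiny_config(population_size = 3L, generations = 0L, n_partners = 2L)
  run <- evolve(cfg, seed = 1)
  expect_equal(nrow(run$record), 0L)
  expect_equal(length(run$population$genomes), 3L)
})

test_that("hare-only episodes pay only multiples of the hare reward", {
  cfg <- tiny_config(n_hares = 4L, n_stags = 0L, episode_steps = 1000L,
                     capture_steps = 100L)
  arch <- cfg$controller
  for (i in 1:10) {
    e <- run_episode(random_genome(arch, make_rng(70 + i, "a")),
                     random_genome(arch, make_rng(80 + i, "b")),
                     cfg, rng = i)
    expect_true(all(e$payoff %% 50 == 0))
    expect_equal(unname(e$counts[["coop_stags"]] + e$counts[["solo_stags"]]),
                 0L)
  }
})

test_that("hare-only pre-evolution passes through to the main run", {
  cfg <- tiny_config(n_hares = 1L, n_stags = 1L, episode_steps = 100L,
                     capture_steps = 50L, population_size = 3L,
                     generations = 2L, n_partners = 2L, sims_per_pair = 1L)
  cfg$evo$pre_generations <- 2L
  pop <- pre_evolve_hare_only(cfg, seed = 11)
  pre_run <- attr(pop, "run")
  # during pre-evolution the arena contains only hares, same total count
  expect_equal(pre_run$config$evo$n_hares, 2L)
  expect_equal(pre_run$config$evo$n_stags, 0L)
  expect_equal(sum(pre_run$record$coop_stags + pre_run$record$solo_stags), 0)
  # the returned population is used as-is (no re-randomisation)
  main <- evolve(cfg, seed = 12, initial_population = pop)
  expect_equal(nrow(main$record), 2L)
  # seeding evolve with a mismatched population errors
  small <- new_population(pop$genomes[1:2])
  expect_error(evolve(cfg, seed = 1, initial_population = small),
               "population size")
})
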