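toy_population <- function(fitnesses, params) {
  tibble::tibble(fitness = fitnesses,
                 network = replicate(length(fitnesses), random_grn(params),
                                     simplify = FALSE))
}

test_that("config arithmetic matches the two protocols", {
  c50 <- evolution_config("evo50")
  expect_equal(c(c50$n_keep, c50$n_offspring, c50$generations),
               c(500, 500, 150))
  c90 <- evolution_config("evo90")
  expect_equal(c(c90$n_keep, c90$n_offspring, c90$generations),
               c(900, 100, 200))
  expect_error(evolution_config("evo50", fitness_cap = 0), "fitness_cap")
})

test_that("truncation keeps exactly the top-k with deterministic tie-break", {
  set.seed(51)
  p <- grn_params(4, 3)
  cfg <- evolution_config("evo50", population_size = 4, generations = 1)
  pop <- toy_population(c(0.2, 0.9, 0.9, 0.5), p)
  nxt <- evolve_generation(pop, cfg, mutate_fn = identity)
  # survivors: the two 0.9 individuals, earlier index first on ties
  expect_equal(nxt$parent[1:2], c(2, 3))
  expect_equal(nxt$fitness[1:2], c(0.9, 0.9))
  # evo50 parents are the ranked survivors in order
  expect_equal(nxt$parent[3:4], c(2, 3))
  expect_equal(nrow(nxt), 4)
})

test_that("a stubbed identity mutation leaves a uniform population unchanged", {
  set.seed(52)
  p <- grn_params(4, 3)
  net <- random_grn(p)
  pop <- tibble::tibble(fitness = rep(grn_fitness(net), 4),
                        network = replicate(4, net, simplify = FALSE))
  cfg <- evolution_config("evo50", population_size = 4, generations = 1)
  nxt <- evolve_generation(pop, cfg, mutate_fn = identity)
  expect_equal(nxt$fitness, pop$fitness)
  for (i in 1:4) expect_identical(nxt$network[[i]]$edges, net$edges)
})

test_that("offspring fitness is capped when a fitness cap is active", {
  set.seed(53)
  p <- grn_params(4, 4)
  cfg <- evolution_config("evo50", population_size = 4, generations = 1,
                          fitness_cap = 0.1)
  pop <- toy_population(c(0.5, 0.3, 0.2, 0.05), p)
  nxt <- evolve_generation(pop, cfg)
  expect_true(all(nxt$fitness <= 0.1))
})

test_that("lineages are valid mutation walks with the recorded fitness", {
  set.seed(54)
  p <- grn_params(n_nodes = 8, n_edges = 12)
  cfg <- evolution_config("evo50", population_size = 40, generations = 25)
  run <- run_evolution(cfg, p)
  lin <- run$lineage
  expect_equal(nrow(lin), 26)
  # recorded fitness equals recomputed fitness of the stored genotype
  for (g in c(1, 10, 26)) {
    expect_equal(lin$fitness[g], grn_fitness(lin$genotype[[g]]),
                 tolerance = 1e-12)
  }
  # consecutive genotypes differ by at most one rewire move
  for (g in 1:25) {
    a <- grnmc:::net_codes(lin$genotype[[g]])
    b <- grnmc:::net_codes(lin$genotype[[g + 1]])
    expect_lte(length(setdiff(b, a)), 1)
    expect_equal(length(b), 12)
    expect_equal(anyDuplicated(b), 0)
  }
})

test_that("max fitness is monotone non-decreasing under both protocols", {
  set.seed(55)
  p <- grn_params(n_nodes = 8, n_edges = 12)
  for (mode in c("evo50", "evo90")) {
    cfg <- evolution_config(mode, population_size = 50, generations = 30)
    run <- run_evolution(cfg, p, store_genotypes = FALSE)
    expect_true(all(diff(run$summary$max_fitness) >= -1e-15))
    expect_equal(nrow(run$summary), 31)
  }
})

test_that("runs are reproducible from the seed", {
  p <- grn_params(n_nodes = 6, n_edges = 8)
  cfg <- evolution_config("evo90", population_size = 30, generations = 10)
  set.seed(77); a <- run_evolution(cfg, p)
  set.seed(77); b <- run_evolution(cfg, p)
  expect_equal(a$lineage$fitness, b$lineage$fitness)
  expect_identical(lapply(a$lineage$genotype, function(n) n$edges),
                   lapply(b$lineage$genotype, function(n) n$edges))
  # generations = 0: the lineage is the best founder
  cfg0 <- evolution_config("evo50", population_size = 10, generations = 0)
  set.seed(78); r0 <- run_evolution(cfg0, p)
  expect_equal(nrow(r0$lineage), 1)
  expect_equal(r0$lineage$fitness[1], r0$summary$max_fitness[1])
})

test_that("a cap of 1.0 reproduces the uncapped trajectory", {
  p <- grn_params(n_nodes = 6, n_edges = 8)
  cfg_free <- evolution_config("evo90", population_size = 30, generations = 15)
  cfg_cap <- evolution_config("evo90", population_size = 30, generations = 15,
                              fitness_cap = 1.0)
  set.seed(88); a <- run_evolution(cfg_free, p, store_genotypes = FALSE)
  set.seed(88); b <- run_evolution(cfg_cap, p, store_genotypes = FALSE)
  expect_equal(a$summary, b$summary)
})

test_that("capped evolution reaches a neutral regime and snapshots capped individuals", {
  # small model where the cap is reached quickly
  set.seed(89)
  p <- grn_params(n_nodes = 6, n_edges = 8)
  run <- run_capped_evolution(p, generations = 60, fitness_cap = 0.2,
                              snapshot_every = 20, population_size = 30)
  expect_false(is.na(run$first_all_capped))
  # once all preserved individuals sit at the cap the preserved set never
  # drops below the cap again (max fitness is the cap thereafter)
  after <- run$summary$max_fitness[(run$first_all_capped + 1):61]
  expect_true(all(abs(after - 0.2) < 1e-15))
  expect_true(!is.null(run$snapshots))
  expect_true(all(run$snapshots$fitness == 0.2))
  late <- run$snapshots[run$snapshots$generation == 60, ]
  expect_gte(nrow(late), 27)  # at least the preserved 90% sit at the cap
})

test_that("replicated runs return one lineage per replicate with genotype filtering", {
  set.seed(90)
  p <- grn_params(n_nodes = 6, n_edges = 8)
  cfg <- evolution_config("evo50", population_size = 20, generations = 8)
  tb <- run_evolution_replicates(3, cfg, p, keep_genotypes_above = 0.05)
  expect_equal(unique(tb$replicate), 1:3)
  expect_equal(nrow(tb), 3 * 9)
  dropped <- tb$fitness < 0.05
  expect_true(all(vapply(tb$genotype[dropped], is.null, TRUE)))
  expect_true(all(!vapply(tb$genotype[!dropped], is.null, TRUE)))
})
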