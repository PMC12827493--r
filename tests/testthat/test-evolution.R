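# Deterministic surrogate fitness used to test the selection machinery
# without growth simulations: rewards large gravitropism, ignores the seed.
stub_fitness <- function(genotype, seed) genotype$gravitrop

test_that("fitness evaluation is deterministic and degenerates to solo growth", {
  soil <- quick_soil()
  f1 <- evaluate_fitness(quick_genotype(), 0, soil = soil, seed = 4,
                         duration = 30)
  f2 <- evaluate_fitness(quick_genotype(), 0, soil = soil, seed = 4,
                         duration = 30)
  expect_identical(f1, f2)
  solo <- run_simulation(quick_genotype(), scenario(0, duration = 30),
                         soil = soil, seed = 4, keep_plants = FALSE)
  expect_equal(f1, solo$shoot[nrow(solo$shoot), 1])
})

test_that("each generation evaluates 2N genotypes and keeps N", {
  run <- evolve(0, pop_size = 15, generations = 3, seed = 1,
                fitness_fn = stub_fitness)
  expect_equal(run$trace$n_evaluated, rep(30L, 3))
  expect_equal(run$trace$n_survivors, rep(15L, 3))
  expect_equal(length(run$population), 15L)
})

test_that("zero mutation collapses the population onto the best founder, then fixes", {
  # duplicate-then-truncate with exact fitness ties resolved older-first:
  # each generation the best value gains copies, so after enough generations
  # the population is homogeneous at the founder maximum and invariant
  zero <- default_mutation_scales() * 0
  run1 <- evolve(0, pop_size = 8, generations = 1, mutation_scales = zero,
                 seed = 2, fitness_fn = stub_fitness)
  # one generation: survivors are duplicated top founders, best value kept
  best <- max(sapply(run1$population, `[[`, "gravitrop"))
  expect_equal(run1$trace$max_fitness[1], best)
  run6 <- evolve(0, pop_size = 8, generations = 6, mutation_scales = zero,
                 seed = 2, fitness_fn = stub_fitness)
  g6 <- sapply(run6$population, `[[`, "gravitrop")
  expect_equal(g6, rep(best, 8))            # converged and invariant
  expect_equal(run6$trace$mean_fitness[6], best)
  expect_equal(run6$trace$max_fitness, rep(best, 6))
})

test_that("ties are broken in favour of older genotypes", {
  # constant fitness: survivors must be exactly the original parents
  const_fit <- function(genotype, seed) 1
  zero <- default_mutation_scales() * 0
  run <- evolve(0, pop_size = 6, generations = 5, mutation_scales = zero,
                seed = 3, fitness_fn = const_fit)
  expect_equal(run$trace$mean_fitness, rep(1, 5))
  # with zero scales and constant fitness, generation after generation the
  # same six founders survive
  run1 <- evolve(0, pop_size = 6, generations = 1, mutation_scales = zero,
                 seed = 3, fitness_fn = const_fit)
  expect_equal(genotypes_to_df(run$population),
               genotypes_to_df(run1$population))
})

test_that("max fitness is non-decreasing under noiseless evaluation", {
  run <- evolve(0, pop_size = 8, generations = 20, seed = 4,
                fitness_fn = stub_fitness)
  expect_true(all(diff(run$trace$max_fitness) >= -1e-12))
  # selection actually improves the surrogate
  expect_gt(run$trace$max_fitness[20], run$trace$max_fitness[1])
})

test_that("evolution runs are reproducible and snapshots are recorded", {
  a <- evolve(0, pop_size = 5, generations = 4, seed = 9,
              fitness_fn = stub_fitness, snapshot_every = 2)
  b <- evolve(0, pop_size = 5, generations = 4, seed = 9,
              fitness_fn = stub_fitness, snapshot_every = 2)
  expect_equal(genotypes_to_df(a$population), genotypes_to_df(b$population))
  expect_equal(names(a$snapshots), c("2", "4"))
  expect_equal(nrow(a$snapshots[["4"]]), 5L)
})

test_that("species extraction keeps the top genotypes of the pooled runs", {
  # synthetic runs with known fitnesses 1..150: survivors must be 121..150
  fake_run <- function(fits) {
    list(population = random_genotype(length(fits)), fitness = fits)
  }
  set.seed(5)
  runs <- lapply(0:4, function(r) fake_run(r * 30 + 1:30))
  sp <- extract_species(runs, "Sp_test", n_select = 30)
  expect_equal(sort(sp$fitness), 121:150)
  expect_true(all(sp$run == 5))
  # brute-force oracle: top 30 of the pooled vector
  pooled <- unlist(lapply(runs, `[[`, "fitness"))
  expect_equal(sort(sp$fitness), sort(pooled, decreasing = TRUE)[30:1])
})

test_that("species extraction breaks ties by run then index", {
  set.seed(6)
  runs <- lapply(1:5, function(r) list(population = random_genotype(10),
                                       fitness = rep(1, 10)))
  sp <- extract_species(runs, "tie", n_select = 12)
  expect_equal(sp$run, c(rep(1L, 10), 2L, 2L))
  expect_equal(sp$index, c(1:10, 1:2))
  expect_error(extract_species(runs[1], "small", n_select = 30), "smaller")
})

test_that("species genotypes always come from the input pool", {
  set.seed(7)
  runs <- lapply(1:2, function(r) list(population = random_genotype(8),
                                       fitness = runif(8)))
  sp <- extract_species(runs, "x", n_select = 5)
  pool_df <- do.call(rbind, lapply(runs, function(r)
    genotypes_to_df(r$population)))
  sp_df <- genotypes_to_df(sp$genotypes)
  for (i in seq_len(nrow(sp_df))) {
    hits <- apply(pool_df, 1, function(row) all(abs(row - sp_df[i, ]) < 1e-12))
    expect_true(any(hits))
  }
})

test_that("genotype PCoA preserves distances and ignores parameter scale", {
  # three points with known pairwise distances embed exactly in 2-d
  set.seed(8)
  base <- genotypes_to_df(random_genotype(3))
  pc <- genotype_pcoa(base)
  d_in <- dist(scale(as.matrix(base)[, apply(base, 2, sd) > 0]))
  d_out <- dist(pc$points)
  expect_equal(as.vector(d_out), as.vector(d_in), tolerance = 1e-6)
  # identical genotypes collapse to the origin
  same <- base[c(1, 1, 1), ]
  pc0 <- genotype_pcoa(same)
  expect_true(all(abs(pc0$points) < 1e-9))
  expect_true(pc0$degenerate)
  # doubling one standardized column leaves coordinates unchanged
  doubled <- base
  doubled$kshoot1 <- doubled$kshoot1 * 2
  pc2 <- genotype_pcoa(doubled)
  expect_equal(abs(pc2$points), abs(pc$points), tolerance = 1e-8)
})
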