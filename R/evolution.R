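#' Fitness of a genotype under a competition scenario
#'
#' Runs a clonal growth simulation: the target plant and its
#' \code{scenario_id} neighbours all carry the same genotype, and the
#' target's final shoot biomass (which includes reproductive organs) is the
#' fitness.
#'
#' @param genotype A [genotype()] object.
#' @param scenario_id Number of clonal neighbours, 0 to 4.
#' @param constants A [model_constants()] object.
#' @param soil A [soil_params()] object.
#' @param seed Integer simulation seed.
#' @param duration Simulation length in days.
#' @param neighbour_distance Distance of the clonal neighbours from the
#'   target (mm).
#' @return Final shoot biomass of the target plant (g).
#' @export
evaluate_fitness <- function(genotype, scenario_id,
                             constants = model_constants(),
                             soil = soil_params(), seed = 1L,
                             duration = 150L, neighbour_distance = 50) {
  scen <- scenario(n_neighbours = scenario_id,
                   neighbour_distance = neighbour_distance,
                   duration = duration)
  res <- run_simulation(genotype, scen, constants, soil, seed,
                        keep_plants = FALSE)
  res$shoot[nrow(res$shoot), 1L]
}

#' Evolve a population of root architecture genotypes
#'
#' Truncation selection over generations. The founder population of
#' \code{pop_size} genotypes is drawn uniformly from the founder sampling
#' ranges. Each generation, every genotype is duplicated with a random
#' Gaussian change in all its parameter values (see [mutate_genotype()]); a
#' growth simulation is then performed for each of the \code{2 * pop_size}
#' genotypes in the enlarged population — parents are re-evaluated every
#' generation, so fitness is noisy — and the \code{pop_size} genotypes with
#' the highest final shoot biomass survive. Ties are broken by genotype
#' creation order (older first).
#'
#' @param scenario_id Competition scenario (number of clonal neighbours,
#'   0 to 4) under which fitness is evaluated.
#' @param pop_size Number of surviving genotypes per generation.
#' @param generations Number of generations.
#' @param mutation_scales Per-parameter Gaussian standard deviations
#'   (default [default_mutation_scales()]).
#' @param constants A [model_constants()] object.
#' @param soil A [soil_params()] object.
#' @param duration Days per growth simulation.
#' @param neighbour_distance Distance of the clonal neighbours from the
#'   target (mm).
#' @param seed Integer run seed; initial sampling, mutation draws and
#'   per-evaluation simulation seeds all derive from it, and evaluations
#'   within a generation are seeded per genotype so they could run in any
#'   order.
#' @param snapshot_every Record a genotype snapshot of the survivors every
#'   this many generations (0 disables snapshots).
#' @param fitness_fn Optional fitness override, a
#'   \code{function(genotype, seed)} returning a scalar; used for surrogate
#'   fitness in tests. Defaults to [evaluate_fitness()] under
#'   \code{scenario_id}.
#' @return A list of class \code{evolution_run}: \code{trace} (data frame
#'   with generation, mean and max survivor fitness, and the population sizes
#'   before and after selection), \code{population} (final survivors, a list
#'   of genotypes), \code{fitness} (their final recorded fitnesses),
#'   \code{snapshots} (list of survivor genotype data frames keyed by
#'   generation), \code{scenario_id} and \code{seed}.
#' @export
evolve <- function(scenario_id, pop_size = 15L, generations = 500L,
                   mutation_scales = default_mutation_scales(),
                   constants = model_constants(), soil = soil_params(),
                   duration = 150L, neighbour_distance = 50, seed = 1L,
                   snapshot_every = 0L, fitness_fn = NULL) {
  stopifnot(pop_size >= 2L, generations >= 1L)
  if (is.null(fitness_fn)) {
    fitness_fn <- function(genotype, eval_seed) {
      evaluate_fitness(genotype, scenario_id, constants, soil,
                       seed = eval_seed, duration = duration,
                       neighbour_distance = neighbour_distance)
    }
  }

  old_rng <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (!is.null(old_rng)) assign(".Random.seed", old_rng, envir = globalenv())
  }, add = TRUE)

  set.seed(derive_seed(seed, 0L))
  population <- random_genotype(pop_size)
  birth <- seq_len(pop_size)          # creation order for tie-breaking
  next_birth <- pop_size + 1L

  trace <- data.frame(generation = seq_len(generations), mean_fitness = NA_real_,
                      max_fitness = NA_real_, n_evaluated = NA_integer_,
                      n_survivors = NA_integer_)
  snapshots <- list()

  for (gen in seq_len(generations)) {
    offspring <- lapply(population, mutate_genotype, scales = mutation_scales)
    pool <- c(population, offspring)
    pool_birth <- c(birth, seq.int(next_birth, length.out = pop_size))
    next_birth <- next_birth + pop_size

    fitness <- vapply(seq_along(pool), function(i) {
      fitness_fn(pool[[i]], derive_seed(seed, gen * 1000L + i))
    }, numeric(1))

    keep <- order(-fitness, pool_birth)[seq_len(pop_size)]
    population <- pool[keep]
    birth <- pool_birth[keep]
    surv_fit <- fitness[keep]

    trace$mean_fitness[gen] <- mean(surv_fit)
    trace$max_fitness[gen] <- max(surv_fit)
    trace$n_evaluated[gen] <- length(pool)
    trace$n_survivors[gen] <- pop_size

    if (snapshot_every > 0L &&
        (gen %% snapshot_every == 0L || gen == generations)) {
      snapshots[[as.character(gen)]] <- genotypes_to_df(population)
    }
  }

  structure(list(trace = trace, population = population,
                 fitness = surv_fit, snapshots = snapshots,
                 scenario_id = scenario_id, seed = seed),
            class = "evolution_run")
}

#' @export
print.evolution_run <- function(x, ...) {
  n <- nrow(x$trace)
  cat(sprintf("<evolution_run> scenario S_%d, %d generations, %d survivors\n",
              x$scenario_id, n, length(x$population)))
  cat(sprintf("mean fitness: %.4g (gen 1) -> %.4g (gen %d)\n",
              x$trace$mean_fitness[1], x$trace$mean_fitness[n], n))
  invisible(x)
}

#' Plot an evolution trace
#'
#' @param x An \code{evolution_run} object.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.evolution_run <- function(x, ...) {
  graphics::matplot(x$trace$generation,
                    cbind(x$trace$mean_fitness, x$trace$max_fitness),
                    type = "l", lty = c(1, 2), col = c(1, 2),
                    xlab = "generation", ylab = "survivor shoot biomass (g)",
                    ...)
  graphics::legend("bottomright", c("mean", "max"), lty = c(1, 2),
                   col = c(1, 2), bty = "n")
}

#' Extract a species from replicate evolutionary runs
#'
#' The final populations of the replicate runs for one scenario are pooled
#' and the genotypes with the highest recorded final shoot biomass are
#' extracted; this genotype group is a theoretical "species". Ties are broken
#' by run id, then by within-run index.
#'
#' @param runs A list of [evolve()] results (replicates of one scenario).
#' @param label Species label, e.g. \code{"Sp_0"}.
#' @param n_select Number of genotypes to extract (default 30).
#' @return A list of class \code{species}: \code{label}, \code{genotypes}
#'   (list of length \code{n_select}), \code{fitness}, and provenance
#'   columns \code{run} and \code{index}.
#' @export
extract_species <- function(runs, label, n_select = 30L) {
  pool <- data.frame(
    run = rep(seq_along(runs), vapply(runs, function(r) length(r$population),
                                      integer(1))),
    index = unlist(lapply(runs, function(r) seq_along(r$population))),
    fitness = unlist(lapply(runs, `[[`, "fitness"))
  )
  if (nrow(pool) < n_select)
    stop(sprintf("pooled population (%d) smaller than n_select (%d)",
                 nrow(pool), n_select))
  genotypes <- unlist(lapply(runs, `[[`, "population"), recursive = FALSE)
  keep <- order(-pool$fitness, pool$run, pool$index)[seq_len(n_select)]
  structure(list(label = label, genotypes = genotypes[keep],
                 fitness = pool$fitness[keep], run = pool$run[keep],
                 index = pool$index[keep]),
            class = "species")
}

#' @export
print.species <- function(x, ...) {
  cat(sprintf("<species %s> %d genotypes, fitness %.4g - %.4g g\n",
              x$label, length(x$genotypes), min(x$fitness), max(x$fitness)))
  invisible(x)
}

#' Principal coordinates analysis of genotype parameter values
#'
#' Classical multidimensional scaling (via [stats::cmdscale()]) on Euclidean
#' distances between standardized parameter vectors: each parameter column is
#' z-scored (zero-variance columns contribute nothing), so the ordination is
#' invariant to the parameters' units.
#'
#' @param genotype_df A data frame of genotype parameter values (one row per
#'   genotype), e.g. from [genotypes_to_df()].
#' @param k Number of coordinates to return (default 2).
#' @return A list with \code{points} (n x k coordinate matrix),
#'   \code{eig_share} (shares of the positive eigenvalues) and
#'   \code{degenerate} (\code{TRUE} when fewer than \code{k} positive
#'   eigenvalues exist).
#' @export
genotype_pcoa <- function(genotype_df, k = 2L) {
  x <- as.matrix(genotype_df)
  stopifnot(nrow(x) >= 3L)
  sds <- apply(x, 2L, stats::sd)
  x <- scale(x, center = TRUE, scale = ifelse(sds > 0, sds, 1))
  x[, sds == 0] <- 0
  mds <- suppressWarnings(stats::cmdscale(stats::dist(x), k = k, eig = TRUE))
  pos <- mds$eig[mds$eig > 1e-8]
  pts <- mds$points
  if (ncol(pts) < k)
    pts <- cbind(pts, matrix(0, nrow(pts), k - ncol(pts)))
  list(points = pts,
       eig_share = if (length(pos)) pos / sum(pos) else numeric(0),
       degenerate = length(pos) < k)
}
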