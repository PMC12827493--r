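#' Build the factorial competition experiment design
#'
#' Crosses the target species, the neighbour species and the neighbour count
#' (1 to 4), plus one alone condition per target species: with 5 species this
#' enumerates (5 x 5 x 4) + 5 = 105 conditions. Per-replicate simulation
#' seeds are derived deterministically from the base seed.
#'
#' @param species_labels Character vector of species labels (no duplicates).
#' @param replicates Replicates per condition.
#' @param base_seed Integer base seed.
#' @return An object of class \code{experiment_design}: a list with
#'   \code{conditions} (data frame with \code{condition}, \code{target},
#'   \code{neighbour} — \code{NA} for alone — and \code{n_neighbours}),
#'   \code{replicates} and \code{base_seed}.
#' @export
build_design <- function(species_labels, replicates = 100L, base_seed = 1L) {
  if (anyDuplicated(species_labels)) stop("duplicate species labels")
  stopifnot(length(species_labels) >= 1L, replicates >= 1L)
  alone <- data.frame(target = species_labels, neighbour = NA_character_,
                      n_neighbours = 0L)
  comp <- expand.grid(n_neighbours = 1:4, neighbour = species_labels,
                      target = species_labels, stringsAsFactors = FALSE)
  cond <- rbind(alone, comp[, c("target", "neighbour", "n_neighbours")])
  cond <- cond[order(cond$target, !is.na(cond$neighbour), cond$neighbour,
                     cond$n_neighbours), ]
  cond <- data.frame(condition = seq_len(nrow(cond)), cond,
                     row.names = NULL)
  structure(list(conditions = cond, replicates = as.integer(replicates),
                 base_seed = as.integer(base_seed)),
            class = "experiment_design")
}

# Deterministic seed of one (condition, replicate) cell.
condition_seed <- function(design, condition, replicate) {
  derive_seed(design$base_seed, condition * 100000L + replicate)
}

#' Run the factorial competition experiments
#'
#' For every condition and replicate, the target plant and each neighbour
#' independently draw a genotype uniformly from their species' pool; the
#' draws use a stream derived from the replicate seed that is separate from
#' the plants' growth streams, so neighbour draws never consume the target's
#' randomness. A growth simulation is then run and the target's final shoot
#' biomass recorded.
#'
#' @param design An [build_design()] object.
#' @param species_pools Named list of species genotype pools: each element is
#'   either an [extract_species()] object or a plain list of genotypes; names
#'   must cover the design's species labels.
#' @param constants A [model_constants()] object.
#' @param soil A [soil_params()] object.
#' @param duration Days per simulation.
#' @param neighbour_distance Neighbour distance (mm).
#' @return A data frame of records: \code{condition}, \code{target},
#'   \code{neighbour}, \code{n_neighbours}, \code{replicate}, \code{seed},
#'   \code{shoot_biomass} (g, the target's final shoot biomass).
#' @export
run_experiments <- function(design, species_pools,
                            constants = model_constants(),
                            soil = soil_params(), duration = 150L,
                            neighbour_distance = 50) {
  pools <- lapply(species_pools, function(p) {
    if (inherits(p, "species")) p$genotypes else p
  })
  cond <- design$conditions
  labels <- unique(c(cond$target, stats::na.omit(cond$neighbour)))
  if (!all(labels %in% names(pools)))
    stop("species_pools is missing: ",
         paste(setdiff(labels, names(pools)), collapse = ", "))
  if (any(vapply(pools, length, integer(1)) == 0L)) stop("empty species pool")

  out <- vector("list", nrow(cond) * design$replicates)
  r <- 0L
  for (ci in seq_len(nrow(cond))) {
    k <- cond$n_neighbours[ci]
    scen <- scenario(n_neighbours = k, neighbour_distance = neighbour_distance,
                     duration = duration)
    for (rep_i in seq_len(design$replicates)) {
      seed <- condition_seed(design, cond$condition[ci], rep_i)
      genotypes <- draw_plant_genotypes(pools, cond$target[ci],
                                        cond$neighbour[ci], k, seed)
      res <- run_simulation(genotypes, scen, constants, soil, seed,
                            keep_plants = FALSE)
      r <- r + 1L
      out[[r]] <- data.frame(condition = cond$condition[ci],
                             target = cond$target[ci],
                             neighbour = cond$neighbour[ci],
                             n_neighbours = k, replicate = rep_i,
                             seed = seed,
                             shoot_biomass = res$shoot[nrow(res$shoot), 1L])
    }
  }
  do.call(rbind, out)
}

# Uniform genotype draws for the target and each neighbour, on a stream
# separate from the growth streams (index offset far above plant ids).
draw_plant_genotypes <- function(pools, target, neighbour, k, seed) {
  old_rng <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (!is.null(old_rng)) assign(".Random.seed", old_rng, envir = globalenv())
  }, add = TRUE)
  set.seed(derive_seed(seed, 999983L))
  draw <- function(label) {
    pool <- pools[[label]]
    pool[[sample.int(length(pool), 1L)]]
  }
  c(list(draw(target)),
    if (k > 0L) lapply(seq_len(k), function(i) draw(neighbour)))
}

#' Summarize experiment records per condition
#'
#' @param records A [run_experiments()] data frame.
#' @return One row per condition with \code{n}, \code{mean}, \code{q25} and
#'   \code{q75} of the target's final shoot biomass. Quantiles use the
#'   default linear-interpolation convention of [stats::quantile()] (type 7).
#' @export
summarize_experiments <- function(records) {
  stopifnot(nrow(records) >= 1L)
  keys <- c("condition", "target", "neighbour", "n_neighbours")
  grp <- records[!duplicated(records$condition), keys]
  grp <- grp[order(grp$condition), , drop = FALSE]
  stat <- function(f) {
    v <- tapply(records$shoot_biomass, records$condition, f)
    as.numeric(v[as.character(grp$condition)])
  }
  data.frame(grp,
             n = stat(length),
             mean = stat(mean),
             q25 = stat(function(x) stats::quantile(x, 0.25, names = FALSE)),
             q75 = stat(function(x) stats::quantile(x, 0.75, names = FALSE)),
             row.names = NULL)
}

#' Competitive effect and response indices per species
#'
#' Ratio-to-alone indices over the densest (four-neighbour) conditions. The
#' competitive response of a target species T is the mean over neighbour
#' species N of its biomass with four N neighbours divided by its biomass
#' alone (higher = more tolerant of competition). The competitive effect of a
#' neighbour species N is the mean over target species T of one minus that
#' ratio (higher = more suppressive). When competition only reduces biomass
#' both indices lie in [0, 1].
#'
#' @param summary A [summarize_experiments()] table including the alone
#'   conditions.
#' @return A data frame with \code{species}, \code{response}, \code{effect}
#'   and \code{alone_biomass} (the species' growth potential, g).
#' @export
competition_indices <- function(summary) {
  alone <- summary[summary$n_neighbours == 0L, ]
  if (nrow(alone) == 0L) stop("summary lacks the alone baseline conditions")
  base <- stats::setNames(alone$mean, alone$target)
  dense <- summary[summary$n_neighbours == 4L, ]
  species <- sort(unique(summary$target))
  ratio <- dense$mean / base[dense$target]
  data.frame(
    species = species,
    response = vapply(species, function(s)
      mean(ratio[dense$target == s]), numeric(1)),
    effect = vapply(species, function(s)
      mean(1 - ratio[dense$neighbour == s]), numeric(1)),
    alone_biomass = as.numeric(base[species]),
    row.names = NULL)
}

#' Plot a competition experiment summary
#'
#' One panel per target species: mean target shoot biomass (with the
#' 25th-75th quantile band) against the number of neighbours, one line per
#' neighbour species; the alone condition is every line's zero-neighbour
#' point.
#'
#' @param summary A [summarize_experiments()] table.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the summary.
#' @export
plot_experiment_summary <- function(summary, ...) {
  targets <- sort(unique(summary$target))
  neighbours <- sort(unique(stats::na.omit(summary$neighbour)))
  old <- graphics::par(mfrow = c(1, length(targets)), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  cols <- stats::setNames(seq_along(neighbours) + 1L, neighbours)
  for (tg in targets) {
    sub <- summary[summary$target == tg, ]
    alone <- sub[sub$n_neighbours == 0, ]
    graphics::plot(NA, xlim = c(0, 4), ylim = c(0, max(sub$q75)),
                   xlab = "neighbours", ylab = "target shoot biomass (g)",
                   main = tg, ...)
    for (nb in neighbours) {
      line <- rbind(alone[, c("n_neighbours", "mean", "q25", "q75")],
                    sub[!is.na(sub$neighbour) & sub$neighbour == nb,
                        c("n_neighbours", "mean", "q25", "q75")])
      line <- line[order(line$n_neighbours), ]
      graphics::polygon(c(line$n_neighbours, rev(line$n_neighbours)),
                        c(line$q25, rev(line$q75)), border = NA,
                        col = grDevices::adjustcolor(cols[[nb]], 0.2))
      graphics::lines(line$n_neighbours, line$mean, col = cols[[nb]], lwd = 2)
    }
    if (tg == targets[1L])
      graphics::legend("topright", legend = neighbours, col = cols,
                       lwd = 2, bty = "n", title = "neighbour")
  }
  invisible(summary)
}
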