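#' Competition scenario
#'
#' A target plant grows in the centre of the world, alone or surrounded by
#' up to four neighbours placed at a fixed distance.
#'
#' @param n_neighbours Number of neighbours, 0 to 4.
#' @param neighbour_distance Distance of each neighbour from the target (mm).
#' @param duration Simulation length in days.
#' @return An object of class \code{scenario}.
#' @export
scenario <- function(n_neighbours = 0L, neighbour_distance = 50,
                     duration = 150L) {
  n_neighbours <- as.integer(n_neighbours)
  stopifnot(n_neighbours >= 0L, n_neighbours <= 4L, neighbour_distance > 0,
            duration >= 0L)
  structure(list(n_neighbours = n_neighbours,
                 neighbour_distance = neighbour_distance,
                 duration = as.integer(duration)),
            class = "scenario")
}

#' Place the plants of a scenario
#'
#' The target is placed at the horizontal centre of the world; the k
#' neighbours occupy the first k of four fixed compass positions (N, E, S, W,
#' with north towards negative y) at \code{neighbour_distance} from the
#' target. Deterministic placement removes positional variance from
#' between-scenario comparisons.
#'
#' @param scen A [scenario()] object.
#' @param soil A [soil_params()] object.
#' @return An (n_neighbours + 1) x 3 matrix of base positions (mm), target
#'   first; all rows have z = 0.
#' @export
place_plants <- function(scen, soil) {
  wx <- soil$nx * soil$voxel_side
  wy <- soil$ny * soil$voxel_side
  d <- scen$neighbour_distance
  if (min(wx, wy) <= 2 * d)
    stop("world horizontal extent must exceed twice the neighbour distance")
  centre <- c(wx / 2, wy / 2, 0)
  offsets <- rbind(c(0, -d, 0), c(d, 0, 0), c(0, d, 0), c(-d, 0, 0))
  k <- scen$n_neighbours
  pos <- rbind(centre, sweep(offsets[seq_len(k), , drop = FALSE], 2L,
                             centre, `+`))
  dimnames(pos) <- NULL
  pos
}

#' Run a multi-plant growth simulation
#'
#' Executes the daily loop for a set of plants sharing one soil grid. Each
#' day the soil processes run in the configured order (recharge, evaporation,
#' diffusion by default), then all plants' segment demands are pooled into a
#' single rationed extraction (so inter-plant competition is simultaneous and
#' symmetric), and finally each plant converts its delivered water into
#' biomass, splits it between shoot and root, and grows its root system.
#'
#' @param genotypes A single [genotype()] (cloned to every plant) or a list
#'   of genotypes, one per plant; the first plant is the target.
#' @param scen A [scenario()] object; the number of plants is
#'   \code{n_neighbours + 1}.
#' @param constants A [model_constants()] object.
#' @param soil A [soil_params()] object.
#' @param seed Integer run seed; per-plant RNG streams are derived from it
#'   unless \code{plant_seeds} is given.
#' @param positions Optional matrix of base positions (default
#'   [place_plants()]).
#' @param plant_seeds Optional integer vector of per-plant stream seeds.
#' @param step_order Character vector ordering the daily soil processes
#'   before uptake; any subset/permutation of
#'   \code{c("recharge", "evaporate", "diffuse")}.
#' @param keep_plants Keep the final plant structures in the result.
#' @return An object of class \code{sim_result}: a list with \code{shoot} and
#'   \code{root} biomass matrices ((duration + 1) rows, day 0 first, one
#'   column per plant), \code{plants}, final \code{grid}, \code{seed}, and a
#'   water/biomass \code{ledger} with cumulative recharged, evaporated and
#'   extracted water (mm^3), per-plant cumulative allocable biomass (g) and
#'   the initial grid water.
#' @export
run_simulation <- function(genotypes, scen = scenario(),
                           constants = model_constants(),
                           soil = soil_params(), seed = 1L,
                           positions = NULL, plant_seeds = NULL,
                           step_order = c("recharge", "evaporate", "diffuse"),
                           keep_plants = TRUE) {
  np <- scen$n_neighbours + 1L
  if (inherits(genotypes, "genotype")) genotypes <- rep(list(genotypes), np)
  stopifnot(length(genotypes) == np,
            all(step_order %in% c("recharge", "evaporate", "diffuse")))
  if (is.null(positions)) positions <- place_plants(scen, soil)
  stopifnot(nrow(positions) == np)
  if (is.null(plant_seeds))
    plant_seeds <- vapply(seq_len(np), function(i) derive_seed(seed, i),
                          integer(1))

  plants <- lapply(seq_len(np), function(i) {
    init_plant(genotypes[[i]], positions[i, ], constants, id = i,
               seed = plant_seeds[i])
  })
  grid <- soil_grid(soil, "full")

  dur <- scen$duration
  shoot <- matrix(0, dur + 1L, np)
  root <- matrix(segment_cost(constants), dur + 1L, np)
  ledger <- list(initial_water = sum(grid$water), recharged = 0,
                 evaporated = 0, extracted = 0,
                 allocable = numeric(np))

  for (day in seq_len(dur)) {
    for (op in step_order) {
      if (op == "recharge") {
        grid <- recharge(grid, day)
        ledger$recharged <- ledger$recharged + attr(grid, "added")
      } else if (op == "evaporate") {
        grid <- evaporate(grid)
        ledger$evaporated <- ledger$evaporated + attr(grid, "removed")
      } else {
        grid <- diffuse(grid)
      }
    }

    dem <- lapply(plants, water_demands, soil = soil)
    nseg <- vapply(dem, function(d) length(d$demand), integer(1))
    ex <- extract_water(grid, unlist(lapply(dem, `[[`, "voxel")),
                        unlist(lapply(dem, `[[`, "demand")))
    grid <- ex$grid
    ledger$extracted <- ledger$extracted + sum(ex$uptake)

    off <- cumsum(c(0L, nseg))
    for (i in seq_len(np)) {
      up <- ex$uptake[(off[i] + 1L):off[i + 1L]]
      allocable <- water_to_growth(delivered_water(up, plants[[i]]), constants)
      ledger$allocable[i] <- ledger$allocable[i] + allocable
      f <- shoot_fraction(allocable, plants[[i]]$genotype)
      plants[[i]]$shoot_biomass <- plants[[i]]$shoot_biomass + f * allocable
      plants[[i]] <- grow_roots(plants[[i]], (1 - f) * allocable, constants)
      shoot[day + 1L, i] <- plants[[i]]$shoot_biomass
      root[day + 1L, i] <- plants[[i]]$root_biomass
    }
  }

  structure(list(shoot = shoot, root = root,
                 plants = if (keep_plants) plants else NULL,
                 grid = grid, seed = seed, plant_seeds = plant_seeds,
                 ledger = c(ledger, list(
                   final_water = sum(grid$water),
                   budget_unused = vapply(plants, `[[`, numeric(1),
                                          "cum_budget_unused"),
                   carry_biomass = vapply(plants, function(p) {
                     sum(p$br_carry) * segment_cost(constants) /
                       constants$segment_length
                   }, numeric(1))))),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  np <- ncol(x$shoot)
  cat(sprintf("<sim_result> %d plant(s), %d day(s)\n", np, nrow(x$shoot) - 1L))
  cat("final shoot biomass (g):",
      paste(signif(x$shoot[nrow(x$shoot), ], 4), collapse = ", "), "\n")
  invisible(x)
}

#' Check the water and biomass ledgers of a simulation
#'
#' Water closure: initial grid water + recharged - evaporated - extracted
#' must equal the final grid water. Biomass closure, per plant: shoot gain +
#' root gain + unused root budget + carried-over funded length (as biomass)
#' must equal the cumulative allocable biomass.
#'
#' @param result A [run_simulation()] result.
#' @return A list with \code{water_relative_error} and per-plant
#'   \code{biomass_relative_error}.
#' @export
ledger_errors <- function(result) {
  l <- result$ledger
  expected <- l$initial_water + l$recharged - l$evaporated - l$extracted
  werr <- abs(expected - l$final_water) / max(l$initial_water, 1)
  n <- nrow(result$shoot)
  shoot_gain <- result$shoot[n, ]
  root_gain <- result$root[n, ] - result$root[1L, ]
  lhs <- shoot_gain + root_gain + l$budget_unused + l$carry_biomass
  berr <- abs(lhs - l$allocable) / pmax(l$allocable, 1e-12)
  list(water_relative_error = werr, biomass_relative_error = berr)
}
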