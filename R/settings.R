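#' Reference study configurations
#'
#' Bundles the configuration of the competition study at two problem sizes.
#' \code{"full"} is the headline configuration: the 10 x 10 x 70 voxel world,
#' 150-day simulations, 50 mm neighbour spacing, populations of 15 genotypes
#' evolved for 500 generations in 5 replicate runs, species of 30 genotypes
#' and 100 experiment replicates. \code{"desk"} is a reduced configuration
#' for interactive use, examples and routine checks: an 8 x 8 x 15 voxel
#' world, 80-day simulations, populations of 8 evolved for 50 generations in
#' 3 replicate runs, species of 10 genotypes and 6 experiment replicates.
#' Because desk-scale plants only reach roughly 15-20 mm horizontally, the
#' neighbour spacing scales down to 20 mm so that root systems overlap the
#' way full-scale ones do at 50 mm; the competition mechanism (rationed
#' uptake in shared voxels) is unchanged.
#'
#' @param scale \code{"full"} or \code{"desk"}.
#' @return A list with \code{soil} ([soil_params()]), \code{duration} (days),
#'   \code{neighbour_distance} (mm), \code{pop_size}, \code{generations},
#'   \code{replicates} (evolutionary runs per scenario), \code{species_size}
#'   and \code{experiment_replicates}.
#' @export
study_settings <- function(scale = c("full", "desk")) {
  scale <- match.arg(scale)
  if (scale == "full") {
    list(soil = soil_params(), duration = 150L, neighbour_distance = 50,
         pop_size = 15L, generations = 500L, replicates = 5L,
         species_size = 30L, experiment_replicates = 100L)
  } else {
    list(soil = soil_params(nx = 8, ny = 8, nz = 15), duration = 80L,
         neighbour_distance = 20, pop_size = 8L, generations = 50L,
         replicates = 3L, species_size = 10L, experiment_replicates = 6L)
  }
}

#' Run the full species-building pipeline for one scenario
#'
#' Convenience wrapper: performs the replicate evolutionary runs for one
#' competition scenario and extracts the species from their pooled final
#' populations.
#'
#' @param scenario_id Number of clonal neighbours (0 to 4).
#' @param settings A [study_settings()] list.
#' @param seed Base seed; replicate r uses seed + r - 1.
#' @param label Species label (default \code{"Sp_<scenario_id>"}).
#' @return A list with \code{runs} (the [evolve()] results) and
#'   \code{species} (the [extract_species()] result).
#' @export
build_species <- function(scenario_id, settings = study_settings("desk"),
                          seed = 1L, label = sprintf("Sp_%d", scenario_id)) {
  runs <- lapply(seq_len(settings$replicates), function(r) {
    evolve(scenario_id,
           pop_size = settings$pop_size,
           generations = settings$generations,
           soil = settings$soil, duration = settings$duration,
           neighbour_distance = settings$neighbour_distance,
           seed = seed + r - 1L)
  })
  list(runs = runs,
       species = extract_species(runs, label,
                                 n_select = settings$species_size))
}
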