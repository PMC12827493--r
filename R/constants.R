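#' Model constants
#'
#' General constant parameters of the growth model, shared by every plant in
#' every simulation (unlike the evolvable [genotype()] parameters).
#'
#' @param water_to_biomass Biomass obtained per volume of water taken up
#'   (g mm^-3).
#' @param biomass_per_volume Biomass per unit of root tissue volume
#'   (g mm^-3).
#' @param water_trans_efficiency Per-mm water transport loss along the root
#'   path from a segment to the plant base, in [0, 1): a segment at path
#'   length L mm delivers a fraction \code{(1 - water_trans_efficiency)^L}
#'   of its uptake. Zero recovers a plain sum over segments.
#' @param water_uptake_per_root_length Potential water uptake per mm of root
#'   length per day (mm^3 mm^-1).
#' @param max_elongation_rate Maximum daily elongation of a branch tip
#'   (mm day^-1).
#' @param segment_length Length of a root segment (mm); all segments share
#'   this length.
#' @param root_radius Radius of the root cylinder used to convert segment
#'   length into tissue volume and hence biomass cost (mm).
#' @param branch_probability Probability of lateral initiation at a new
#'   segment junction beyond the base zone (within the base zone the
#'   genotype's \code{basezonep} applies).
#' @return An object of class \code{model_constants}.
#' @export
model_constants <- function(water_to_biomass = 1e-5,
                            biomass_per_volume = 1e-3,
                            water_trans_efficiency = 0.002,
                            water_uptake_per_root_length = 10,
                            max_elongation_rate = 5,
                            segment_length = 2,
                            root_radius = 0.5,
                            branch_probability = 1) {
  stopifnot(water_to_biomass > 0, biomass_per_volume >= 0,
            water_trans_efficiency >= 0, water_trans_efficiency < 1,
            water_uptake_per_root_length >= 0, max_elongation_rate > 0,
            segment_length > 0, root_radius > 0,
            branch_probability >= 0, branch_probability <= 1)
  structure(list(water_to_biomass = water_to_biomass,
                 biomass_per_volume = biomass_per_volume,
                 water_trans_efficiency = water_trans_efficiency,
                 water_uptake_per_root_length = water_uptake_per_root_length,
                 max_elongation_rate = max_elongation_rate,
                 segment_length = segment_length,
                 root_radius = root_radius,
                 branch_probability = branch_probability),
            class = "model_constants")
}

#' Biomass cost of one root segment
#'
#' A segment is costed as a cylinder: pi * root_radius^2 * segment_length *
#' biomass_per_volume grams. Cost is linear in length, which is the only
#' property the growth dynamics rely on.
#'
#' @param constants A [model_constants()] object.
#' @return Cost in grams.
#' @export
segment_cost <- function(constants) {
  pi * constants$root_radius^2 * constants$segment_length *
    constants$biomass_per_volume
}
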