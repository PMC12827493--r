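#' @title Root architecture genotypes
#' @description A genotype is the set of nine evolvable architecture
#'   parameters that determine how a plant's root system develops. The
#'   parameters are constant within a plant's lifetime but evolve across
#'   generations.
#' @name genotype
NULL

# Hard limits and initial sampling ranges for the nine evolvable parameters.
# limits: lo/hi are hard bounds enforced at construction and after mutation
# (NA = unbounded); sampling: the uniform range used to draw founder
# genotypes. maxorder is integer-valued.
.genotype_table <- data.frame(
  param    = c("rotang", "branchang", "gravitrop", "basezonelength",
               "basezonep", "maxorder", "orderweightings",
               "kshoot1", "kshoot2"),
  lo       = c(NA, NA, 0, 0, 0, 2, 0, NA, NA),
  hi       = c(NA, NA, NA, NA, 1, 9, NA, NA, NA),
  sample_lo = c(0, 0, 0, 5, 0, 2, 0.5, -5, -0.1),
  sample_hi = c(1.5, 1.5, 0.3, 30, 1, 8, 2, 5, 0.03),
  stringsAsFactors = FALSE
)

#' Names of the evolvable architecture parameters
#'
#' @return Character vector of the nine parameter names.
#' @export
genotype_params <- function() .genotype_table$param

#' Hard limits and initial sampling ranges of the architecture parameters
#'
#' @return A data frame with columns \code{param}, \code{lo}, \code{hi}
#'   (hard limits, \code{NA} = unbounded) and \code{sample_lo},
#'   \code{sample_hi} (uniform founder sampling range).
#' @export
genotype_ranges <- function() .genotype_table

#' Construct a root architecture genotype
#'
#' @param rotang Horizontal rotation angle from one lateral to the next
#'   (radians): the phyllotactic phase increment around the parent axis.
#' @param branchang Vertical rotation angle of a new lateral away from its
#'   parent axis (radians).
#' @param gravitrop Strength of gravitropism (>= 0): the downward pull added
#'   to the tip heading at every new segment.
#' @param basezonelength Length of the base zone (mm, >= 0): the region of a
#'   branch near its origin within which lateral initiation is governed by
#'   \code{basezonep}.
#' @param basezonep Probability of branching within the base zone, in [0, 1].
#' @param maxorder Maximum root branching order, integer in [2, 9]; laterals
#'   never exceed this order.
#' @param orderweightings Growth priority per root order (>= 0): a tip of
#'   order k receives weight \code{orderweightings^k} when the root biomass
#'   budget is shared, so values > 1 favour high-order laterals and values
#'   < 1 favour the main axes.
#' @param kshoot1,kshoot2 Shoot allocation coefficients: the fraction of the
#'   day's allocable biomass sent above ground is
#'   \code{plogis(kshoot1 + kshoot2 * allocable_mg)}.
#' @return An object of class \code{genotype} (a named list).
#' @export
genotype <- function(rotang = 0.5, branchang = 0.8, gravitrop = 0.1,
                     basezonelength = 10, basezonep = 0.5, maxorder = 4,
                     orderweightings = 1, kshoot1 = 0, kshoot2 = 0) {
  g <- list(rotang = rotang, branchang = branchang, gravitrop = gravitrop,
            basezonelength = basezonelength, basezonep = basezonep,
            maxorder = as.integer(round(maxorder)),
            orderweightings = orderweightings,
            kshoot1 = kshoot1, kshoot2 = kshoot2)
  validate_genotype(g)
  structure(g, class = "genotype")
}

validate_genotype <- function(g) {
  tab <- .genotype_table
  for (i in seq_len(nrow(tab))) {
    v <- g[[tab$param[i]]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop(sprintf("parameter '%s' must be a finite scalar", tab$param[i]))
    if (!is.na(tab$lo[i]) && v < tab$lo[i])
      stop(sprintf("parameter '%s' = %g below its limit %g",
                   tab$param[i], v, tab$lo[i]))
    if (!is.na(tab$hi[i]) && v > tab$hi[i])
      stop(sprintf("parameter '%s' = %g above its limit %g",
                   tab$param[i], v, tab$hi[i]))
  }
  invisible(g)
}

#' @export
print.genotype <- function(x, ...) {
  cat("<genotype>\n")
  for (p in genotype_params()) cat(sprintf("  %-16s %g\n", p, x[[p]]))
  invisible(x)
}

#' @export
as.data.frame.genotype <- function(x, ...) {
  as.data.frame(unclass(x)[genotype_params()])
}

#' Bind a list of genotypes into a data frame
#'
#' @param genotypes A list of [genotype()] objects.
#' @return A data frame with one row per genotype and one column per
#'   parameter.
#' @export
genotypes_to_df <- function(genotypes) {
  do.call(rbind, lapply(genotypes, as.data.frame))
}

#' Draw random founder genotypes
#'
#' Parameters are sampled uniformly and independently within the founder
#' sampling ranges (see [genotype_ranges()]); \code{maxorder} is rounded to
#' the nearest integer. Uses the current RNG state.
#'
#' @param n Number of genotypes to draw.
#' @return A list of \code{n} [genotype()] objects.
#' @export
random_genotype <- function(n = 1L) {
  tab <- .genotype_table
  lapply(seq_len(n), function(i) {
    vals <- stats::runif(nrow(tab), tab$sample_lo, tab$sample_hi)
    names(vals) <- tab$param
    do.call(genotype, as.list(vals))
  })
}

#' Default mutation scales
#'
#' Per-parameter standard deviations of the Gaussian mutation kernel, set to
#' a fixed fraction of each parameter's founder sampling-range width.
#'
#' @param fraction Fraction of the sampling-range width (default 0.05).
#' @return Named numeric vector of standard deviations.
#' @export
default_mutation_scales <- function(fraction = 0.05) {
  tab <- .genotype_table
  stats::setNames((tab$sample_hi - tab$sample_lo) * fraction, tab$param)
}

#' Mutate a genotype
#'
#' Every parameter is perturbed by an independent Gaussian draw with its own
#' standard deviation, then clipped to the hard limits; \code{maxorder} is
#' rounded to the nearest integer within [2, 9]. Unbounded parameters
#' (\code{rotang}, \code{branchang}, \code{kshoot1}, \code{kshoot2}) are not
#' clipped. Uses the current RNG state.
#'
#' @param g A [genotype()] object.
#' @param scales Named vector of per-parameter standard deviations
#'   (default [default_mutation_scales()]).
#' @return The mutated [genotype()].
#' @export
mutate_genotype <- function(g, scales = default_mutation_scales()) {
  tab <- .genotype_table
  vals <- unlist(unclass(g)[tab$param])
  sd <- scales[tab$param]
  vals <- vals + stats::rnorm(length(vals), 0, sd)
  vals <- pmax(vals, ifelse(is.na(tab$lo), -Inf, tab$lo))
  vals <- pmin(vals, ifelse(is.na(tab$hi), Inf, tab$hi))
  do.call(genotype, as.list(vals))
}

#' Serialize genotypes to JSON
#'
#' Genotypes are written as an array of records keyed by the parameter names.
#'
#' @param genotypes A list of [genotype()] objects.
#' @param path Optional output path; if \code{NULL} the JSON string is
#'   returned.
#' @return The path (invisibly) or a JSON string.
#' @export
write_genotypes_json <- function(genotypes, path = NULL) {
  df <- genotypes_to_df(genotypes)
  if (is.null(path))
    return(jsonlite::toJSON(df, digits = NA, auto_unbox = TRUE))
  jsonlite::write_json(df, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read genotypes from JSON
#'
#' @param path Path to a JSON file written by [write_genotypes_json()], or a
#'   JSON string.
#' @return A list of [genotype()] objects.
#' @export
read_genotypes_json <- function(path) {
  df <- jsonlite::fromJSON(path)
  lapply(seq_len(nrow(df)), function(i) do.call(genotype, as.list(df[i, ])))
}
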