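#' @title Plants with explicit segment-based root systems
#' @description A plant has two biomass compartments: an above-ground shoot
#'   biomass scalar and a below-ground root system with explicit
#'   three-dimensional structure. The root system is a set of branches, each
#'   a chain of fixed-length linear segments; growth adds segments at branch
#'   tips and initiates laterals at new segment junctions. The z axis points
#'   downward from the soil surface.
#' @name plant
NULL

# --- small vector helpers -------------------------------------------------

vnorm <- function(v) sqrt(sum(v * v))

vcross <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

# Initial heading of a lateral: the parent axis `a` (unit) tilted by
# `branchang` radians towards a reference perpendicular, then rotated about
# `a` by the phyllotactic phase (radians). The reference perpendicular is
# chosen deterministically from `a` so growth is reproducible.
lateral_heading <- function(a, branchang, phase) {
  if (abs(a[1L]) + abs(a[2L]) < 1e-12) {
    u0 <- c(1, 0, 0)
  } else {
    u0 <- c(a[2L], -a[1L], 0)
    u0 <- u0 / vnorm(u0)
  }
  v0 <- vcross(a, u0)
  cos(branchang) * a + sin(branchang) * (cos(phase) * u0 + sin(phase) * v0)
}

# Capture a fresh RNG state for a plant's private stream without disturbing
# the caller's stream. Each plant draws its branching randomness from its own
# stream, so plants are reproducible independently of scheduling order.
make_rng_state <- function(seed) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  set.seed(seed)
  state <- get(".Random.seed", envir = globalenv())
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  state
}

# Combine a run seed and a stream index into a derived seed < 2^31.
derive_seed <- function(seed, index) {
  v <- (as.double(seed) %% 2147483647) * 48271 + as.double(index) * 7919
  as.integer(v %% 2147483646) + 1L
}

# --- construction ---------------------------------------------------------

#' Initialise a plant
#'
#' A plant starts with no shoot biomass and a single root branch of order 0
#' holding one segment heading straight down from the base.
#'
#' @param genotype A [genotype()] object.
#' @param base Numeric length-3 base position (mm); must lie on the soil
#'   surface (z = 0).
#' @param constants A [model_constants()] object.
#' @param id Plant identifier (integer).
#' @param seed Seed for the plant's private branching RNG stream.
#' @return An object of class \code{plant}.
#' @export
init_plant <- function(genotype, base = c(0, 0, 0),
                       constants = model_constants(), id = 1L, seed = 1L) {
  validate_genotype(genotype)
  stopifnot(length(base) == 3L, base[3L] == 0)
  sl <- constants$segment_length
  tip <- base + c(0, 0, sl)
  structure(list(
    id = as.integer(id),
    genotype = genotype,
    constants = constants,
    base = as.double(base),
    shoot_biomass = 0,
    root_biomass = segment_cost(constants),
    # per-segment state (n x 3 matrices / length-n vectors)
    seg_start = matrix(base, 1L, 3L),
    seg_end = matrix(tip, 1L, 3L),
    seg_branch = 1L,
    seg_path = 0,                  # path length (mm) from proximal end to base
    # per-branch state
    br_parent = NA_integer_,
    br_order = 0L,
    br_heading = matrix(c(0, 0, 1), 1L, 3L),
    br_tip = matrix(tip, 1L, 3L),
    br_dist = sl,                  # length laid so far (mm along the branch)
    br_base_path = 0,              # path length from branch origin to base
    br_laterals = 0L,              # laterals emitted (phyllotactic phase)
    br_carry = 0,                  # funded length not yet a whole segment (mm)
    # biomass ledger
    cum_budget_in = 0,
    cum_budget_unused = 0,
    rng_state = make_rng_state(seed)
  ), class = "plant")
}

#' @export
print.plant <- function(x, ...) {
  cat(sprintf("<plant %d> %d segments on %d branches; shoot %.4g g, root %.4g g\n",
              x$id, nrow(x$seg_start), length(x$br_order),
              x$shoot_biomass, x$root_biomass))
  invisible(x)
}

#' Number of root segments of a plant
#' @param plant A [init_plant()] object.
#' @return Integer segment count.
#' @export
n_segments <- function(plant) nrow(plant$seg_start)

# --- water ----------------------------------------------------------------

#' Per-segment water demands
#'
#' Every segment demands a constant potential uptake,
#' \code{water_uptake_per_root_length * segment_length} mm^3 per day, from
#' the voxel containing its midpoint. Segments whose midpoint lies outside
#' the grid (below the world floor) demand nothing.
#'
#' @param plant A [init_plant()] object.
#' @param soil A [soil_params()] object.
#' @return A list with \code{voxel} (linear 1-based voxel index per segment,
#'   \code{NA} if outside) and \code{demand} (mm^3 per segment).
#' @export
water_demands <- function(plant, soil) {
  mid <- (plant$seg_start + plant$seg_end) / 2
  idx <- locate_voxel(mid, soil)
  vox <- rep(NA_integer_, nrow(idx))
  ok <- !is.na(idx[, 1L])
  if (any(ok)) vox[ok] <- voxel_linear_index(idx[ok, , drop = FALSE], soil)
  per_seg <- plant$constants$water_uptake_per_root_length *
    plant$constants$segment_length
  list(voxel = vox, demand = rep(per_seg, nrow(idx)))
}

#' Water delivered to the plant base
#'
#' Sums the per-segment realized uptakes, discounting each by the water
#' transport loss along its root path:
#' \code{uptake * (1 - water_trans_efficiency)^path_length_mm}. With zero
#' transport loss this is the plain sum over segments.
#'
#' @param uptake Numeric vector of realized per-segment uptakes (mm^3), in
#'   segment order.
#' @param plant A [init_plant()] object.
#' @param constants A [model_constants()] object.
#' @return Delivered water volume (mm^3).
#' @export
delivered_water <- function(uptake, plant, constants = plant$constants) {
  stopifnot(length(uptake) == n_segments(plant), all(uptake >= 0))
  sum(uptake * (1 - constants$water_trans_efficiency)^plant$seg_path)
}

#' Convert delivered water into allocable biomass
#'
#' @param delivered Delivered water volume (mm^3), non-negative.
#' @param constants A [model_constants()] object.
#' @return Allocable biomass (g).
#' @export
water_to_growth <- function(delivered, constants) {
  stopifnot(delivered >= 0)
  delivered * constants$water_to_biomass
}

#' Fraction of allocable biomass sent to the shoot
#'
#' The shoot fraction is a logistic function of the day's allocable biomass:
#' \code{plogis(kshoot1 + kshoot2 * allocable_mg)}, with the allocable
#' biomass expressed in milligrams so that the evolvable range of
#' \code{kshoot2} is numerically meaningful. The fraction is strictly inside
#' (0, 1) and monotone in the allocable biomass with the sign of
#' \code{kshoot2}.
#'
#' @param allocable Allocable biomass for the day (g), non-negative.
#' @param genotype A [genotype()] object.
#' @return Shoot fraction in (0, 1).
#' @export
shoot_fraction <- function(allocable, genotype) {
  stopifnot(allocable >= 0)
  stats::plogis(genotype$kshoot1 + genotype$kshoot2 * allocable * 1000)
}

# --- growth ---------------------------------------------------------------

#' Grow the root system for one day
#'
#' Every branch tip has a daily potential elongation of
#' \code{max_elongation_rate} mm. When the summed biomass demand of all tips
#' exceeds the root budget, the budget is shared among tips proportionally to
#' \code{orderweightings^order} (capped at each tip's potential; no
#' sequential priority, so the outcome is independent of branch enumeration
#' order). Funded length accumulates per tip and whole segments of
#' \code{segment_length} mm are appended while it permits; the remainder
#' carries over to the next day. Each new segment's direction is the previous
#' heading plus a downward gravitropic pull of strength \code{gravitrop},
#' renormalized. At each newly created segment junction on a branch of order
#' below \code{maxorder}, a lateral is initiated with probability
#' \code{basezonep} within \code{basezonelength} mm of the branch origin and
#' \code{branch_probability} beyond it; its initial heading is the parent
#' heading rotated \code{branchang} away from the parent axis and rotated
#' about that axis by the cumulative phyllotactic phase
#' \code{laterals_emitted * rotang}. Branching draws are the only random
#' element and come from the plant's private RNG stream.
#'
#' @param plant A [init_plant()] object.
#' @param root_budget Biomass available for root growth today (g), >= 0.
#' @param constants A [model_constants()] object.
#' @return The grown plant.
#' @export
grow_roots <- function(plant, root_budget, constants = plant$constants) {
  if (root_budget < 0) stop("negative root budget")
  g <- plant$genotype
  sl <- constants$segment_length
  cost <- segment_cost(constants)
  cost_per_mm <- cost / sl
  nb <- length(plant$br_order)

  potential <- rep(constants$max_elongation_rate, nb)
  demand <- potential * cost_per_mm
  total_demand <- sum(demand)
  if (total_demand <= root_budget) {
    funded_len <- potential
  } else {
    w <- g$orderweightings^plant$br_order
    sw <- sum(w)
    share <- if (sw > 0) root_budget * w / sw else rep(0, nb)
    funded_len <- pmin(potential, share / cost_per_mm)
  }
  used <- sum(funded_len) * cost_per_mm
  plant$cum_budget_in <- plant$cum_budget_in + root_budget
  plant$cum_budget_unused <- plant$cum_budget_unused + (root_budget - used)

  carry <- plant$br_carry + funded_len
  n_new <- floor(carry / sl + 1e-9)
  carry <- pmax(carry - n_new * sl, 0)
  plant$br_carry <- carry
  total_new <- sum(n_new)
  if (total_new == 0) return(plant)

  # swap in the plant's private RNG stream for the branching draws
  old_rng <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  assign(".Random.seed", plant$rng_state, envir = globalenv())
  on.exit({
    if (!is.null(old_rng)) assign(".Random.seed", old_rng, envir = globalenv())
  }, add = TRUE)

  ns_start <- matrix(0, total_new, 3L)
  ns_end <- matrix(0, total_new, 3L)
  ns_branch <- integer(total_new)
  ns_path <- numeric(total_new)
  k <- 0L
  new_br <- list()

  grav <- c(0, 0, g$gravitrop)
  for (i in which(n_new > 0)) {
    h <- plant$br_heading[i, ]
    pos <- plant$br_tip[i, ]
    dist <- plant$br_dist[i]
    ord <- plant$br_order[i]
    can_branch <- ord < g$maxorder
    for (s in seq_len(n_new[i])) {
      h <- h + grav
      h <- h / vnorm(h)
      # lateral initiation at the junction with the previous segment
      if (dist > 0 && can_branch) {
        p <- if (dist <= g$basezonelength) g$basezonep else
          constants$branch_probability
        do_branch <- if (p >= 1) TRUE else if (p <= 0) FALSE else
          stats::runif(1) < p
        if (do_branch) {
          phase <- plant$br_laterals[i] * g$rotang
          new_br[[length(new_br) + 1L]] <- list(
            parent = i, order = ord + 1L,
            heading = lateral_heading(h, g$branchang, phase),
            origin = pos,
            base_path = plant$br_base_path[i] + dist)
          plant$br_laterals[i] <- plant$br_laterals[i] + 1L
        }
      }
      k <- k + 1L
      ns_start[k, ] <- pos
      ns_branch[k] <- i
      ns_path[k] <- plant$br_base_path[i] + dist
      pos <- pos + sl * h
      ns_end[k, ] <- pos
      dist <- dist + sl
    }
    plant$br_heading[i, ] <- h
    plant$br_tip[i, ] <- pos
    plant$br_dist[i] <- dist
  }
  plant$rng_state <- get(".Random.seed", envir = globalenv())

  plant$seg_start <- rbind(plant$seg_start, ns_start)
  plant$seg_end <- rbind(plant$seg_end, ns_end)
  plant$seg_branch <- c(plant$seg_branch, ns_branch)
  plant$seg_path <- c(plant$seg_path, ns_path)
  plant$root_biomass <- plant$root_biomass + total_new * cost

  if (length(new_br)) {
    m <- length(new_br)
    plant$br_parent <- c(plant$br_parent,
                         vapply(new_br, `[[`, integer(1), "parent"))
    plant$br_order <- c(plant$br_order,
                        vapply(new_br, `[[`, integer(1), "order"))
    plant$br_heading <- rbind(plant$br_heading,
                              t(vapply(new_br, `[[`, numeric(3), "heading")))
    plant$br_tip <- rbind(plant$br_tip,
                          t(vapply(new_br, `[[`, numeric(3), "origin")))
    plant$br_dist <- c(plant$br_dist, numeric(m))
    plant$br_base_path <- c(plant$br_base_path,
                            vapply(new_br, `[[`, numeric(1), "base_path"))
    plant$br_laterals <- c(plant$br_laterals, integer(m))
    plant$br_carry <- c(plant$br_carry, numeric(m))
  }
  plant
}
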