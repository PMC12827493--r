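#' Soil world parameters
#'
#' Describes the voxelized soil volume in which roots grow and compete for
#' water. The default world is 10 x 10 x 70 cubic voxels of 20 mm side
#' (200 x 200 x 1400 mm), with a water-holding capacity of 10% of the voxel
#' volume, 10% of each voxel's water diffusible per day, 50% of the top
#' layer's water lost to evaporation per day, and a full recharge every day.
#' The horizontal borders wrap around (toroidal world) for both diffusion and
#' root positions; the top and bottom are closed.
#'
#' @param nx,ny,nz Number of voxels along x, y (horizontal) and z (depth).
#' @param voxel_side Side length of a cubic voxel (mm).
#' @param whc Water-holding capacity as a fraction of voxel volume, in [0, 1].
#' @param diffuse_per_day Fraction of a voxel's water that is diffusible per
#'   day, in [0, 1]; 1/6 of the diffusible amount moves to each face
#'   neighbour.
#' @param evaporation_rate Fraction of the top layer's water removed per day,
#'   in [0, 1].
#' @param recharge_interval Days between full recharges (integer >= 1).
#' @return An object of class \code{soil_params}.
#' @seealso [soil_grid()], [voxel_capacity()]
#' @export
soil_params <- function(nx = 10L, ny = 10L, nz = 70L, voxel_side = 20,
                        whc = 0.1, diffuse_per_day = 0.1,
                        evaporation_rate = 0.5, recharge_interval = 1L) {
  nx <- as.integer(nx); ny <- as.integer(ny); nz <- as.integer(nz)
  recharge_interval <- as.integer(recharge_interval)
  stopifnot(nx >= 1L, ny >= 1L, nz >= 1L, voxel_side > 0,
            whc >= 0, whc <= 1,
            diffuse_per_day >= 0, diffuse_per_day <= 1,
            evaporation_rate >= 0, evaporation_rate <= 1,
            recharge_interval >= 1L)
  structure(list(nx = nx, ny = ny, nz = nz, voxel_side = voxel_side,
                 whc = whc, diffuse_per_day = diffuse_per_day,
                 evaporation_rate = evaporation_rate,
                 recharge_interval = recharge_interval),
            class = "soil_params")
}

#' Maximum water volume a voxel can hold
#'
#' Capacity is voxel volume times the water-holding capacity fraction:
#' with the defaults, 20^3 x 0.1 = 800 mm^3 per voxel.
#'
#' @param params A [soil_params()] object.
#' @return Capacity in mm^3.
#' @export
voxel_capacity <- function(params) {
  params$voxel_side^3 * params$whc
}

#' Create a soil grid
#'
#' @param params A [soil_params()] object.
#' @param fill \code{"full"} (every voxel at capacity, the state after a
#'   recharge) or \code{"empty"}, or a numeric array of dimension
#'   \code{c(nx, ny, nz)} giving per-voxel water volumes (mm^3).
#' @return An object of class \code{soil_grid}: a list with \code{params} and
#'   the 3-d \code{water} array (mm^3), indexed \code{[x, y, z]} with
#'   \code{z = 1} the top layer.
#' @export
soil_grid <- function(params, fill = c("full", "empty")) {
  cap <- voxel_capacity(params)
  dims <- c(params$nx, params$ny, params$nz)
  if (is.numeric(fill)) {
    water <- array(as.double(fill), dim = dims)
    if (any(water < 0) || any(water > cap + 1e-9))
      stop("water volumes must lie in [0, capacity]")
  } else {
    fill <- match.arg(fill)
    water <- array(if (fill == "full") cap else 0, dim = dims)
  }
  structure(list(params = params, water = water), class = "soil_grid")
}

#' @export
print.soil_grid <- function(x, ...) {
  p <- x$params
  cat(sprintf("<soil_grid> %d x %d x %d voxels (%.0f mm side), %.1f / %.1f mm^3 water\n",
              p$nx, p$ny, p$nz, sum(x$water),
              voxel_capacity(p) * p$nx * p$ny * p$nz))
  invisible(x)
}

#' Locate world positions in the voxel grid
#'
#' Converts world coordinates (mm) to zero-based voxel indices. The z axis
#' points downward from the soil surface (z = 0 at the surface). Horizontal
#' coordinates wrap around the world extent; positions above the surface or
#' below the world floor are outside the grid. Voxels cover half-open
#' intervals \code{[k * side, (k + 1) * side)} along each axis.
#'
#' @param position Numeric vector of length 3 (x, y, z), or an n x 3 matrix.
#' @param params A [soil_params()] object.
#' @return An n x 3 integer matrix of zero-based voxel indices, with
#'   \code{NA} rows for positions outside the grid (a single position is
#'   still returned as a 1 x 3 matrix).
#' @export
locate_voxel <- function(position, params) {
  if (is.null(dim(position))) position <- matrix(position, ncol = 3L, byrow = TRUE)
  side <- params$voxel_side
  wx <- params$nx * side
  wy <- params$ny * side
  x <- position[, 1L] %% wx
  y <- position[, 2L] %% wy
  z <- position[, 3L]
  out <- cbind(as.integer(floor(x / side)),
               as.integer(floor(y / side)),
               as.integer(floor(z / side)))
  outside <- z < 0 | z >= params$nz * side
  out[outside, ] <- NA_integer_
  out
}

# Linear (1-based) voxel index from zero-based (x, y, z) indices; NA passes
# through. Used to pool per-segment demands into one rationing pass.
voxel_linear_index <- function(idx, params) {
  idx[, 1L] + params$nx * idx[, 2L] + params$nx * params$ny * idx[, 3L] + 1L
}

#' Recharge the soil
#'
#' On recharge days (\code{day} divisible by \code{recharge_interval}) every
#' voxel is refilled to capacity; on other days the grid is unchanged.
#'
#' @param grid A [soil_grid()] object.
#' @param day Simulation day (integer >= 0).
#' @return The updated grid, with attribute \code{"added"} giving the water
#'   volume added (mm^3).
#' @export
recharge <- function(grid, day) {
  stopifnot(day >= 0)
  added <- 0
  if (day %% grid$params$recharge_interval == 0) {
    cap <- voxel_capacity(grid$params)
    added <- sum(cap - grid$water)
    grid$water[] <- cap
  }
  attr(grid, "added") <- added
  grid
}

#' Evaporate water from the soil surface
#'
#' Removes a fraction \code{evaporation_rate} of the water in every voxel of
#' the top layer; deeper layers are unaffected.
#'
#' @param grid A [soil_grid()] object.
#' @return The updated grid, with attribute \code{"removed"} giving the water
#'   volume lost (mm^3).
#' @export
evaporate <- function(grid) {
  rate <- grid$params$evaporation_rate
  removed <- sum(grid$water[, , 1L]) * rate
  grid$water[, , 1L] <- grid$water[, , 1L] * (1 - rate)
  attr(grid, "removed") <- removed
  grid
}

#' Diffuse water between neighbouring voxels
#'
#' A fraction \code{diffuse_per_day} of each voxel's water is diffusible and
#' 1/6 of that amount moves to each of its six face neighbours. The update is
#' synchronous: all outgoing fluxes are computed from the pre-update state and
#' then applied, so the result is independent of voxel enumeration order.
#' Horizontal neighbours wrap around; there is no diffusion up from the top
#' layer or down from the bottom layer (the would-be flux stays in the source
#' voxel). Total water is conserved exactly.
#'
#' @param grid A [soil_grid()] object.
#' @return The updated grid.
#' @export
diffuse <- function(grid) {
  d <- grid$params$diffuse_per_day
  if (d == 0) return(grid)
  w <- grid$water
  nz <- grid$params$nz
  flux <- w * (d / 6)           # per-face outgoing flux

  shift <- function(a, k, axis) {
    # circular shift by k along axis (wrap-around neighbours)
    n <- dim(a)[axis]
    idx <- ((seq_len(n) - 1L - k) %% n) + 1L
    switch(axis, a[idx, , , drop = FALSE], a[, idx, , drop = FALSE],
           a[, , idx, drop = FALSE])
  }

  # leaving: 4 horizontal faces always, vertical faces only when open
  open_up <- slice.index(w, 3L) > 1L
  open_dn <- slice.index(w, 3L) < nz
  leaving <- flux * (4 + open_up + open_dn)

  incoming <- shift(flux, 1L, 1L) + shift(flux, -1L, 1L) +
              shift(flux, 1L, 2L) + shift(flux, -1L, 2L)
  if (nz > 1L) {
    down <- array(0, dim = dim(w)); down[, , 2L:nz] <- flux[, , 1L:(nz - 1L)]
    up   <- array(0, dim = dim(w)); up[, , 1L:(nz - 1L)] <- flux[, , 2L:nz]
    incoming <- incoming + down + up
  }
  grid$water <- w - leaving + incoming
  grid
}

#' Extract water from the soil, rationed per voxel
#'
#' Serves a pooled set of per-segment demands. Within a voxel, if the total
#' demand does not exceed the available water every claimant receives its full
#' demand; otherwise the available water is split across all claimants in
#' proportion to their demands, regardless of which plant they belong to.
#' This proportional rationing is the competition mechanism: plants interact
#' only through voxels where their segments co-occur.
#'
#' @param grid A [soil_grid()] object.
#' @param voxel Integer vector of linear 1-based voxel indices, one per
#'   demand (see [locate_voxel()]); \code{NA} entries (segments outside the
#'   grid) receive zero uptake.
#' @param demand Numeric vector of demanded volumes (mm^3), non-negative.
#' @return A list with \code{grid} (water decremented by the realized
#'   uptakes) and \code{uptake} (realized volumes, in input order).
#' @export
extract_water <- function(grid, voxel, demand) {
  stopifnot(length(voxel) == length(demand))
  if (any(demand < 0, na.rm = TRUE))
    stop("negative water demand: invalid root state")
  n <- length(demand)
  uptake <- numeric(n)
  ok <- !is.na(voxel) & demand > 0
  if (any(ok)) {
    v <- voxel[ok]
    dem <- demand[ok]
    totals <- rowsum(dem, group = v, reorder = FALSE)
    uv <- as.integer(rownames(totals))
    avail <- grid$water[uv]
    ratio <- pmin(1, avail / totals[, 1L])
    uptake[ok] <- dem * ratio[match(v, uv)]
    grid$water[uv] <- avail - totals[, 1L] * ratio
  }
  list(grid = grid, uptake = uptake)
}

#' Write a soil grid snapshot as long-format CSV
#'
#' Columns \code{x, y, z} (zero-based voxel indices) and \code{water_mm3}.
#'
#' @param grid A [soil_grid()] object.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_grid_csv <- function(grid, path) {
  p <- grid$params
  idx <- expand.grid(x = 0:(p$nx - 1L), y = 0:(p$ny - 1L), z = 0:(p$nz - 1L))
  idx$water_mm3 <- as.vector(grid$water)
  utils::write.csv(idx, path, row.names = FALSE)
  invisible(path)
}
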