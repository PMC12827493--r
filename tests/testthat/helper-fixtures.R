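# Shared fixtures: small worlds and hand-picked genotypes used across tests.

tiny_soil <- function(...) soil_params(nx = 3, ny = 3, nz = 3, ...)

# Reduced problem size used for the slower, study-level checks: a smaller
# world, shorter simulations and closer neighbours so that root systems of
# desk-scale plants overlap the way full-scale ones do at 50 mm.
quick_soil <- function() soil_params(nx = 8, ny = 8, nz = 15)
quick_duration <- 100L
quick_distance <- 20

# A mid-range genotype that grows reliably in the quick settings.
quick_genotype <- function() {
  genotype(rotang = 0.7, branchang = 0.9, gravitrop = 0.05,
           basezonelength = 10, basezonep = 0.8, maxorder = 5,
           orderweightings = 1.2, kshoot1 = -2, kshoot2 = 0.01)
}

# A genotype that never branches: basezonep 0 and a base zone longer than
# any branch can get, with lateral initiation beyond the base zone disabled
# through the zone length (branch_probability stays at its default 1).
unbranched_genotype <- function() {
  genotype(rotang = 0, branchang = 0, gravitrop = 0, basezonelength = 1e9,
           basezonep = 0, maxorder = 2, orderweightings = 1,
           kshoot1 = 0, kshoot2 = 0)
}

# Independent triple-loop diffusion oracle: literal per-voxel flux
# bookkeeping with wrap-around in x/y and closed top/bottom faces.
diffuse_oracle <- function(grid) {
  p <- grid$params
  w <- grid$water
  out <- array(0, dim = dim(w))
  d <- p$diffuse_per_day
  for (x in seq_len(p$nx)) for (y in seq_len(p$ny)) for (z in seq_len(p$nz)) {
    flux <- w[x, y, z] * d / 6
    wrap <- function(i, n) ((i - 1) %% n) + 1
    # four horizontal neighbours, wrapped
    nbrs <- list(c(wrap(x + 1, p$nx), y, z), c(wrap(x - 1, p$nx), y, z),
                 c(x, wrap(y + 1, p$ny), z), c(x, wrap(y - 1, p$ny), z))
    if (z > 1) nbrs <- c(nbrs, list(c(x, y, z - 1)))
    if (z < p$nz) nbrs <- c(nbrs, list(c(x, y, z + 1)))
    out[x, y, z] <- out[x, y, z] - length(nbrs) * flux
    for (nb in nbrs) out[nb[1], nb[2], nb[3]] <- out[nb[1], nb[2], nb[3]] + flux
  }
  grid$water <- w + out
  grid
}

# Independent brute-force box count: loops over a bounding lattice of boxes
# and tests each for point membership.
box_count_oracle <- function(points, s) {
  lo <- floor(apply(points, 2, min) / s)
  hi <- floor(apply(points, 2, max) / s)
  count <- 0
  for (ix in lo[1]:hi[1]) for (iy in lo[2]:hi[2]) for (iz in lo[3]:hi[3]) {
    inside <- points[, 1] >= ix * s & points[, 1] < (ix + 1) * s &
      points[, 2] >= iy * s & points[, 2] < (iy + 1) * s &
      points[, 3] >= iz * s & points[, 3] < (iz + 1) * s
    if (any(inside)) count <- count + 1
  }
  count
}
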