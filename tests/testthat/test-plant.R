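test_that("a new plant is one downward segment with no shoot", {
  k <- model_constants()
  p <- init_plant(quick_genotype(), c(100, 100, 0), k)
  expect_equal(n_segments(p), 1L)
  expect_equal(p$shoot_biomass, 0)
  expect_equal(p$seg_end[1, ], c(100, 100, 2))
  expect_equal(p$root_biomass, pi * 0.5^2 * 2 * 0.001)
  # segment length passes through
  k5 <- model_constants(segment_length = 5)
  p5 <- init_plant(quick_genotype(), c(0, 0, 0), k5)
  expect_equal(p5$seg_end[1, 3], 5)
  expect_error(init_plant(quick_genotype(), c(0, 0, 5)))
})

test_that("per-segment demand is constant and targets the midpoint voxel", {
  soil <- soil_params()
  p <- init_plant(quick_genotype(), c(100, 100, 0))
  d <- water_demands(p, soil)
  expect_equal(d$demand, 20)   # 10 mm^3 per mm x 2 mm
  mid <- c(100, 100, 1)
  expect_equal(d$voxel,
               voxel_linear_index(locate_voxel(mid, soil), soil))
  # three segments in one voxel: three independent demands of 20
  p3 <- p
  p3$seg_start <- matrix(rep(c(100, 100, 0), 3), 3, byrow = TRUE)
  p3$seg_end <- matrix(rep(c(100, 100, 2), 3), 3, byrow = TRUE)
  p3$seg_branch <- rep(1L, 3)
  p3$seg_path <- rep(0, 3)
  d3 <- water_demands(p3, soil)
  expect_equal(d3$demand, rep(20, 3))
  expect_equal(length(unique(d3$voxel)), 1L)
})

test_that("segments below the world floor demand nothing", {
  soil <- tiny_soil()  # 60 mm deep
  p <- init_plant(quick_genotype(), c(10, 10, 0))
  p$seg_start[1, ] <- c(10, 10, 80)
  p$seg_end[1, ] <- c(10, 10, 82)
  d <- water_demands(p, soil)
  expect_true(is.na(d$voxel))
  g <- soil_grid(soil, "full")
  ex <- extract_water(g, d$voxel, d$demand)
  expect_equal(ex$uptake, 0)
})

test_that("delivered water discounts uptake along the path to the base", {
  k0 <- model_constants(water_trans_efficiency = 0)
  p <- init_plant(quick_genotype(), c(0, 0, 0), k0)
  p$seg_start <- rbind(p$seg_start, c(0, 0, 2))
  p$seg_end <- rbind(p$seg_end, c(0, 0, 4))
  p$seg_branch <- c(1L, 1L)
  p$seg_path <- c(0, 2)
  expect_equal(delivered_water(c(20, 20), p, k0), 40)
  k <- model_constants(water_trans_efficiency = 0.002)
  p$seg_path <- c(0, 500)
  expect_equal(delivered_water(c(20, 20), p, k), 20 + 20 * 0.998^500)
  expect_equal(20 * 0.998^500, 7.355, tolerance = 1e-3)
})

test_that("water converts to biomass linearly", {
  k <- model_constants()
  expect_equal(water_to_growth(20, k), 2e-4)
  expect_equal(water_to_growth(0, k), 0)
  expect_equal(water_to_growth(800, k), 0.008)
  expect_error(water_to_growth(-1, k))
})

test_that("shoot fraction is a logistic of the allocable biomass in mg", {
  g0 <- genotype(kshoot1 = 0, kshoot2 = 0)
  expect_equal(shoot_fraction(0.123, g0), 0.5)
  expect_equal(shoot_fraction(0, g0), 0.5)
  gsat <- genotype(kshoot1 = 100, kshoot2 = 0)
  expect_equal(shoot_fraction(1, gsat), 1, tolerance = 1e-12)
  # kshoot1 = 1, kshoot2 = -0.1, 10 mg allocable -> logistic(0)
  g <- genotype(kshoot1 = 1, kshoot2 = -0.1)
  expect_equal(shoot_fraction(0.010, g), 0.5)
  # monotone decreasing when kshoot2 < 0
  expect_lt(shoot_fraction(0.020, g), shoot_fraction(0.010, g))
})

test_that("elongation carryover accumulates across days", {
  k <- model_constants()
  p <- init_plant(unbranched_genotype(), c(100, 100, 0), k)
  big <- 1  # more than enough biomass for the 5 mm daily potential
  p1 <- grow_roots(p, big, k)
  expect_equal(n_segments(p1), 1L + 2L)   # 5 mm -> 2 segments + 1 mm carry
  expect_equal(p1$br_carry, 1)
  p2 <- grow_roots(p1, big, k)
  expect_equal(n_segments(p2), 3L + 3L)   # carry 1 + 5 -> 3 segments, 0 carry
  expect_equal(p2$br_carry, 0)
})

test_that("zero budget leaves the structure untouched", {
  k <- model_constants()
  p <- init_plant(quick_genotype(), c(100, 100, 0), k)
  p0 <- grow_roots(p, 0, k)
  expect_equal(n_segments(p0), 1L)
  expect_equal(p0$br_carry, p$br_carry)
  expect_error(grow_roots(p, -1e-9, k), "negative")
})

test_that("without gravitropism a vertical axis stays vertical", {
  k <- model_constants()
  p <- init_plant(unbranched_genotype(), c(100, 100, 0), k)
  for (i in 1:10) p <- grow_roots(p, 1, k)
  expect_equal(n_segments(p), 26L)  # 1 + 10 days x 2.5 mm/segment-day
  expect_true(all(p$seg_start[, 1] == 100))
  expect_true(all(p$seg_start[, 2] == 100))
  expect_equal(max(p$seg_end[, 3]), 52)
  # hand-computed trajectory: segment j spans [2(j-1), 2j] in z
  expect_equal(p$seg_end[, 3], 2 * seq_len(26))
  expect_equal(p$seg_path, 2 * (seq_len(26) - 1))
})

test_that("budget sharing is proportional to order weightings", {
  k <- model_constants()
  g <- unbranched_genotype()
  p <- init_plant(g, c(100, 100, 0), k)
  # graft a second branch of order 3 by hand
  p$br_parent <- c(NA_integer_, 1L)
  p$br_order <- c(0L, 3L)
  p$br_heading <- rbind(p$br_heading, c(1, 0, 0))
  p$br_tip <- rbind(p$br_tip, c(100, 100, 2))
  p$br_dist <- c(p$br_dist, 0)
  p$br_base_path <- c(p$br_base_path, 2)
  p$br_laterals <- c(p$br_laterals, 0L)
  p$br_carry <- c(p$br_carry, 0)
  # orderweightings = 1: half the total demand funds each tip 50%
  cost_per_mm <- segment_cost(k) / k$segment_length
  half <- 0.5 * 2 * 5 * cost_per_mm
  p1 <- grow_roots(p, half, k)
  n_new <- c(sum(p1$seg_branch == 1) - 1L, sum(p1$seg_branch == 2))
  expect_equal(p1$br_carry + 2 * n_new, c(2.5, 2.5))
  # orderweightings favouring high orders shifts funding to the lateral
  p$genotype$orderweightings <- 2
  g2 <- p$genotype
  p2 <- grow_roots(p, half, k)
  len2 <- p2$br_carry + 2 * c(sum(p2$seg_branch == 1) - 1, sum(p2$seg_branch == 2))
  w <- 2^c(0, 3)
  funded <- pmin(5, 5 * w / sum(w))  # 5 mm worth of budget, shared by weight
  expect_equal(len2, funded)
})

test_that("growth respects maxorder everywhere", {
  k <- model_constants()
  g <- genotype(rotang = 1, branchang = 1, gravitrop = 0.05,
                basezonelength = 5, basezonep = 1, maxorder = 2,
                orderweightings = 1, kshoot1 = 0, kshoot2 = 0)
  p <- init_plant(g, c(100, 100, 0), k, seed = 5)
  for (i in 1:25) p <- grow_roots(p, 0.02, k)
  orders <- p$br_order[p$seg_branch]
  expect_true(all(sort(unique(orders)) %in% 0:2))
  expect_gt(max(orders), 1)  # branching actually happened
})

test_that("all headings stay unit length and gravitropism pulls tips down", {
  k <- model_constants()
  g <- genotype(rotang = 0.9, branchang = 1.2, gravitrop = 0.15,
                basezonelength = 10, basezonep = 0.5, maxorder = 4,
                orderweightings = 1, kshoot1 = 0, kshoot2 = 0)
  p <- init_plant(g, c(100, 100, 0), k, seed = 9)
  zs <- list()
  for (i in 1:20) {
    p <- grow_roots(p, 0.05, k)
    expect_equal(sqrt(rowSums(p$br_heading^2)),
                 rep(1, length(p$br_order)), tolerance = 1e-9)
  }
  # along any single branch, segment direction z-components never decrease
  for (b in unique(p$seg_branch)) {
    rows <- which(p$seg_branch == b)
    dz <- (p$seg_end[rows, 3] - p$seg_start[rows, 3]) / k$segment_length
    expect_true(all(diff(dz) >= -1e-9))
  }
})

test_that("growth is bit-identical for identical genotype, seed and budgets", {
  k <- model_constants()
  g <- quick_genotype()
  grow <- function() {
    p <- init_plant(g, c(100, 100, 0), k, seed = 42)
    for (i in 1:15) p <- grow_roots(p, 0.03, k)
    p
  }
  a <- grow(); b <- grow()
  expect_identical(a$seg_end, b$seg_end)
  expect_identical(a$br_order, b$br_order)
  # and independent of the caller's RNG stream
  set.seed(999); runif(3)
  c2 <- grow()
  expect_identical(a$seg_end, c2$seg_end)
})

test_that("grow_roots does not disturb the caller's RNG stream", {
  set.seed(123)
  before <- .Random.seed
  p <- init_plant(quick_genotype(), c(100, 100, 0), seed = 7)
  p <- grow_roots(p, 0.05)
  expect_identical(.Random.seed, before)
})

test_that("root biomass ledger matches the segment count exactly", {
  k <- model_constants()
  p <- init_plant(quick_genotype(), c(100, 100, 0), k, seed = 3)
  for (i in 1:20) p <- grow_roots(p, 0.04, k)
  expect_equal(p$root_biomass, n_segments(p) * segment_cost(k),
               tolerance = 1e-12)
  # budget conservation: in = new tissue + carryover + unused
  cost_per_mm <- segment_cost(k) / k$segment_length
  new_tissue <- (n_segments(p) - 1L) * segment_cost(k)
  expect_equal(p$cum_budget_in,
               new_tissue + sum(p$br_carry) * cost_per_mm + p$cum_budget_unused,
               tolerance = 1e-12)
})
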