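#' Rasterize root segments into points
#'
#' Samples points along every segment at a fixed step (1 mm by default),
#' including both endpoints. Used by the box-counting fractal dimension.
#'
#' @param seg_start,seg_end n x 3 matrices of segment endpoints (mm).
#' @param step Sampling step along each segment (mm).
#' @return An m x 3 matrix of points.
#' @export
rasterize_segments <- function(seg_start, seg_end, step = 1) {
  stopifnot(nrow(seg_start) == nrow(seg_end), step > 0)
  len <- sqrt(rowSums((seg_end - seg_start)^2))
  tt <- seq(0, 1, by = step / max(len))
  if (tt[length(tt)] < 1) tt <- c(tt, 1)
  pts <- lapply(tt, function(t) seg_start + t * (seg_end - seg_start))
  do.call(rbind, pts)
}

#' Box-counting fractal dimension of a point set
#'
#' Counts the number N(s) of occupied cubic boxes of side s (boxes anchored
#' at the origin) for each scale, and returns the negative slope of the
#' least-squares line of log N(s) against log s, together with the R^2 of
#' the fit. A straight line has dimension ~1, a filled volume ~3.
#'
#' @param points An m x 3 matrix of points (mm), e.g. from
#'   [rasterize_segments()].
#' @param scales Box side lengths (mm), default dyadic 40, 20, 10, 5.
#' @return A list with \code{dimension}, \code{r_squared}, \code{counts} and
#'   \code{scales}. If every scale yields a single occupied box the dimension
#'   is undefined: \code{dimension} is \code{NA} and a warning is issued.
#' @export
box_counting_dimension <- function(points, scales = c(40, 20, 10, 5)) {
  stopifnot(ncol(points) == 3L, length(scales) >= 2L, all(scales > 0))
  counts <- vapply(scales, function(s) {
    idx <- floor(points / s)
    nrow(unique(idx))
  }, numeric(1))
  if (all(counts <= 1)) {
    warning("all points fall in a single box at every scale; dimension undefined")
    return(list(dimension = NA_real_, r_squared = NA_real_,
                counts = counts, scales = scales))
  }
  fit <- stats::lm(log(counts) ~ log(scales))
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((log(counts) - mean(log(counts)))^2)
  list(dimension = -unname(stats::coef(fit)[2L]),
       r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1,
       counts = counts, scales = scales)
}

#' Emergent root morphology metrics of a plant
#'
#' Computes the seven morphology measures used to compare evolved species:
#' maximum root horizontal length (mm, the largest horizontal distance of a
#' segment endpoint from the base, in unwrapped coordinates), root depth
#' (mm, the deepest segment endpoint), root biomass (g), total root length
#' per unit biomass (mm g^-1), number of branches per unit root length
#' (mm^-1, counting branches with at least one segment), root density per
#' voxel (g voxel^-1, biomass divided by the number of distinct voxels
#' containing at least one segment midpoint) and the box-counting fractal
#' dimension.
#'
#' @param plant A grown [init_plant()] object with at least one segment.
#' @param soil A [soil_params()] object (for the voxel partition).
#' @param scales Box sides for the fractal dimension (mm).
#' @param step Rasterization step for the fractal dimension (mm).
#' @return A one-row data frame with columns \code{max_horizontal_length},
#'   \code{root_depth}, \code{root_biomass}, \code{length_per_biomass},
#'   \code{branches_per_length}, \code{density_per_voxel},
#'   \code{fractal_dimension}.
#' @export
morphology <- function(plant, soil = soil_params(),
                       scales = c(40, 20, 10, 5), step = 1) {
  n <- n_segments(plant)
  if (n < 1L) stop("plant has no root segments")
  ends <- rbind(plant$seg_start, plant$seg_end)
  horiz <- sqrt((ends[, 1L] - plant$base[1L])^2 +
                (ends[, 2L] - plant$base[2L])^2)
  depth <- max(ends[, 3L])
  total_length <- n * plant$constants$segment_length
  n_branches <- length(unique(plant$seg_branch))

  mid <- (plant$seg_start + plant$seg_end) / 2
  idx <- locate_voxel(mid, soil)
  idx <- idx[!is.na(idx[, 1L]), , drop = FALSE]
  n_vox <- if (nrow(idx)) nrow(unique(idx)) else NA_integer_

  fd <- box_counting_dimension(
    rasterize_segments(plant$seg_start, plant$seg_end, step), scales)

  data.frame(max_horizontal_length = max(horiz),
             root_depth = depth,
             root_biomass = plant$root_biomass,
             length_per_biomass = total_length / plant$root_biomass,
             branches_per_length = n_branches / total_length,
             density_per_voxel = plant$root_biomass / n_vox,
             fractal_dimension = fd$dimension)
}

#' Principal components analysis of morphology records
#'
#' Z-scores each metric and eigendecomposes the correlation structure.
#' Constant columns are dropped with a warning. Sign convention: each
#' component is flipped so that its largest-magnitude loading is positive.
#'
#' @param records A data frame of morphology metrics (one row per plant),
#'   e.g. rbound [morphology()] rows.
#' @param standardize Z-score the metrics before the decomposition
#'   (default \code{TRUE}).
#' @return A list with \code{scores} (rows follow \code{records}),
#'   \code{loadings} and \code{explained_var} (variance shares).
#' @export
morphology_pca <- function(records, standardize = TRUE) {
  x <- as.matrix(records)
  stopifnot(nrow(x) >= 3L)
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0)) {
    warning("dropping constant metric column(s): ",
            paste(colnames(x)[sds == 0], collapse = ", "))
    x <- x[, sds > 0, drop = FALSE]
  }
  if (ncol(x) < 2L) stop("need at least two metrics with nonzero variance")
  p <- stats::prcomp(x, center = TRUE, scale. = standardize)
  flip <- vapply(seq_len(ncol(p$rotation)), function(j) {
    v <- p$rotation[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  flip[flip == 0] <- 1
  scores <- sweep(p$x, 2L, flip, `*`)
  loadings <- sweep(p$rotation, 2L, flip, `*`)
  list(scores = scores, loadings = loadings,
       explained_var = p$sdev^2 / sum(p$sdev^2))
}
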