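# Discretization and the 79 first-order features. Percentiles use the linear
# interpolation rule (R quantile type 7); skewness/kurtosis are the
# population moments (kurtosis reported as excess).

#' Discretize in-mask intensities into a fixed number of bins
#'
#' `level(x) = min(floor((x - min) * n_bins / (max - min)) + 1, n_bins)` over
#' the in-mask range; a constant-intensity mask maps every voxel to bin 1.
#' Voxels outside the mask are coded 0.
#'
#' @param volume numeric 3D array.
#' @param mask logical 3D array.
#' @param n_bins number of gray levels (default 32).
#' @return integer 3D array of levels in `0..n_bins`.
#' @export
discretize <- function(volume, mask, n_bins = 32) {
  check_vol_mask(volume, mask)
  stopifnot(n_bins >= 2)
  x <- volume[mask]
  if (!all(is.finite(x))) stop("non-finite in-mask intensities", call. = FALSE)
  lo <- min(x); hi <- max(x)
  lev <- if (hi > lo)
    pmin(floor((x - lo) * n_bins / (hi - lo)) + 1L, n_bins)
  else
    rep(1L, length(x))
  out <- array(0L, dim = dim(volume))
  out[mask] <- as.integer(lev)
  out
}

# internal: population skewness / excess kurtosis
pop_skew <- function(x) {
  m <- mean(x); s2 <- mean((x - m)^2)
  if (s2 == 0) return(0)
  mean((x - m)^3) / s2^1.5
}
pop_kurt_excess <- function(x) {
  m <- mean(x); s2 <- mean((x - m)^2)
  if (s2 == 0) return(0)
  mean((x - m)^4) / s2^2 - 3
}

# internal: morphology block (mask geometry + centre-of-mass shift)
morphology_features <- function(volume, mask, voxel_size_mm) {
  idx <- which(mask)
  coord <- arrayInd(idx, dim(mask))
  nvox <- length(idx)
  vv <- prod(voxel_size_mm)
  vol_mm3 <- nvox * vv
  # surface: count exposed faces per axis (neighbour outside mask or grid)
  surf <- 0
  d <- dim(mask)
  face_area <- c(voxel_size_mm[2] * voxel_size_mm[3],
                 voxel_size_mm[1] * voxel_size_mm[3],
                 voxel_size_mm[1] * voxel_size_mm[2])
  for (a in 1:3) {
    for (s in c(-1L, 1L)) {
      nb <- coord
      nb[, a] <- nb[, a] + s
      inside <- nb[, a] >= 1 & nb[, a] <= d[a]
      covered <- rep(FALSE, nvox)
      covered[inside] <- mask[cbind(nb[inside, 1], nb[inside, 2], nb[inside, 3])]
      surf <- surf + sum(!covered) * face_area[a]
    }
  }
  mm <- sweep(coord, 2, 0.5, `-`)
  mm <- sweep(mm, 2, voxel_size_mm, `*`)          # voxel centres in mm
  ctr <- colMeans(mm)
  w <- volume[idx]
  ctr_w <- colSums(mm * w) / sum(w)
  ev <- eigen(stats::cov(mm), symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  axes <- 4 * sqrt(ev)                             # descending
  bbox <- apply(coord, 2, function(v) diff(range(v)) + 1) * voxel_size_mm
  sph <- (36 * pi * vol_mm3^2)^(1 / 3) / surf
  c(morph.voxel_count = nvox,
    morph.volume_mm3 = vol_mm3,
    morph.surface_area_mm2 = surf,
    morph.surface_to_volume_ratio = surf / vol_mm3,
    morph.compactness_1 = vol_mm3 / (sqrt(pi) * surf^1.5),
    morph.compactness_2 = 36 * pi * vol_mm3^2 / surf^3,
    morph.spherical_disproportion = 1 / sph,
    morph.sphericity = sph,
    morph.equivalent_sphere_diameter = 2 * (3 * vol_mm3 / (4 * pi))^(1 / 3),
    morph.major_axis_length = axes[1],
    morph.minor_axis_length = axes[2],
    morph.least_axis_length = axes[3],
    morph.elongation = sqrt(ev[2] / ev[1]),
    morph.flatness = sqrt(ev[3] / ev[1]),
    morph.centre_of_mass_shift_mm = sqrt(sum((ctr - ctr_w)^2)),
    morph.bounding_box_volume_mm3 = prod(bbox),
    morph.bounding_box_extent = vol_mm3 / prod(bbox))
}

# internal: intensity statistics block
stat_features <- function(x) {
  q <- quantile(x, c(.05, .10, .25, .50, .75, .90, .95), names = FALSE, type = 7)
  m <- mean(x)
  rx <- x[x >= q[2] & x <= q[6]]
  c(stat.mean = m,
    stat.variance = mean((x - m)^2),
    stat.sd = sqrt(mean((x - m)^2)),
    stat.skewness = pop_skew(x),
    stat.kurtosis_excess = pop_kurt_excess(x),
    stat.median = q[4],
    stat.minimum = min(x),
    stat.maximum = max(x),
    stat.range = max(x) - min(x),
    stat.p5 = q[1], stat.p10 = q[2], stat.p25 = q[3],
    stat.p75 = q[5], stat.p90 = q[6], stat.p95 = q[7],
    stat.interquartile_range = q[5] - q[3],
    stat.mean_absolute_deviation = mean(abs(x - m)),
    stat.robust_mean_absolute_deviation =
      if (length(rx)) mean(abs(rx - mean(rx))) else 0,
    stat.median_absolute_deviation = mean(abs(x - q[4])),
    stat.coefficient_of_variation = if (m != 0) sqrt(mean((x - m)^2)) / m else NaN,
    stat.quartile_coefficient_of_dispersion =
      if ((q[5] + q[3]) != 0) (q[5] - q[3]) / (q[5] + q[3]) else NaN,
    stat.energy = sum(x^2),
    stat.root_mean_square = sqrt(mean(x^2)),
    stat.total_sum = sum(x))
}

# internal: intensity-histogram block on the discretized levels (1..n_bins)
hist_features <- function(lev, n_bins) {
  counts <- tabulate(lev, nbins = n_bins)
  p <- counts / sum(counts)
  q <- quantile(lev, c(.10, .25, .50, .75, .90), names = FALSE, type = 7)
  m <- mean(lev)
  rx <- lev[lev >= q[1] & lev <= q[5]]
  grad <- rep(NA_real_, n_bins)
  if (n_bins >= 2) {
    grad[1] <- counts[2] - counts[1]
    grad[n_bins] <- counts[n_bins] - counts[n_bins - 1]
    if (n_bins > 2)
      grad[2:(n_bins - 1)] <- (counts[3:n_bins] - counts[1:(n_bins - 2)]) / 2
  }
  pp <- p[p > 0]
  c(hist.mean = m,
    hist.variance = mean((lev - m)^2),
    hist.sd = sqrt(mean((lev - m)^2)),
    hist.skewness = pop_skew(lev),
    hist.kurtosis_excess = pop_kurt_excess(lev),
    hist.median = q[3],
    hist.min_level = min(lev),
    hist.max_level = max(lev),
    hist.mode = which.max(counts),
    hist.p10 = q[1], hist.p25 = q[2], hist.p75 = q[4], hist.p90 = q[5],
    hist.interquartile_range = q[4] - q[2],
    hist.range = max(lev) - min(lev),
    hist.mean_absolute_deviation = mean(abs(lev - m)),
    hist.robust_mean_absolute_deviation =
      if (length(rx)) mean(abs(rx - mean(rx))) else 0,
    hist.median_absolute_deviation = mean(abs(lev - q[3])),
    hist.coefficient_of_variation = if (m != 0) sqrt(mean((lev - m)^2)) / m else NaN,
    hist.quartile_coefficient_of_dispersion =
      if ((q[4] + q[2]) != 0) (q[4] - q[2]) / (q[4] + q[2]) else NaN,
    hist.entropy = -sum(pp * log2(pp)),
    hist.uniformity = sum(p^2),
    hist.max_gradient = max(grad),
    hist.max_gradient_level = which.max(grad),
    hist.min_gradient = min(grad),
    hist.min_gradient_level = which.min(grad))
}

# internal: intensity-volume-histogram block. nu = fractional intensity in
# [0,1]; v(gamma) = fraction of voxels with nu >= gamma; i_x = smallest gamma
# at which v(gamma) <= x.
ivh_features <- function(x) {
  lo <- min(x); hi <- max(x)
  if (hi == lo) {
    return(c(ivh.v10 = 1, ivh.v25 = 1, ivh.v75 = 1, ivh.v90 = 1,
             ivh.i10 = 0, ivh.i25 = 0, ivh.i75 = 0, ivh.i90 = 0,
             ivh.v10_minus_v90 = 0, ivh.i10_minus_i90 = 0, ivh.auc = 1))
  }
  nu <- (x - lo) / (hi - lo)
  gam <- seq(0, 1, length.out = 1001)
  vfrac <- vapply(gam, function(g) mean(nu >= g), numeric(1))
  vat <- function(g) mean(nu >= g)
  # i_x: smallest fractional intensity whose retained-volume fraction is <= x
  iat <- function(f) gam[which(vfrac <= f)[1]]
  c(ivh.v10 = vat(0.10), ivh.v25 = vat(0.25),
    ivh.v75 = vat(0.75), ivh.v90 = vat(0.90),
    ivh.i10 = iat(0.10), ivh.i25 = iat(0.25),
    ivh.i75 = iat(0.75), ivh.i90 = iat(0.90),
    ivh.v10_minus_v90 = vat(0.10) - vat(0.90),
    ivh.i10_minus_i90 = iat(0.10) - iat(0.90),
    ivh.auc = mean(vfrac))
}

# internal: mean intensity in a 1 cm^3 sphere around the hottest voxel
local_intensity_peak <- function(volume, mask, voxel_size_mm) {
  idx <- which(mask)
  peak <- idx[which.max(volume[idx])]
  pc <- arrayInd(peak, dim(volume))[1, ]
  r_mm <- (3 / (4 * pi))^(1 / 3) * 10          # radius of a 1 cm^3 sphere
  rad <- ceiling(r_mm / voxel_size_mm)
  d <- dim(volume)
  rng <- lapply(1:3, function(a)
    max(1, pc[a] - rad[a]):min(d[a], pc[a] + rad[a]))
  g <- expand.grid(x = rng[[1]], y = rng[[2]], z = rng[[3]])
  dist2 <- ((g$x - pc[1]) * voxel_size_mm[1])^2 +
           ((g$y - pc[2]) * voxel_size_mm[2])^2 +
           ((g$z - pc[3]) * voxel_size_mm[3])^2
  sel <- as.matrix(g[dist2 <= r_mm^2, ])
  mean(volume[sel])
}

#' Compute the 79 first-order features
#'
#' @param volume preprocessed numeric 3D array.
#' @param mask logical brain mask.
#' @param binned integer level array from [discretize()] (recomputed when
#'   omitted).
#' @param voxel_size_mm voxel size in mm.
#' @param n_bins bins used if `binned` is missing.
#' @return named numeric vector of length 79, in manifest order.
#' @export
first_order_features <- function(volume, mask, binned = NULL,
                                 voxel_size_mm = c(2, 2, 2), n_bins = 32) {
  check_vol_mask(volume, mask)
  if (is.null(binned)) binned <- discretize(volume, mask, n_bins)
  x <- volume[mask]
  lev <- binned[mask]
  out <- c(morphology_features(volume, mask, voxel_size_mm),
           stat_features(x),
           hist_features(lev, max(n_bins, max(lev))),
           ivh_features(x),
           loc.local_intensity_peak = local_intensity_peak(volume, mask, voxel_size_mm))
  stopifnot(length(out) == 79)
  out
}
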