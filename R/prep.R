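# Intensity preprocessing of template-space volumes: global-mean scaling and
# isotropic Gaussian smoothing, the two steps applied to every volume before
# feature extraction.

#' Convert a Gaussian FWHM in mm to per-axis sigma in voxel units
#'
#' `sigma_axis = fwhm / (2 * sqrt(2 * log(2))) / voxel_size_axis`.
#'
#' @param fwhm_mm full width at half maximum, mm.
#' @param voxel_size_mm voxel edge lengths in mm (length 3).
#' @return numeric triple of sigmas in voxel units.
#' @export
fwhm_to_sigma <- function(fwhm_mm, voxel_size_mm = c(2, 2, 2)) {
  stopifnot(fwhm_mm >= 0, all(voxel_size_mm > 0), length(voxel_size_mm) == 3)
  fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size_mm
}

# internal: discrete Gaussian kernel, unit mass, radius 4 sigma
gaussian_kernel_1d <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

#' Smooth a volume with an isotropic 3D Gaussian kernel
#'
#' Separable convolution with a unit-mass discrete Gaussian (radius 4 sigma
#' per axis); boundaries are handled by mirror reflection, so a constant
#' volume stays exactly constant. `fwhm_mm = 0` is the identity.
#'
#' @param volume numeric 3D array.
#' @param fwhm_mm kernel full width at half maximum, mm.
#' @param voxel_size_mm voxel edge lengths in mm.
#' @return smoothed numeric 3D array.
#' @export
smooth_volume <- function(volume, fwhm_mm, voxel_size_mm = c(2, 2, 2)) {
  stopifnot(length(dim(volume)) == 3, fwhm_mm >= 0)
  if (fwhm_mm == 0) return(volume)
  sig <- fwhm_to_sigma(fwhm_mm, voxel_size_mm)
  out <- cpp_sep_conv3d(volume,
                        gaussian_kernel_1d(sig[1]),
                        gaussian_kernel_1d(sig[2]),
                        gaussian_kernel_1d(sig[3]))
  array(out, dim = dim(volume))
}

#' Scale a volume so its in-mask mean equals a target value
#'
#' All voxels (inside and outside the mask) are multiplied by the same factor
#' `target / mean(volume[mask])`; only the in-mask mean defines the factor.
#'
#' @param volume numeric 3D array.
#' @param mask logical 3D array (brain mask).
#' @param target desired in-mask mean (default 1).
#' @return rescaled volume.
#' @export
global_mean_scale <- function(volume, mask, target = 1) {
  check_vol_mask(volume, mask)
  stopifnot(target > 0)
  m <- mean(volume[mask])
  if (!is.finite(m) || m <= 0)
    stop("in-mask mean must be positive to scale", call. = FALSE)
  volume * (target / m)
}

#' Preprocess one volume: smooth, then scale to the global mean
#'
#' @param volume numeric 3D array (already in template space).
#' @param mask logical brain mask.
#' @param fwhm_mm smoothing kernel FWHM in mm (default 8).
#' @param target in-mask mean after scaling (default 1).
#' @param voxel_size_mm voxel size in mm.
#' @return preprocessed volume.
#' @export
prep_volume <- function(volume, mask, fwhm_mm = 8, target = 1,
                        voxel_size_mm = c(2, 2, 2)) {
  global_mean_scale(smooth_volume(volume, fwhm_mm, voxel_size_mm), mask, target)
}
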