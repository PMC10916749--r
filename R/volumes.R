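# Volumes are plain numeric 3D arrays in a common template grid; the voxel
# size (mm) travels as an explicit argument where geometry matters. NIfTI-1
# I/O goes through RNifti.

#' Read a 3D volume from a NIfTI-1 file
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @return a numeric 3D array with attribute `voxel_size_mm`.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  vol <- array(as.numeric(img), dim = dim(img))
  attr(vol, "voxel_size_mm") <- RNifti::pixdim(img)[seq_len(3)]
  vol
}

#' Write a 3D volume to a NIfTI-1 file
#'
#' @param volume numeric 3D array.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param voxel_size_mm voxel edge lengths in mm (length 3).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, voxel_size_mm = c(2, 2, 2)) {
  stopifnot(length(dim(volume)) == 3)
  img <- RNifti::asNifti(array(volume, dim = dim(volume)))
  RNifti::pixdim(img) <- voxel_size_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Crop or zero-pad a volume to a target shape
#'
#' Centred crop/pad, used to bring template-grid volumes to the cubic input
#' shape of the 3D CNN.
#'
#' @param volume numeric 3D array.
#' @param shape target integer triple.
#' @return numeric 3D array with `dim == shape`.
#' @export
crop_pad <- function(volume, shape) {
  d <- dim(volume)
  stopifnot(length(d) == 3, length(shape) == 3)
  out <- array(0, dim = shape)
  # source and destination index ranges, centred
  idx <- lapply(seq_len(3), function(a) {
    n <- min(d[a], shape[a])
    s0 <- (d[a] - n) %/% 2
    t0 <- (shape[a] - n) %/% 2
    list(src = seq.int(s0 + 1, s0 + n), dst = seq.int(t0 + 1, t0 + n))
  })
  out[idx[[1]]$dst, idx[[2]]$dst, idx[[3]]$dst] <-
    volume[idx[[1]]$src, idx[[2]]$src, idx[[3]]$src]
  out
}

# internal: validate a volume/mask pair
check_vol_mask <- function(volume, mask) {
  if (!identical(dim(volume), dim(mask)))
    stop("volume and mask shapes differ", call. = FALSE)
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  invisible(TRUE)
}
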