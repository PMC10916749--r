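# Synthetic FDG-PET cohort in template space. Healthy controls carry a smooth
# baseline metabolic field; dementia subtypes additionally carry regional
# hypometabolism (a multiplicative intensity reduction inside a configurable
# ellipsoidal pattern region) applied before smoothing so the lesion border
# shows PET-like partial-volume blur. Everything is seeded per subject, so a
# cohort is bit-reproducible subject-wise regardless of generation order.

#' Configuration for the synthetic cohort generator
#'
#' Defaults reproduce the study conditions the pipeline emulates: a
#' 79 x 95 x 69 grid of 2 mm voxels, 125 healthy controls
#' (age 64.8 +/- 11.33 y) and 85 patients (age 73.9 +/- 6.8 y) split as
#' 38 AD + 2 MCI + 25 DLB + 20 FTD, 8 mm FWHM smoothing and global-mean
#' scaling.
#'
#' @param grid_shape integer triple, template grid.
#' @param voxel_size_mm voxel edge lengths in mm.
#' @param n_controls number of healthy controls.
#' @param n_patients_by_subtype named integer vector, patients per subtype
#'   (names must have entries in `pattern_masks`).
#' @param age_mean_sd_controls,age_mean_sd_patients mean/SD pairs in years;
#'   ages are redrawn until they fall in \[20, 95\].
#' @param pattern_masks named list of subtype region specifications, each a
#'   `list(centre=, semi_axes=)` in grid-fraction coordinates (see
#'   [default_pattern_masks()]).
#' @param hypometabolism_factor multiplicative intensity reduction inside the
#'   pattern region, in (0, 1]; 1 means no effect.
#' @param noise_sd relative (multiplicative) voxel noise SD.
#' @param baseline_field_sd SD of the smooth low-frequency baseline field.
#' @param baseline_field_fwhm_mm FWHM of the baseline-field smoothing.
#' @param smoothing_fwhm_mm final isotropic smoothing FWHM in mm.
#' @param seed integer master seed; per-subject streams are derived from it.
#' @return a `petrad_generator_config` list.
#' @export
generator_config <- function(grid_shape = c(79, 95, 69),
                             voxel_size_mm = c(2, 2, 2),
                             n_controls = 125,
                             n_patients_by_subtype = c(AD = 38, MCI = 2,
                                                       DLB = 25, FTD = 20),
                             age_mean_sd_controls = c(64.8, 11.33),
                             age_mean_sd_patients = c(73.9, 6.8),
                             pattern_masks = default_pattern_masks(),
                             hypometabolism_factor = 0.75,
                             noise_sd = 0.05,
                             baseline_field_sd = 0.03,
                             baseline_field_fwhm_mm = 24,
                             smoothing_fwhm_mm = 8,
                             seed = 42L) {
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 1),
            all(voxel_size_mm > 0),
            n_controls >= 0, all(n_patients_by_subtype >= 0),
            hypometabolism_factor > 0, hypometabolism_factor <= 1,
            noise_sd >= 0, smoothing_fwhm_mm >= 0)
  if (length(n_patients_by_subtype) > 0) {
    if (is.null(names(n_patients_by_subtype)) ||
        !all(names(n_patients_by_subtype) %in% names(pattern_masks)))
      stop("every patient subtype needs a pattern mask", call. = FALSE)
  }
  structure(list(grid_shape = as.integer(grid_shape),
                 voxel_size_mm = voxel_size_mm,
                 n_controls = as.integer(n_controls),
                 n_patients_by_subtype = n_patients_by_subtype,
                 age_mean_sd_controls = age_mean_sd_controls,
                 age_mean_sd_patients = age_mean_sd_patients,
                 pattern_masks = pattern_masks,
                 hypometabolism_factor = hypometabolism_factor,
                 noise_sd = noise_sd,
                 baseline_field_sd = baseline_field_sd,
                 baseline_field_fwhm_mm = baseline_field_fwhm_mm,
                 smoothing_fwhm_mm = smoothing_fwhm_mm,
                 seed = as.integer(seed)),
            class = "petrad_generator_config")
}

#' Default subtype hypometabolism regions
#'
#' Ellipsoids in grid-fraction coordinates, placed by the neurodegeneration
#' convention: AD-like posterior temporo-parietal, DLB-like occipital,
#' FTD-like frontal. The MCI-like pattern reuses the AD-like region (the
#' emulated MCI cases are converters to AD). They are labels of convenience
#' on a geometric phantom, not anatomical atlas regions; each covers roughly
#' 4-6% of the brain mask.
#'
#' @return named list of `list(centre, semi_axes)` specifications.
#' @export
default_pattern_masks <- function() {
  list(
    AD  = list(centre = c(0.50, 0.32, 0.55), semi_axes = c(0.20, 0.14, 0.14)),
    MCI = list(centre = c(0.50, 0.32, 0.55), semi_axes = c(0.20, 0.14, 0.14)),
    DLB = list(centre = c(0.50, 0.24, 0.50), semi_axes = c(0.18, 0.12, 0.12)),
    FTD = list(centre = c(0.50, 0.78, 0.55), semi_axes = c(0.18, 0.13, 0.13))
  )
}

# internal: centred ellipsoid mask given centre/semi-axes in grid fractions
ellipsoid_mask <- function(grid_shape, centre_frac, semi_frac) {
  g <- as.integer(grid_shape)
  cx <- centre_frac * g
  ax <- pmax(semi_frac * g, 1e-9)
  x <- (seq_len(g[1]) - 0.5 - cx[1]) / ax[1]
  y <- (seq_len(g[2]) - 0.5 - cx[2]) / ax[2]
  z <- (seq_len(g[3]) - 0.5 - cx[3]) / ax[3]
  r2 <- outer(outer(x^2, y^2, `+`), z^2, `+`)
  array(r2 <= 1, dim = g)
}

#' Build the template brain mask
#'
#' A centred ellipsoid with semi-axes 40% of each grid dimension stands in
#' for the template brain; it is identical for all subjects of a cohort.
#'
#' @param config a [generator_config()].
#' @return logical 3D array.
#' @export
make_brain_mask <- function(config = generator_config()) {
  g <- config$grid_shape
  if (any(g < 8)) stop("degenerate grid: every dimension must be >= 8", call. = FALSE)
  ellipsoid_mask(g, centre_frac = c(0.5, 0.5, 0.5), semi_frac = c(0.4, 0.4, 0.4))
}

#' Build one subtype's hypometabolism pattern mask
#'
#' The configured ellipsoid intersected with the brain mask, so the pattern
#' region always lies inside the brain.
#'
#' @param subtype subtype name present in `config$pattern_masks`.
#' @param config a [generator_config()].
#' @param brain_mask optional precomputed brain mask.
#' @return logical 3D array.
#' @export
make_pattern_mask <- function(subtype, config = generator_config(),
                              brain_mask = make_brain_mask(config)) {
  spec <- config$pattern_masks[[subtype]]
  if (is.null(spec)) stop("unknown subtype: ", subtype, call. = FALSE)
  m <- ellipsoid_mask(config$grid_shape, spec$centre, spec$semi_axes) & brain_mask
  if (!any(m)) stop("pattern mask for ", subtype, " is empty", call. = FALSE)
  m
}

# internal: deterministic 31-polynomial string hash folded with the master
# seed; keeps every derived seed below 2^31.
subject_seed <- function(seed, subject_id, salt = "") {
  h <- 0
  for (ch in utf8ToInt(paste0(subject_id, salt)))
    h <- (h * 31 + ch) %% 2147483647
  as.integer((h + as.numeric(seed)) %% 2147483647)
}

#' Simulate one subject's preprocessed FDG-PET volume
#'
#' Baseline = 1 plus a low-frequency Gaussian-filtered field; for dementia
#' subjects the subtype's pattern region is multiplied by
#' `hypometabolism_factor` before noise; multiplicative voxel noise is added;
#' the volume is then smoothed at `smoothing_fwhm_mm` and scaled to unit
#' in-mask mean. Deterministic given `(config$seed, subject_id)`.
#'
#' @param record one-row tibble or list with `subject_id`, `group`, `subtype`.
#' @param mask brain mask from [make_brain_mask()].
#' @param config a [generator_config()].
#' @return numeric 3D array, non-negative, zero outside the brain mask.
#' @export
simulate_subject <- function(record, mask, config = generator_config()) {
  g <- config$grid_shape
  set.seed(subject_seed(config$seed, record$subject_id))
  field <- array(rnorm(prod(g)), dim = g)
  field <- smooth_volume(field, config$baseline_field_fwhm_mm, config$voxel_size_mm)
  s <- sd(field)
  if (s > 0) field <- field / s * config$baseline_field_sd
  vol <- 1 + field
  if (record$group == "dementia") {
    pm <- make_pattern_mask(record$subtype, config, mask)
    vol[pm] <- vol[pm] * config$hypometabolism_factor
  } else if (record$subtype != "HC") {
    stop("unknown subtype for control: ", record$subtype, call. = FALSE)
  }
  if (config$noise_sd > 0)
    vol <- vol * (1 + array(rnorm(prod(g), sd = config$noise_sd), dim = g))
  vol[!mask] <- 0
  vol <- smooth_volume(vol, config$smoothing_fwhm_mm, config$voxel_size_mm)
  vol[vol < 0] <- 0
  global_mean_scale(vol, mask, target = 1)
}

# internal: truncated-normal age draw (redraw until in [20, 95])
draw_age <- function(mean, sd) {
  repeat {
    a <- rnorm(1, mean, sd)
    if (a >= 20 && a <= 95) return(a)
  }
}

#' Build the subjects table for a cohort
#'
#' Controls first (`hc001`, ...), then patients grouped by subtype in the
#' order of `n_patients_by_subtype`. Ages are drawn from the configured
#' truncated normals using a per-subject stream.
#'
#' @param config a [generator_config()].
#' @return tibble with `subject_id`, `group`, `subtype`, `age`.
#' @export
cohort_records <- function(config = generator_config()) {
  ids <- character(0); groups <- character(0); subtypes <- character(0)
  if (config$n_controls > 0) {
    ids <- sprintf("hc%03d", seq_len(config$n_controls))
    groups <- rep("control", config$n_controls)
    subtypes <- rep("HC", config$n_controls)
  }
  for (st in names(config$n_patients_by_subtype)) {
    n <- config$n_patients_by_subtype[[st]]
    if (n == 0) next
    ids <- c(ids, sprintf("%s%03d", tolower(st), seq_len(n)))
    groups <- c(groups, rep("dementia", n))
    subtypes <- c(subtypes, rep(st, n))
  }
  ages <- vapply(seq_along(ids), function(i) {
    ms <- if (groups[i] == "control") config$age_mean_sd_controls
          else config$age_mean_sd_patients
    set.seed(subject_seed(config$seed, ids[i], salt = "#age"))
    draw_age(ms[1], ms[2])
  }, numeric(1))
  tibble::tibble(subject_id = ids, group = groups, subtype = subtypes, age = ages)
}

#' Simulate a full synthetic cohort
#'
#' @param config a [generator_config()].
#' @return list with `records` (tibble), `volumes` (named list of 3D arrays,
#'   in `records` order) and `mask` (logical 3D array).
#' @export
simulate_cohort <- function(config = generator_config()) {
  records <- cohort_records(config)
  mask <- make_brain_mask(config)
  volumes <- lapply(seq_len(nrow(records)), function(i)
    simulate_subject(records[i, ], mask, config))
  names(volumes) <- records$subject_id
  list(records = records, volumes = volumes, mask = mask)
}

#' Write a cohort to disk as NIfTI volumes plus a participants table
#'
#' @param cohort result of [simulate_cohort()].
#' @param dir output directory (created if missing).
#' @param voxel_size_mm voxel size recorded in the NIfTI headers.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, voxel_size_mm = c(2, 2, 2)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(cohort$records, file.path(dir, "participants.csv"), row.names = FALSE)
  write_volume(cohort$mask * 1, file.path(dir, "brain_mask.nii.gz"), voxel_size_mm)
  for (id in names(cohort$volumes))
    write_volume(cohort$volumes[[id]], file.path(dir, paste0(id, ".nii.gz")),
                 voxel_size_mm)
  invisible(dir)
}
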