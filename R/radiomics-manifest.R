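# The fixed, versioned feature manifest: 79 first-order features (morphology,
# intensity statistics, intensity histogram, intensity-volume histogram,
# local intensity) and 136 texture features over six gray-level matrix
# families. The two directional families (GLCM, GLRLM) contribute both a
# merged-matrix variant (counts pooled over the 13 unique 3D directions) and
# a direction-averaged variant (features computed per direction, then
# averaged), the way IBSI-style frameworks report both aggregations.

glcm_feature_names <- function() c(
  "joint_maximum", "joint_average", "joint_variance", "joint_entropy",
  "difference_average", "difference_variance", "difference_entropy",
  "sum_average", "sum_variance", "sum_entropy",
  "angular_second_moment", "contrast", "dissimilarity",
  "inverse_difference", "inverse_difference_normalised",
  "inverse_difference_moment", "inverse_difference_moment_normalised",
  "inverse_variance", "correlation", "autocorrelation",
  "cluster_tendency", "cluster_shade", "cluster_prominence",
  "information_correlation_1", "information_correlation_2")

# run/size/distance-style families share a 16-feature scheme; `jword` names
# the column axis (run_length, zone_size, zone_distance)
rlm_feature_names <- function(short, long, jword) c(
  short, long,
  "low_gray_level_emphasis", "high_gray_level_emphasis",
  paste0(sub("_emphasis$", "", short), "_low_gray_level_emphasis"),
  paste0(sub("_emphasis$", "", short), "_high_gray_level_emphasis"),
  paste0(sub("_emphasis$", "", long), "_low_gray_level_emphasis"),
  paste0(sub("_emphasis$", "", long), "_high_gray_level_emphasis"),
  "gray_level_nonuniformity", "gray_level_nonuniformity_normalised",
  paste0(jword, "_nonuniformity"), paste0(jword, "_nonuniformity_normalised"),
  switch(jword, run_length = "run_percentage", zone_size = "zone_percentage",
         zone_distance = "zone_percentage"),
  "gray_level_variance", paste0(jword, "_variance"), paste0(jword, "_entropy"))

ngldm_feature_names <- function() c(
  "low_dependence_emphasis", "high_dependence_emphasis",
  "low_gray_level_count_emphasis", "high_gray_level_count_emphasis",
  "low_dependence_low_gray_level_emphasis",
  "low_dependence_high_gray_level_emphasis",
  "high_dependence_low_gray_level_emphasis",
  "high_dependence_high_gray_level_emphasis",
  "gray_level_nonuniformity", "gray_level_nonuniformity_normalised",
  "dependence_count_nonuniformity", "dependence_count_nonuniformity_normalised",
  "dependence_count_percentage", "gray_level_variance",
  "dependence_count_variance", "dependence_count_entropy",
  "dependence_count_energy")

ngtdm_feature_names <- function() c(
  "coarseness", "contrast", "busyness", "complexity", "strength")

first_order_names <- function() {
  morph <- paste0("morph.", c(
    "voxel_count", "volume_mm3", "surface_area_mm2", "surface_to_volume_ratio",
    "compactness_1", "compactness_2", "spherical_disproportion", "sphericity",
    "equivalent_sphere_diameter", "major_axis_length", "minor_axis_length",
    "least_axis_length", "elongation", "flatness", "centre_of_mass_shift_mm",
    "bounding_box_volume_mm3", "bounding_box_extent"))
  stat <- paste0("stat.", c(
    "mean", "variance", "sd", "skewness", "kurtosis_excess", "median",
    "minimum", "maximum", "range", "p5", "p10", "p25", "p75", "p90", "p95",
    "interquartile_range", "mean_absolute_deviation",
    "robust_mean_absolute_deviation", "median_absolute_deviation",
    "coefficient_of_variation", "quartile_coefficient_of_dispersion",
    "energy", "root_mean_square", "total_sum"))
  hist <- paste0("hist.", c(
    "mean", "variance", "sd", "skewness", "kurtosis_excess", "median",
    "min_level", "max_level", "mode", "p10", "p25", "p75", "p90",
    "interquartile_range", "range", "mean_absolute_deviation",
    "robust_mean_absolute_deviation", "median_absolute_deviation",
    "coefficient_of_variation", "quartile_coefficient_of_dispersion",
    "entropy", "uniformity", "max_gradient", "max_gradient_level",
    "min_gradient", "min_gradient_level"))
  ivh <- paste0("ivh.", c(
    "v10", "v25", "v75", "v90", "i10", "i25", "i75", "i90",
    "v10_minus_v90", "i10_minus_i90", "auc"))
  c(morph, stat, hist, ivh, "loc.local_intensity_peak")
}

#' The fixed 215-entry radiomic feature manifest
#'
#' 79 first-order features (17 morphology, 24 intensity statistics, 26
#' intensity-histogram, 11 intensity-volume-histogram, 1 local intensity)
#' plus 136 texture features: GLCM (25 merged + 25 direction-averaged),
#' GLRLM (16 + 16), GLSZM (16), GLDZM (16), NGLDM (17), NGTDM (5). The order
#' of this tibble is the canonical feature order of every extracted vector.
#'
#' @return tibble with columns `name`, `family`, `category`.
#' @export
feature_manifest <- function() {
  fo <- first_order_names()
  tex <- c(paste0("glcm.", glcm_feature_names()),
           paste0("glcm_avg.", glcm_feature_names()),
           paste0("glrlm.", rlm_feature_names("short_run_emphasis",
                                              "long_run_emphasis", "run_length")),
           paste0("glrlm_avg.", rlm_feature_names("short_run_emphasis",
                                                  "long_run_emphasis", "run_length")),
           paste0("glszm.", rlm_feature_names("small_zone_emphasis",
                                              "large_zone_emphasis", "zone_size")),
           paste0("gldzm.", rlm_feature_names("small_distance_emphasis",
                                              "large_distance_emphasis", "zone_distance")),
           paste0("ngldm.", ngldm_feature_names()),
           paste0("ngtdm.", ngtdm_feature_names()))
  tibble::tibble(
    name = c(fo, tex),
    family = sub("\\..*$", "", c(fo, tex)),
    category = c(rep("first_order", length(fo)), rep("texture", length(tex))))
}
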