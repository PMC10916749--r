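# Texture matrix families: GLCM, GLRLM, GLSZM, GLDZM, NGLDM, NGTDM, all in
# 3D over the whole-brain VOI. GLCM and GLRLM are directional and computed
# over the 13 unique direction vectors at Chebyshev distance 1; the other
# four use the full 26-neighbourhood / 26-connected zones.

#' Configuration of the radiomic extraction
#'
#' @param n_bins number of gray levels for fixed-bin-number discretization
#'   (default 32).
#' @param gldm_alpha gray-level dependence tolerance `alpha` (default 0): a
#'   neighbour with level `j` is dependent on a centre of level `i` when
#'   `|i - j| <= alpha`.
#' @param neighborhood_delta Chebyshev neighbourhood radius `delta`
#'   (default 1, i.e. 26 neighbours) for NGLDM/NGTDM.
#' @return a `petrad_extraction_config` list.
#' @export
extraction_config <- function(n_bins = 32, gldm_alpha = 0,
                              neighborhood_delta = 1) {
  stopifnot(n_bins >= 2, gldm_alpha >= 0, neighborhood_delta >= 1)
  structure(list(n_bins = as.integer(n_bins),
                 gldm_alpha = as.integer(gldm_alpha),
                 neighborhood_delta = as.integer(neighborhood_delta)),
            class = "petrad_extraction_config")
}

new_texture_matrix <- function(family, counts, n_voxels, n_bins,
                               per_direction = NULL) {
  structure(list(family = family, counts = counts, total = sum(counts),
                 n_voxels = n_voxels, n_bins = n_bins,
                 per_direction = per_direction),
            class = "petrad_texture_matrix")
}

#' @export
print.petrad_texture_matrix <- function(x, ...) {
  cat(sprintf("<%s texture matrix: %d x %d, total %s, %d voxels>\n",
              x$family, nrow(x$counts), ncol(x$counts),
              format(x$total), x$n_voxels))
  invisible(x)
}

# internal: number of in-mask voxels of a binned volume
n_inmask <- function(binned) sum(binned > 0L)

#' Gray-level co-occurrence matrix (3D, symmetric)
#'
#' Counts pooled over the 13 unique direction vectors at Chebyshev distance
#' 1, each pair counted in both orders (symmetric matrix); `per_direction`
#' holds the 13 separate matrices.
#'
#' @param binned integer level array from [discretize()] (0 outside mask).
#' @param config an [extraction_config()].
#' @return a `petrad_texture_matrix` (level x level counts).
#' @export
glcm <- function(binned, config = extraction_config()) {
  arr <- cpp_glcm(binned, config$n_bins)
  new_texture_matrix("GLCM", apply(arr, c(1, 2), sum), n_inmask(binned),
                     config$n_bins, per_direction = arr)
}

#' Gray-level run-length matrix (3D)
#'
#' Maximal runs of equal level counted per direction over the 13 unique 3D
#' directions; merged counts pool all directions.
#'
#' @inheritParams glcm
#' @return a `petrad_texture_matrix` (level x run length).
#' @export
glrlm <- function(binned, config = extraction_config()) {
  arr <- cpp_glrlm(binned, config$n_bins)
  new_texture_matrix("GLRLM", apply(arr, c(1, 2), sum), n_inmask(binned),
                     config$n_bins, per_direction = arr)
}

# internal: zone list (level, size, border distance) via 26-connected flood
# fill; distance = city-block distance to the nearest out-of-mask voxel
zone_list <- function(binned) {
  dm <- cpp_distance_map(binned)
  cpp_zones(binned, dm)
}

# internal: dense counts matrix from (i, j) pairs
pairs_to_matrix <- function(i, j, n_bins, jmax) {
  M <- matrix(0, n_bins, jmax)
  tab <- dplyr::count(tibble::tibble(i = i, j = j), i, j)
  M[cbind(tab$i, tab$j)] <- tab$n
  M
}

#' Gray-level size-zone matrix (3D, 26-connected zones)
#'
#' @inheritParams glcm
#' @return a `petrad_texture_matrix` (level x zone size).
#' @export
glszm <- function(binned, config = extraction_config()) {
  z <- zone_list(binned)
  jmax <- max(z$size, 1L)
  new_texture_matrix("GLSZM", pairs_to_matrix(z$level, z$size,
                                              config$n_bins, jmax),
                     n_inmask(binned), config$n_bins)
}

#' Gray-level distance-zone matrix (3D)
#'
#' Same zones as [glszm()]; each zone is indexed by the minimum over its
#' voxels of the city-block distance to the mask border (border voxels have
#' distance 1).
#'
#' @inheritParams glcm
#' @return a `petrad_texture_matrix` (level x zone distance).
#' @export
gldzm <- function(binned, config = extraction_config()) {
  z <- zone_list(binned)
  jmax <- max(z$distance, 1L)
  new_texture_matrix("GLDZM", pairs_to_matrix(z$level, z$distance,
                                              config$n_bins, jmax),
                     n_inmask(binned), config$n_bins)
}

#' Neighbouring gray-level dependence matrix
#'
#' For each in-mask voxel of level `i`, `k` = number of in-mask neighbours
#' within Chebyshev distance `delta` whose level differs from `i` by at most
#' `alpha`; the dependence count is stored as `j = k + 1`, so `j >= 1` and
#' division by `j^2` in the emphasis features is always defined. The total
#' count equals the number of in-mask voxels.
#'
#' @inheritParams glcm
#' @return a `petrad_texture_matrix` (level x dependence count).
#' @export
ngldm <- function(binned, config = extraction_config()) {
  M <- cpp_ngldm(binned, config$n_bins, config$gldm_alpha,
                 config$neighborhood_delta)
  new_texture_matrix("NGLDM", M, n_inmask(binned), config$n_bins)
}

#' Neighbourhood gray-tone difference matrix
#'
#' Per level `i`: `s_i` = sum over in-mask voxels of level `i` of
#' `|i - mean level of in-mask neighbours|`, with occurrence counts `n_i`
#' (voxels with no in-mask neighbour are skipped).
#'
#' @inheritParams glcm
#' @return a `petrad_texture_matrix` whose `counts` is a two-column matrix
#'   `cbind(s, n)` with one row per gray level.
#' @export
ngtdm <- function(binned, config = extraction_config()) {
  r <- cpp_ngtdm(binned, config$n_bins, config$neighborhood_delta)
  new_texture_matrix("NGTDM", cbind(s = r$s, n = r$n), n_inmask(binned),
                     config$n_bins)
}

## ---- feature formulas --------------------------------------------------

# internal: 25 GLCM features from a (possibly unnormalized) co-occurrence
# matrix; returns NaN-flagged values when the matrix is empty or degenerate.
glcm_features_from_matrix <- function(M) {
  nms <- glcm_feature_names()
  Ng <- nrow(M)
  tot <- sum(M)
  if (tot == 0) return(setNames(rep(NaN, length(nms)), nms))
  P <- M / tot
  ii <- row(P); jj <- col(P)
  px <- rowSums(P)
  mu <- sum(ii * P)
  ent <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  # diagonal (difference) and cross-diagonal (sum) probabilities
  dk <- 0:(Ng - 1)
  pd <- vapply(dk, function(k) sum(P[abs(ii - jj) == k]), numeric(1))
  sk <- 2:(2 * Ng)
  ps <- vapply(sk, function(k) sum(P[(ii + jj) == k]), numeric(1))
  da <- sum(dk * pd); sa <- sum(sk * ps)
  varx <- sum((ii - mu)^2 * P)
  aut <- sum(ii * jj * P)
  hx <- ent(px)
  pxy <- outer(px, px)
  sel <- P > 0 & pxy > 0
  hxy <- ent(P)
  hxy1 <- -sum(P[sel] * log2(pxy[sel]))
  hxy2 <- ent(pxy)
  ic2arg <- 1 - exp(-2 * (hxy2 - hxy))
  out <- c(
    max(P), mu, varx, hxy,
    da, sum((dk - da)^2 * pd), ent(pd),
    sa, sum((sk - sa)^2 * ps), ent(ps),
    sum(P^2), sum((ii - jj)^2 * P), sum(abs(ii - jj) * P),
    sum(P / (1 + abs(ii - jj))), sum(P / (1 + abs(ii - jj) / Ng)),
    sum(P / (1 + (ii - jj)^2)), sum(P / (1 + (ii - jj)^2 / Ng^2)),
    sum(P[ii != jj] / (ii - jj)[ii != jj]^2),
    if (varx > 0) (aut - mu^2) / varx else NaN,
    aut,
    sum((ii + jj - 2 * mu)^2 * P),
    sum((ii + jj - 2 * mu)^3 * P),
    sum((ii + jj - 2 * mu)^4 * P),
    if (hx > 0) (hxy - hxy1) / hx else NaN,
    if (ic2arg >= 0) sqrt(ic2arg) else NaN)
  setNames(out, nms)
}

# internal: the 16 run/zone/distance-style features from a counts matrix.
# rows = gray level i, columns = j (run length / zone size / zone distance);
# `nv_den` is the denominator of the percentage feature.
rlm_features_from_matrix <- function(M, nv_den, nms) {
  tot <- sum(M)
  if (tot == 0) return(setNames(rep(NaN, length(nms)), nms))
  iv <- seq_len(nrow(M)); jv <- seq_len(ncol(M))
  r <- rowSums(M); cc <- colSums(M)
  P <- M / tot
  mui <- sum(rowSums(P) * iv)
  muj <- sum(colSums(P) * jv)
  out <- c(
    sum(cc / jv^2) / tot, sum(cc * jv^2) / tot,
    sum(r / iv^2) / tot, sum(r * iv^2) / tot,
    sum(sweep(sweep(M, 1, iv^2, `/`), 2, jv^2, `/`)) / tot,
    sum(sweep(sweep(M, 1, iv^2, `*`), 2, jv^2, `/`)) / tot,
    sum(sweep(sweep(M, 1, iv^2, `/`), 2, jv^2, `*`)) / tot,
    sum(sweep(sweep(M, 1, iv^2, `*`), 2, jv^2, `*`)) / tot,
    sum(r^2) / tot, sum(r^2) / tot^2,
    sum(cc^2) / tot, sum(cc^2) / tot^2,
    tot / nv_den,
    sum(sweep(P, 1, (iv - mui)^2, `*`)),
    sum(sweep(P, 2, (jv - muj)^2, `*`)),
    { p <- P[P > 0]; -sum(p * log2(p)) })
  setNames(out, nms)
}

#' Per-family texture feature vectors
#'
#' Compute the named feature set of one texture matrix family. For GLCM and
#' GLRLM, `aggregation` chooses between the merged matrix (counts pooled
#' over the 13 directions) and direction-averaged features.
#'
#' @param m a `petrad_texture_matrix` from the matching builder.
#' @param aggregation `"merged"` or `"average"` (directional families only).
#' @return named numeric vector (25 for GLCM, 16 for GLRLM/GLSZM/GLDZM,
#'   17 for NGLDM, 5 for NGTDM).
#' @export
glcm_features <- function(m, aggregation = c("merged", "average")) {
  aggregation <- match.arg(aggregation)
  stopifnot(m$family == "GLCM")
  if (aggregation == "merged") return(glcm_features_from_matrix(m$counts))
  per <- apply(m$per_direction, 3, glcm_features_from_matrix)
  rowMeans(per, na.rm = FALSE)
}

#' @rdname glcm_features
#' @export
glrlm_features <- function(m, aggregation = c("merged", "average")) {
  aggregation <- match.arg(aggregation)
  stopifnot(m$family == "GLRLM")
  nms <- rlm_feature_names("short_run_emphasis", "long_run_emphasis", "run_length")
  if (aggregation == "merged")
    return(rlm_features_from_matrix(m$counts, 13 * m$n_voxels, nms))
  per <- apply(m$per_direction, 3, rlm_features_from_matrix,
               nv_den = m$n_voxels, nms = nms)
  rowMeans(per, na.rm = FALSE)
}

#' @rdname glcm_features
#' @export
glszm_features <- function(m) {
  stopifnot(m$family == "GLSZM")
  rlm_features_from_matrix(m$counts, m$n_voxels,
                           rlm_feature_names("small_zone_emphasis",
                                             "large_zone_emphasis", "zone_size"))
}

#' @rdname glcm_features
#' @export
gldzm_features <- function(m) {
  stopifnot(m$family == "GLDZM")
  rlm_features_from_matrix(m$counts, m$n_voxels,
                           rlm_feature_names("small_distance_emphasis",
                                             "large_distance_emphasis", "zone_distance"))
}

#' @rdname glcm_features
#' @export
ngldm_features <- function(m) {
  stopifnot(m$family == "NGLDM")
  base <- rlm_features_from_matrix(
    m$counts, m$n_voxels,
    c("low_dependence_emphasis", "high_dependence_emphasis",
      "low_gray_level_count_emphasis", "high_gray_level_count_emphasis",
      "low_dependence_low_gray_level_emphasis",
      "low_dependence_high_gray_level_emphasis",
      "high_dependence_low_gray_level_emphasis",
      "high_dependence_high_gray_level_emphasis",
      "gray_level_nonuniformity", "gray_level_nonuniformity_normalised",
      "dependence_count_nonuniformity",
      "dependence_count_nonuniformity_normalised",
      "dependence_count_percentage", "gray_level_variance",
      "dependence_count_variance", "dependence_count_entropy"))
  tot <- sum(m$counts)
  c(base, dependence_count_energy = if (tot > 0) sum((m$counts / tot)^2) else NaN)
}

#' @rdname glcm_features
#' @export
ngtdm_features <- function(m) {
  stopifnot(m$family == "NGTDM")
  s <- m$counts[, "s"]; n <- m$counts[, "n"]
  nms <- ngtdm_feature_names()
  nv <- sum(n)
  if (nv == 0) return(setNames(rep(NaN, length(nms)), nms))
  p <- n / nv
  pres <- which(p > 0)
  ngp <- length(pres)
  iv <- seq_along(p)
  coarse <- { d <- sum(p * s); if (d > 0) min(1 / d, 1e6) else 1e6 }
  if (ngp > 1) {
    ij <- expand.grid(i = pres, j = pres)
    contrast <- sum(p[ij$i] * p[ij$j] * (ij$i - ij$j)^2) /
      (ngp * (ngp - 1)) * sum(s) / nv
    busy_den <- sum(abs(ij$i * p[ij$i] - ij$j * p[ij$j]))
    busy <- if (busy_den > 0) sum(p * s) / busy_den else NaN
    compl <- sum(abs(ij$i - ij$j) *
                   (p[ij$i] * s[ij$i] + p[ij$j] * s[ij$j]) /
                   (p[ij$i] + p[ij$j])) / nv
    strength <- if (sum(s) > 0)
      sum((p[ij$i] + p[ij$j]) * (ij$i - ij$j)^2) / sum(s) else NaN
  } else {
    contrast <- NaN; busy <- NaN; compl <- NaN; strength <- NaN
  }
  setNames(c(coarse, contrast, busy, compl, strength), nms)
}

#' Dependence count non-uniformity of an NGLDM
#'
#' `DN = sum_j (sum_i P(i,j))^2 / Nz`; lower values indicate more homogeneous
#' dependence structure.
#'
#' @param m a `petrad_texture_matrix` from [ngldm()].
#' @return scalar feature value.
#' @export
ngldm_dependence_count_nonuniformity <- function(m) {
  stopifnot(m$family == "NGLDM")
  if (sum(m$counts) == 0) stop("empty dependence matrix", call. = FALSE)
  sum(colSums(m$counts)^2) / sum(m$counts)
}

#' Low dependence low gray-level emphasis of an NGLDM
#'
#' `LDLGLE = (sum_ij P(i,j) / (i^2 j^2)) / Nz`; large when mass sits at small
#' dependence counts and low gray levels.
#'
#' @inheritParams ngldm_dependence_count_nonuniformity
#' @return scalar feature value.
#' @export
ngldm_low_dependence_low_gray_level_emphasis <- function(m) {
  stopifnot(m$family == "NGLDM")
  if (sum(m$counts) == 0) stop("empty dependence matrix", call. = FALSE)
  iv <- seq_len(nrow(m$counts)); jv <- seq_len(ncol(m$counts))
  sum(sweep(sweep(m$counts, 1, iv^2, `/`), 2, jv^2, `/`)) / sum(m$counts)
}

#' Extract the full 215-entry radiomic feature vector
#'
#' Discretizes the preprocessed volume over the VOI and computes the 79
#' first-order and 136 texture features of [feature_manifest()], in manifest
#' order. Values that are undefined for an input (degenerate matrices) are
#' returned as `NaN`, never dropped.
#'
#' @param volume preprocessed numeric 3D array.
#' @param mask logical brain mask.
#' @param config an [extraction_config()].
#' @param voxel_size_mm voxel size in mm.
#' @return named numeric vector of length 215.
#' @export
extract_all <- function(volume, mask, config = extraction_config(),
                        voxel_size_mm = c(2, 2, 2)) {
  check_vol_mask(volume, mask)
  binned <- discretize(volume, mask, config$n_bins)
  fo <- first_order_features(volume, mask, binned, voxel_size_mm, config$n_bins)
  mc <- glcm(binned, config)
  mr <- glrlm(binned, config)
  # both zone families share one flood fill
  z <- zone_list(binned)
  nv <- n_inmask(binned)
  msz <- new_texture_matrix("GLSZM",
                            pairs_to_matrix(z$level, z$size, config$n_bins,
                                            max(z$size, 1L)), nv, config$n_bins)
  mdz <- new_texture_matrix("GLDZM",
                            pairs_to_matrix(z$level, z$distance, config$n_bins,
                                            max(z$distance, 1L)), nv, config$n_bins)
  pre <- function(prefix, v) setNames(v, paste0(prefix, ".", names(v)))
  tex <- c(pre("glcm", glcm_features(mc, "merged")),
           pre("glcm_avg", glcm_features(mc, "average")),
           pre("glrlm", glrlm_features(mr, "merged")),
           pre("glrlm_avg", glrlm_features(mr, "average")),
           pre("glszm", glszm_features(msz)),
           pre("gldzm", gldzm_features(mdz)),
           pre("ngldm", ngldm_features(ngldm(binned, config))),
           pre("ngtdm", ngtdm_features(ngtdm(binned, config))))
  out <- c(fo, tex)
  manifest <- feature_manifest()$name
  if (!identical(names(out), manifest))
    stop("internal error: feature order does not match the manifest")
  out
}

#' Extract features for every subject of a cohort
#'
#' @param cohort a [simulate_cohort()] result (or a compatible list with
#'   `records`, `volumes`, `mask`).
#' @param config an [extraction_config()].
#' @param voxel_size_mm voxel size in mm.
#' @return tibble: `subject_id`, `group`, `subtype`, `age`, then the 215
#'   feature columns.
#' @export
extract_cohort <- function(cohort, config = extraction_config(),
                           voxel_size_mm = c(2, 2, 2)) {
  feats <- lapply(cohort$volumes, extract_all, mask = cohort$mask,
                  config = config, voxel_size_mm = voxel_size_mm)
  dplyr::bind_cols(cohort$records,
                   tibble::as_tibble(do.call(rbind, feats)))
}
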