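# Single-subject voxel-wise comparison against a control group: per voxel an
# ordinary least-squares fit of intensity on [intercept, patient indicator,
# age]; the t statistic of the patient indicator, thresholded and filtered by
# cluster extent, flags candidate hypometabolic regions.

#' Voxel-wise GLM t-map for one patient versus a control group
#'
#' Per in-mask voxel, OLS of intensity on intercept, a patient indicator
#' (patient coded 1) and age; `t` is the indicator coefficient over its
#' standard error, with `df = n_subjects - 3`. Negative `t` means the patient
#' is hypometabolic relative to age-adjusted controls. Voxels with (near)
#' zero residual variance get `t = 0` and are flagged.
#'
#' @param patient numeric 3D array, the patient volume.
#' @param controls list of control volumes (>= 4), same shape.
#' @param ages numeric vector of ages, patient first then controls, in the
#'   order of `controls`.
#' @param mask logical brain mask.
#' @return a `petrad_tmap`: list with 3D arrays `t` and `p` (two-sided, NA
#'   outside the mask), `df`, `mask`, and `degenerate` (logical 3D array).
#' @export
voxelwise_glm_t <- function(patient, controls, ages, mask) {
  if (length(controls) < 4) stop("need at least 4 controls", call. = FALSE)
  check_vol_mask(patient, mask)
  for (v in controls) check_vol_mask(v, mask)
  n <- length(controls) + 1L
  if (length(ages) != n) stop("ages must cover patient + all controls", call. = FALSE)
  sel <- which(mask)
  Y <- vapply(c(list(patient), controls), function(v) v[sel],
              numeric(length(sel)))            # V x n
  X <- cbind(1, c(1, rep(0, n - 1L)), ages)    # n x 3
  df <- n - 3L
  if (df < 1) stop("not enough subjects for the model", call. = FALSE)
  XtXinv <- solve(crossprod(X))
  B <- Y %*% X %*% XtXinv                       # V x 3 (coefficients)
  resid <- Y - B %*% t(X)
  s2 <- rowSums(resid^2) / df
  se <- sqrt(s2 * XtXinv[2, 2])
  degen <- se < sqrt(.Machine$double.eps) * pmax(1, abs(B[, 2]))
  tval <- ifelse(degen, 0, B[, 2] / ifelse(se > 0, se, 1))
  pval <- 2 * pt(-abs(tval), df)
  pval[degen] <- 1
  tmap <- array(NA_real_, dim = dim(patient)); tmap[sel] <- tval
  pmap <- array(NA_real_, dim = dim(patient)); pmap[sel] <- pval
  dmap <- array(FALSE, dim = dim(patient));    dmap[sel] <- degen
  structure(list(t = tmap, p = pmap, df = df, mask = mask, degenerate = dmap),
            class = "petrad_tmap")
}

# internal: neighbour offset matrix for a connectivity scheme
connectivity_offsets <- function(connectivity = 18) {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nz <- rowSums(abs(g))
  keep <- switch(as.character(connectivity),
                 "6" = nz == 1,
                 "18" = nz >= 1 & nz <= 2,
                 "26" = nz >= 1,
                 stop("connectivity must be 6, 18 or 26", call. = FALSE))
  storage.mode(g) <- "integer"
  unname(g[keep, , drop = FALSE])
}

#' Extract suprathreshold clusters from a t-map
#'
#' Voxels with `p < p_threshold` (restricted by direction: `hypo` keeps
#' `t < 0`, `hyper` keeps `t > 0`) are labeled into connected components;
#' only components with strictly more than `min_extent` voxels are reported,
#' sorted by size (largest first). Voxel coordinates are 1-based array
#' indices.
#'
#' @param tmap a `petrad_tmap`.
#' @param p_threshold uncorrected two-sided p threshold (default 0.01).
#' @param min_extent strict lower bound on cluster size in voxels
#'   (default 100: a 100-voxel cluster is excluded).
#' @param direction `"hypo"`, `"hyper"` or `"two_sided"`.
#' @param connectivity 6, 18 (default) or 26.
#' @return a `petrad_clusters` tibble: `cluster`, `n_voxels`, `peak_t`,
#'   `peak_x/y/z`, `centroid_x/y/z`; attributes carry the labeled array and
#'   parameters.
#' @export
extract_clusters <- function(tmap, p_threshold = 0.01, min_extent = 100,
                             direction = c("hypo", "hyper", "two_sided"),
                             connectivity = 18) {
  direction <- match.arg(direction)
  stopifnot(inherits(tmap, "petrad_tmap"))
  sel <- !is.na(tmap$p) & tmap$p < p_threshold
  if (direction == "hypo") sel <- sel & tmap$t < 0
  if (direction == "hyper") sel <- sel & tmap$t > 0
  labs <- cpp_label_components(sel, connectivity_offsets(connectivity))
  out <- tibble::tibble(cluster = integer(), n_voxels = integer(),
                        peak_t = numeric(), peak_x = integer(),
                        peak_y = integer(), peak_z = integer(),
                        centroid_x = numeric(), centroid_y = numeric(),
                        centroid_z = numeric())
  nlab <- max(labs)
  if (nlab > 0) {
    rows <- list()
    for (k in seq_len(nlab)) {
      idx <- which(labs == k)
      if (length(idx) <= min_extent) next
      coord <- arrayInd(idx, dim(labs))
      tv <- tmap$t[idx]
      pk <- which.max(abs(tv))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        cluster = k, n_voxels = length(idx), peak_t = tv[pk],
        peak_x = coord[pk, 1], peak_y = coord[pk, 2], peak_z = coord[pk, 3],
        centroid_x = mean(coord[, 1]), centroid_y = mean(coord[, 2]),
        centroid_z = mean(coord[, 3]))
    }
    if (length(rows))
      out <- dplyr::arrange(dplyr::bind_rows(rows), dplyr::desc(.data$n_voxels))
  }
  attr(out, "labels") <- labs
  attr(out, "p_threshold") <- p_threshold
  attr(out, "min_extent") <- min_extent
  attr(out, "direction") <- direction
  class(out) <- c("petrad_clusters", class(out))
  out
}
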