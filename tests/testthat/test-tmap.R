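make_null_inputs <- function(n_controls = 30, d = c(14, 14, 14), seed = 21) {
  set.seed(seed)
  mask <- ellipsoid <- array(FALSE, dim = d)
  mask[2:(d[1] - 1), 2:(d[2] - 1), 2:(d[3] - 1)] <- TRUE
  patient <- array(rnorm(prod(d)), dim = d)
  controls <- lapply(seq_len(n_controls), function(i)
    array(rnorm(prod(d)), dim = d))
  ages <- runif(n_controls + 1, 50, 85)
  list(patient = patient, controls = controls, ages = ages, mask = mask)
}

test_that("identical patient and controls give a flagged all-zero t-map", {
  d <- c(8, 8, 8)
  mask <- array(TRUE, dim = d)
  v <- bump_volume(d)
  tm <- voxelwise_glm_t(v, replicate(5, v, simplify = FALSE),
                        ages = c(70, 61, 62, 63, 64, 65), mask = mask)
  expect_true(all(tm$t[mask] == 0))
  expect_true(all(tm$degenerate[mask]))
  expect_true(all(tm$p[mask] == 1))
})

test_that("t is invariant to affine intensity rescaling", {
  x <- make_null_inputs(n_controls = 10)
  tm1 <- voxelwise_glm_t(x$patient, x$controls, x$ages, x$mask)
  tm2 <- voxelwise_glm_t(x$patient * 3 + 7,
                         lapply(x$controls, function(v) v * 3 + 7),
                         x$ages, x$mask)
  expect_equal(tm1$t, tm2$t, tolerance = 1e-8)
  expect_equal(tm1$df, 10 + 1 - 3)
})

test_that("type-I error under the null is calibrated at p < 0.01", {
  x <- make_null_inputs(n_controls = 40, d = c(16, 16, 16))
  tm <- voxelwise_glm_t(x$patient, x$controls, x$ages, x$mask)
  nvox <- sum(x$mask)
  rate <- mean(tm$p[x$mask] < 0.01)
  expect_gt(nvox, 500)
  expect_lt(abs(rate - 0.01), 2 * sqrt(0.01 * 0.99 / nvox) + 1e-9)
})

test_that("the planted lesion concentrates sub-threshold voxels in its region", {
  cfg <- tiny_gen_config(hypometabolism_factor = 0.7)
  co <- simulate_cohort(cfg)
  ctrl <- co$records[co$records$group == "control", ]
  pat <- co$records[co$records$subtype == "AD", ][1, ]
  tm <- voxelwise_glm_t(co$volumes[[pat$subject_id]],
                        co$volumes[ctrl$subject_id],
                        c(pat$age, ctrl$age), co$mask)
  pm <- make_pattern_mask("AD", cfg, co$mask)
  hit_in <- mean(tm$p[pm] < 0.01 & tm$t[pm] < 0)
  hit_out <- mean(tm$p[co$mask & !pm] < 0.01 & tm$t[co$mask & !pm] < 0)
  expect_gt(hit_in, 10 * max(hit_out, 1e-3))
})

test_that("cluster extraction agrees with the flood-fill oracle", {
  # build a synthetic t-map with known blobs
  d <- c(10, 10, 10)
  mask <- array(TRUE, dim = d)
  tv <- array(0, dim = d)
  tv[2:4, 2:4, 2:4] <- -6       # 27-voxel blob
  tv[8, 8, 8] <- -6             # singleton
  p <- array(1, dim = d); p[tv < 0] <- 1e-4
  tm <- structure(list(t = tv, p = p, df = 20, mask = mask,
                       degenerate = array(FALSE, dim = d)),
                  class = "petrad_tmap")
  cl <- extract_clusters(tm, min_extent = 5, direction = "hypo",
                         connectivity = 26)
  zo <- oracle_zones(array(as.integer(p < 0.01), dim = d))
  sizes <- sort(vapply(zo, function(z) length(z$voxels), numeric(1)),
                decreasing = TRUE)
  expect_equal(cl$n_voxels, as.integer(sizes[sizes > 5]))
  expect_equal(cl$peak_t[1], -6)
})

test_that("the extent rule is strict: a cluster of exactly min_extent is dropped", {
  d <- c(10, 10, 10)
  mask <- array(TRUE, dim = d)
  tv <- array(0, dim = d)
  tv[1:4, 1:5, 1:5] <- -5       # 100-voxel block
  p <- array(1, dim = d); p[tv < 0] <- 1e-4
  tm <- structure(list(t = tv, p = p, df = 20, mask = mask,
                       degenerate = array(FALSE, dim = d)),
                  class = "petrad_tmap")
  expect_equal(nrow(extract_clusters(tm, min_extent = 100)), 0)
  expect_equal(extract_clusters(tm, min_extent = 99)$n_voxels, 100L)
  # empty threshold set gives an empty report, not an error
  tm$p[] <- 1
  expect_equal(nrow(extract_clusters(tm)), 0)
})

test_that("direction filtering keeps only the requested sign", {
  d <- c(8, 8, 8)
  mask <- array(TRUE, dim = d)
  tv <- array(0, dim = d)
  tv[1:3, 1:3, 1:3] <- -5
  tv[6:8, 6:8, 6:8] <- 5
  p <- array(1, dim = d); p[abs(tv) > 0] <- 1e-4
  tm <- structure(list(t = tv, p = p, df = 20, mask = mask,
                       degenerate = array(FALSE, dim = d)),
                  class = "petrad_tmap")
  expect_equal(nrow(extract_clusters(tm, min_extent = 5, direction = "hypo")), 1)
  expect_equal(nrow(extract_clusters(tm, min_extent = 5, direction = "hyper")), 1)
  expect_equal(nrow(extract_clusters(tm, min_extent = 5, direction = "two_sided")), 2)
})
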