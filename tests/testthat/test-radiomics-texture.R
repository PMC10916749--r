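cfg_bins <- function(n) extraction_config(n_bins = n)

test_that("GLCM worked examples", {
  # 1x1x2 mask with levels (1,2): one pair, symmetric
  b <- array(c(1L, 2L), dim = c(1, 1, 2))
  m <- glcm(b, cfg_bins(2))
  expect_equal(m$counts, matrix(c(0, 1, 1, 0), 2, 2))
  expect_equal(m$total, 2)
  # uniform volume: single gray level, ASM 1, contrast 0
  u <- array(1L, dim = c(3, 3, 3))
  fu <- glcm_features(glcm(u, cfg_bins(2)))
  expect_equal(unname(fu["angular_second_moment"]), 1)
  expect_equal(unname(fu["contrast"]), 0)
  # single-voxel mask: no pairs, NaN-flagged features
  s <- array(0L, dim = c(3, 3, 3)); s[2, 2, 2] <- 1L
  expect_true(all(is.nan(glcm_features(glcm(s, cfg_bins(2))))))
})

test_that("GLRLM worked examples", {
  # 1x1x4 of a single level: one run of length 4 along the long axis
  b <- array(1L, dim = c(1, 1, 4))
  m <- glrlm(b, cfg_bins(2))
  expect_equal(m$per_direction[1, 4, 3], 1)   # direction (0,0,1)
  expect_equal(sum(m$per_direction[, , 3]), 1)
  # all-distinct levels: every run has length 1
  b2 <- array(1:8, dim = c(2, 2, 2)); storage.mode(b2) <- "integer"
  m2 <- glrlm(b2, cfg_bins(8))
  expect_true(all(m2$counts[, -1] == 0))
})

test_that("texture matrices match exhaustive brute-force oracles on random fixtures", {
  for (seed in 1:60) {
    fx <- random_fixture(seed)
    lev <- fx$levels; nb <- fx$n_bins
    cfg <- cfg_bins(nb)
    expect_equal(glcm(lev, cfg)$per_direction, oracle_glcm(lev, nb),
                 ignore_attr = TRUE, label = sprintf("glcm seed %d", seed))
    glr <- glrlm(lev, cfg)$per_direction
    orc <- oracle_glrlm(lev, nb)
    expect_equal(glr[, seq_len(dim(orc)[2]), ], orc, ignore_attr = TRUE,
                 label = sprintf("glrlm seed %d", seed))
    # zones: compare (level, size) and (level, distance) multisets
    zo <- oracle_zones(lev)
    dmo <- oracle_distance_map(lev)
    ztab <- data.frame(
      level = vapply(zo, `[[`, numeric(1), "level"),
      size = vapply(zo, function(z) length(z$voxels), numeric(1)),
      distance = vapply(zo, function(z) min(dmo[z$voxels]), numeric(1)))
    sz <- glszm(lev, cfg)$counts
    sz_o <- matrix(0, nb, max(ztab$size))
    for (r in seq_len(nrow(ztab)))
      sz_o[ztab$level[r], ztab$size[r]] <- sz_o[ztab$level[r], ztab$size[r]] + 1
    expect_equal(sz, sz_o, label = sprintf("glszm seed %d", seed))
    dz <- gldzm(lev, cfg)$counts
    dz_o <- matrix(0, nb, max(ztab$distance))
    for (r in seq_len(nrow(ztab)))
      dz_o[ztab$level[r], ztab$distance[r]] <-
        dz_o[ztab$level[r], ztab$distance[r]] + 1
    expect_equal(dz, dz_o, label = sprintf("gldzm seed %d", seed))
    expect_equal(ngldm(lev, cfg)$counts, oracle_ngldm(lev, nb, 0, 1),
                 label = sprintf("ngldm seed %d", seed))
    ng <- ngtdm(lev, cfg)
    oo <- oracle_ngtdm(lev, nb, 1)
    expect_equal(unname(ng$counts[, "s"]), oo$s, tolerance = 1e-12,
                 label = sprintf("ngtdm s seed %d", seed))
    expect_equal(unname(ng$counts[, "n"]), oo$n,
                 label = sprintf("ngtdm n seed %d", seed))
  }
})

test_that("GLSZM/GLDZM worked examples", {
  u <- array(1L, dim = c(3, 3, 3))
  m <- glszm(u, cfg_bins(2))
  expect_equal(sum(m$counts), 1)
  expect_equal(m$counts[1, 27], 1)    # single zone covering the cube
  # 5x5x5 cube, uniform level: one zone at border distance 1
  c5 <- array(1L, dim = c(5, 5, 5))
  md <- gldzm(c5, cfg_bins(2))
  expect_equal(md$counts[1, 1], 1)
  expect_equal(sum(md$counts), 1)
  # single-voxel mask: zone distance 1
  s <- array(0L, dim = c(3, 3, 3)); s[2, 2, 2] <- 1L
  ms <- gldzm(s, cfg_bins(2))
  expect_equal(ms$counts[1, 1], 1)
})

test_that("NGLDM worked example and closed forms", {
  b <- array(c(1L, 1L, 1L, 2L), dim = c(2, 2, 1))
  m <- ngldm(b, cfg_bins(2))
  expect_equal(m$counts[1, 3], 3)
  expect_equal(m$counts[2, 1], 1)
  expect_equal(sum(m$counts), 4)
  expect_equal(ngldm_dependence_count_nonuniformity(m), 2.5)
  expect_equal(ngldm_low_dependence_low_gray_level_emphasis(m),
               (3 / 9 + 1 / 4) / 4, tolerance = 1e-12)
  # uniform mask of n voxels: single column at the maximal dependence count
  u <- array(1L, dim = c(3, 3, 3))
  mu <- ngldm(u, cfg_bins(2))
  expect_equal(sum(mu$counts), 27)
  expect_equal(ngldm_dependence_count_nonuniformity(mu) > 0, TRUE)
  # all mass in one dependence column: DN = Nz
  m1 <- m; m1$counts[] <- 0; m1$counts[1, 3] <- 4
  expect_equal(ngldm_dependence_count_nonuniformity(m1), 4)
  # mass split evenly over 2 columns: DN = Nz / 2
  m2 <- m; m2$counts[] <- 0; m2$counts[1, 1] <- 2; m2$counts[1, 2] <- 2
  expect_equal(ngldm_dependence_count_nonuniformity(m2), 2)
  # alpha saturation: every neighbour dependent
  mixed <- array(c(1L, 2L, 1L, 2L, 2L, 1L, 2L, 1L), dim = c(2, 2, 2))
  msat <- ngldm(mixed, extraction_config(n_bins = 2, gldm_alpha = 1))
  expect_true(all(msat$counts[, 8] == c(4, 4)))
  # all mass at (1, 1): LDLGLE is maximal (1)
  m3 <- m; m3$counts[] <- 0; m3$counts[1, 1] <- 5
  expect_equal(ngldm_low_dependence_low_gray_level_emphasis(m3), 1)
})

test_that("NGTDM degenerate cases behave as documented", {
  u <- array(1L, dim = c(3, 3, 3))
  fu <- ngtdm_features(ngtdm(u, cfg_bins(2)))
  expect_equal(unname(fu["coarseness"]), 1e6)   # capped maximum
  expect_true(is.nan(fu["busyness"]))           # single level present
})

test_that("normalized matrices sum to one and features agree on both forms", {
  fx <- random_fixture(101)
  m <- ngldm(fx$levels, cfg_bins(fx$n_bins))
  P <- m$counts / sum(m$counts)
  expect_equal(sum(P), 1, tolerance = 1e-12)
  # DN computed from counts equals Nz * (DN-normalised from probabilities)
  dn <- ngldm_dependence_count_nonuniformity(m)
  expect_equal(dn / sum(m$counts), sum(colSums(P)^2), tolerance = 1e-12)
})

test_that("extract_all yields 215 manifest-ordered features, invariant to axis symmetry", {
  co <- tiny_cohort()
  cfg <- tiny_gen_config()
  f <- extract_all(co$volumes[[1]], co$mask, voxel_size_mm = cfg$voxel_size_mm)
  expect_length(f, 215)
  expect_identical(names(f), feature_manifest()$name)
  expect_false(any(is.nan(f)))
  # axis permutation with isotropic voxels: identical non-morphology features
  v <- co$volumes[[1]]
  # use a cubic sub-volume so permutation keeps the mask geometry
  n <- 16
  sub <- v[1:n, 1:n, 1:n]; smask <- co$mask[1:n, 1:n, 1:n]
  if (!any(smask)) smask[8, 8, 8] <- TRUE
  f1 <- extract_all(sub, smask, voxel_size_mm = c(4, 4, 4))
  f2 <- extract_all(aperm(sub, c(3, 1, 2)), aperm(smask, c(3, 1, 2)),
                    voxel_size_mm = c(4, 4, 4))
  tex <- feature_manifest()$name[feature_manifest()$category == "texture"]
  expect_equal(f1[tex], f2[tex], tolerance = 1e-9)
  # intensity features are also permutation-invariant
  stat <- grep("^stat\\.", names(f1), value = TRUE)
  expect_equal(f1[stat], f2[stat], tolerance = 1e-12)
})

test_that("full-resolution extraction stays within the time budget", {
  cfg <- generator_config(n_controls = 1, n_patients_by_subtype = c(AD = 0),
                          seed = 31)
  mask <- make_brain_mask(cfg)
  rec <- cohort_records(cfg)
  v <- simulate_subject(rec[1, ], mask, cfg)
  elapsed <- system.time(f <- extract_all(v, mask))[["elapsed"]]
  expect_length(f, 215)
  expect_lt(elapsed, 60)
})
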