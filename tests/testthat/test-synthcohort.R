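test_that("brain mask is a strict subset of the grid with the configured shape", {
  cfg <- generator_config(grid_shape = c(79, 95, 69))
  m <- make_brain_mask(cfg)
  expect_identical(dim(m), c(79L, 95L, 69L))
  expect_gt(sum(m), 0)
  expect_lt(sum(m), prod(dim(m)))
  expect_identical(m, make_brain_mask(cfg))
  expect_error(make_brain_mask(generator_config(grid_shape = c(4, 20, 20))),
               "degenerate")
})

test_that("pattern masks are non-empty and contained in the brain mask", {
  cfg <- tiny_gen_config()
  bm <- make_brain_mask(cfg)
  for (st in names(default_pattern_masks())) {
    pm <- make_pattern_mask(st, cfg, bm)
    expect_gt(sum(pm), 0)
    expect_true(all(bm[pm]))
  }
  expect_error(make_pattern_mask("nope", cfg, bm), "unknown subtype")
})

test_that("subject simulation is deterministic and respects the mask", {
  cfg <- tiny_gen_config()
  bm <- make_brain_mask(cfg)
  rec <- list(subject_id = "ad001", group = "dementia", subtype = "AD")
  v1 <- simulate_subject(rec, bm, cfg)
  v2 <- simulate_subject(rec, bm, cfg)
  expect_identical(v1, v2)
  expect_true(all(is.finite(v1)))
  expect_true(all(v1 >= 0))
  expect_equal(mean(v1[bm]), 1, tolerance = 1e-10)
})

test_that("hypometabolism lowers pattern-region intensity monotonically in the factor", {
  # Monte-Carlo: same subjects regenerated under decreasing factors
  region_mean <- function(factor, ids) {
    cfg <- tiny_gen_config(hypometabolism_factor = factor)
    bm <- make_brain_mask(cfg)
    pm <- make_pattern_mask("AD", cfg, bm)
    mean(vapply(ids, function(id) {
      v <- simulate_subject(list(subject_id = id, group = "dementia",
                                 subtype = "AD"), bm, cfg)
      mean(v[pm])
    }, numeric(1)))
  }
  ids <- sprintf("mc%03d", 1:50)
  m100 <- region_mean(1.0, ids)
  m85 <- region_mean(0.85, ids)
  m70 <- region_mean(0.70, ids)
  expect_gt(m100, m85)
  expect_gt(m85, m70)
})

test_that("factor 1 makes patients indistinguishable from controls in the region", {
  # two-sample t-test on pattern-region means should reject at ~alpha
  cfg <- tiny_gen_config(hypometabolism_factor = 1.0)
  bm <- make_brain_mask(cfg)
  pm <- make_pattern_mask("AD", cfg, bm)
  n_rep <- 60
  alpha <- 0.05
  rejections <- vapply(seq_len(n_rep), function(r) {
    cfg_r <- tiny_gen_config(hypometabolism_factor = 1.0, seed = 1000 + r)
    a <- vapply(sprintf("p%02d", 1:6), function(id)
      mean(simulate_subject(list(subject_id = id, group = "dementia",
                                 subtype = "AD"), bm, cfg_r)[pm]),
      numeric(1))
    b <- vapply(sprintf("c%02d", 1:6), function(id)
      mean(simulate_subject(list(subject_id = id, group = "control",
                                 subtype = "HC"), bm, cfg_r)[pm]),
      numeric(1))
    stats::t.test(a, b)$p.value < alpha
  }, logical(1))
  rate <- mean(rejections)
  # within ~3 binomial SD of alpha at 60 replicates
  expect_lt(abs(rate - alpha), 3 * sqrt(alpha * (1 - alpha) / n_rep) + 1e-9)
})

test_that("cohort has the configured composition and reproduces exactly", {
  cfg <- generator_config(grid_shape = c(16, 16, 16), voxel_size_mm = c(4, 4, 4),
                          n_controls = 5,
                          n_patients_by_subtype = c(AD = 3, DLB = 2), seed = 3)
  co <- simulate_cohort(cfg)
  expect_equal(nrow(co$records), 10)
  expect_equal(sum(co$records$group == "control"), 5)
  expect_equal(sum(co$records$subtype == "DLB"), 2)
  expect_true(all(co$records$age >= 20 & co$records$age <= 95))
  expect_true(all((co$records$group == "control") ==
                    (co$records$subtype == "HC")))
  co2 <- simulate_cohort(cfg)
  expect_identical(co$records, co2$records)
  expect_identical(co$volumes, co2$volumes)
})

test_that("an empty cohort is allowed", {
  cfg <- generator_config(grid_shape = c(16, 16, 16),
                          n_controls = 0,
                          n_patients_by_subtype = c(AD = 0))
  co <- simulate_cohort(cfg)
  expect_equal(nrow(co$records), 0)
  expect_length(co$volumes, 0)
})

test_that("cohorts round-trip through NIfTI files and a participants table", {
  cfg <- generator_config(grid_shape = c(12, 12, 12), voxel_size_mm = c(4, 4, 4),
                          n_controls = 2, n_patients_by_subtype = c(FTD = 1),
                          seed = 8)
  co <- simulate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(co, dir, cfg$voxel_size_mm)
  tab <- read.csv(file.path(dir, "participants.csv"))
  expect_equal(tab$subject_id, co$records$subject_id)
  v <- read_volume(file.path(dir, paste0(co$records$subject_id[1], ".nii.gz")))
  expect_equal(array(v, dim = dim(v)),
               co$volumes[[1]], tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(attr(v, "voxel_size_mm"), c(4, 4, 4), ignore_attr = TRUE)
})
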