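toy_feature_cohort <- function(n = 60, sep = 10, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    subject_id = sprintf("s%03d", seq_len(n)),
    group = rep(c("control", "dementia"), each = n / 2),
    f1 = rnorm(n) + ifelse(rep(c(TRUE, FALSE), each = n / 2), 0, sep),
    f2 = rnorm(n))
}

test_that("z-score normalization fits on training only and applies elsewhere", {
  tr <- matrix(c(1, 2, 3, 4, 5, 6), 3, 2,
               dimnames = list(NULL, c("a", "b")))
  z <- zscore_fit_apply(tr, tr)
  expect_equal(z$train[, "a"], c(-1, 0, 1), ignore_attr = TRUE)  # sample SD
  expect_equal(z$train, z$other)
  # far-out test values stay finite and unclipped
  far <- matrix(c(1000, -1000), 1, 2, dimnames = list(NULL, c("a", "b")))
  zf <- zscore_fit_apply(tr, far)
  expect_true(all(is.finite(zf$other)))
  expect_gt(abs(zf$other[1, 1]), 100)
  # zero-SD feature errors with its name
  bad <- cbind(a = c(1, 1, 1), b = c(1, 2, 3))
  expect_error(zscore_fit_apply(bad), "a")
})

test_that("split carves a balanced shared test set and stratified validation", {
  rec <- toy_feature_cohort(n = 100)[c("subject_id", "group")]
  sp <- make_split(rec, test_per_class = 10, val_fraction = 0.10, seed = 3)
  expect_equal(sum(sp$role == "test"), 20)
  expect_equal(as.integer(table(sp$group[sp$role == "test"])), c(10L, 10L))
  expect_equal(sum(sp$role == "validation"), 10)
  expect_identical(sp, make_split(rec, 10, 0.10, seed = 3))
})

test_that("the feature network separates an easy two-blob problem", {
  tbl <- toy_feature_cohort()
  sp <- make_split(tbl, test_per_class = 5, val_fraction = 0.1, seed = 2)
  fit <- train_feature_nn(tbl, c("f1", "f2"), sp, nn_config(epochs = 150))
  expect_equal(fit$val_accuracy, 1)
  expect_equal(fit$test_accuracy, 1)
  # score table invariants
  sc <- fit$scores
  expect_true(all(sc$score >= 50 & sc$score <= 100))
  expect_equal(sc$prob_control + sc$prob_dementia, rep(100, nrow(sc)),
               tolerance = 1e-9)
  expect_true(all((sc$score >= 50) == (sc$predicted ==
    ifelse(sc$prob_control >= 50, "control", "dementia"))))
})

test_that("training is deterministic given the seed", {
  tbl <- toy_feature_cohort(seed = 4)
  sp <- make_split(tbl, 5, 0.1, seed = 5)
  f1 <- train_feature_nn(tbl, c("f1", "f2"), sp, nn_config(epochs = 60, seed = 9))
  f2 <- train_feature_nn(tbl, c("f1", "f2"), sp, nn_config(epochs = 60, seed = 9))
  expect_identical(f1$scores, f2$scores)
})

test_that("label-shuffled features score near chance", {
  accs <- vapply(1:5, function(r) {
    tbl <- toy_feature_cohort(n = 80, sep = 10, seed = 20 + r)
    set.seed(30 + r)
    tbl$group <- sample(tbl$group)       # break the association
    sp <- make_split(tbl, 10, 0.1, seed = 40 + r)
    fit <- train_feature_nn(tbl, c("f1", "f2"), sp, nn_config(epochs = 100))
    fit$test_accuracy
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 0.2)
})

test_that("re-prediction is idempotent and matches training-time scores", {
  tbl <- toy_feature_cohort(seed = 6)
  sp <- make_split(tbl, 5, 0.1, seed = 7)
  fit <- train_feature_nn(tbl, c("f1", "f2"), sp, nn_config(epochs = 80))
  te <- tbl[tbl$subject_id %in% sp$subject_id[sp$role == "test"], ]
  p1 <- predict_scores(fit, te)
  p2 <- predict_scores(fit, te)
  expect_identical(p1, p2)
  expect_equal(p1$score, fit$scores$score, tolerance = 1e-9)
})

test_that("degenerate splits are rejected", {
  tbl <- toy_feature_cohort(n = 30)
  sp <- make_split(tbl, 3, 0.1, seed = 8)
  sp$role[sp$group == "dementia" & sp$role == "test"] <- "train"
  expect_error(train_feature_nn(tbl, c("f1", "f2"), sp, nn_config()),
               "degenerate")
})

test_that("the 3D CNN separates offset toy volumes and behaves at chance on identical ones", {
  set.seed(11)
  n <- 24
  mk <- function(mu) array(rnorm(16^3, mean = mu), dim = c(16, 16, 16))
  vols <- c(lapply(1:(n / 2), function(i) mk(0)),
            lapply(1:(n / 2), function(i) mk(1.5)))
  names(vols) <- sprintf("s%02d", 1:n)
  rec <- tibble::tibble(subject_id = names(vols),
                        group = rep(c("control", "dementia"), each = n / 2))
  sp <- make_split(rec, 3, 0.15, seed = 12)
  fit <- train_cnn_3d(vols, rec, sp,
                      cnn_config(input_shape = c(16, 16, 16), epochs = 6,
                                 batch_size = 6, seed = 13))
  expect_equal(fit$test_accuracy, 1)
  sc <- fit$scores
  expect_equal(sc$prob_control + sc$prob_dementia, rep(100, nrow(sc)),
               tolerance = 1e-9)
  # identical volumes for both classes: accuracy near chance
  vols2 <- lapply(seq_len(n), function(i) vols[[1]])
  names(vols2) <- names(vols)
  fit2 <- train_cnn_3d(vols2, rec, sp,
                       cnn_config(input_shape = c(16, 16, 16), epochs = 3,
                                  batch_size = 6, seed = 14))
  expect_lt(fit2$val_accuracy, 0.99)
  # determinism
  fit3 <- train_cnn_3d(vols, rec, sp,
                       cnn_config(input_shape = c(16, 16, 16), epochs = 6,
                                  batch_size = 6, seed = 13))
  expect_identical(fit$scores, fit3$scores)
})

test_that("volume shape mismatches error", {
  vols <- list(a = array(0, dim = c(8, 8, 8)), b = array(0, dim = c(8, 8, 9)))
  rec <- tibble::tibble(subject_id = c("a", "b"),
                        group = c("control", "dementia"))
  sp <- tibble::tibble(subject_id = c("a", "b"), group = rec$group,
                       role = c("train", "train"))
  expect_error(train_cnn_3d(vols, rec, sp), "shape")
})

test_that("crop_pad centres content and is shape-exact", {
  v <- array(1:27, dim = c(3, 3, 3))
  big <- crop_pad(v, c(5, 5, 5))
  expect_equal(dim(big), c(5, 5, 5))
  expect_equal(big[2:4, 2:4, 2:4], v)
  expect_equal(sum(big), sum(v))
  back <- crop_pad(big, c(3, 3, 3))
  expect_equal(back, v)
})
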