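# End-to-end orchestration of the two study arms: simulate -> preprocess ->
# extract -> select -> train (radiomics NN and, optionally, 3D CNN) ->
# compare, with one global seed deriving every stage seed and a manifest of
# content hashes for reproducibility checks.

#' Configuration of a full pipeline run
#'
#' @param generator a [generator_config()]; its `seed` is overridden by
#'   `seed`.
#' @param extraction an [extraction_config()].
#' @param selection list with `fraction` (top MRMR fraction, default 0.10)
#'   and `r_threshold` (Pearson pruning bound, default 0.30).
#' @param split list with `test_per_class` (default 10) and `val_fraction`
#'   (default 0.10).
#' @param nn an [nn_config()].
#' @param cnn a [cnn_config()].
#' @param run_cnn train the CNN arm too (default TRUE).
#' @param scale_target in-mask mean after global-mean scaling.
#' @param seed global seed; stage seeds are derived from it.
#' @return a `petrad_run_config` list.
#' @export
run_config <- function(generator = generator_config(),
                       extraction = extraction_config(),
                       selection = list(fraction = 0.10, r_threshold = 0.30),
                       split = list(test_per_class = 10, val_fraction = 0.10),
                       nn = nn_config(),
                       cnn = cnn_config(),
                       run_cnn = TRUE,
                       scale_target = 1,
                       seed = 42L) {
  seed <- as.integer(seed)
  generator$seed <- seed
  nn$seed <- (seed + 2L) %% .Machine$integer.max
  cnn$seed <- (seed + 3L) %% .Machine$integer.max
  structure(list(generator = generator, extraction = extraction,
                 selection = selection, split = split, nn = nn, cnn = cnn,
                 run_cnn = isTRUE(run_cnn), scale_target = scale_target,
                 seed = seed),
            class = "petrad_run_config")
}

#' Run the whole pipeline
#'
#' Simulates the cohort, rescales every volume to the common global mean
#' (generation already applies the 8 mm smoothing), extracts the 215-entry
#' feature vectors, runs MRMR + correlation pruning on the non-test
#' subjects, trains the radiomics network (and optionally the CNN) on the
#' shared split, and compares the two arms' test scores.
#'
#' @param config a [run_config()].
#' @param outdir optional directory; when given, volumes, tables and the
#'   manifest are written there.
#' @return list with `records`, `mask`, `features`, `split`, `selection`,
#'   `nn`, `cnn` (or NULL), `comparison` (or NULL), `manifest`.
#' @export
run_all <- function(config = run_config(), outdir = NULL) {
  stopifnot(inherits(config, "petrad_run_config"))
  if (config$generator$n_controls == 0 ||
      sum(config$generator$n_patients_by_subtype) == 0)
    stop("cohort needs both controls and patients before training",
         call. = FALSE)
  cohort <- simulate_cohort(config$generator)
  vs <- config$generator$voxel_size_mm
  cohort$volumes <- lapply(cohort$volumes, global_mean_scale,
                           mask = cohort$mask, target = config$scale_target)
  features <- extract_cohort(cohort, config$extraction, vs)
  split <- make_split(cohort$records,
                      test_per_class = config$split$test_per_class,
                      val_fraction = config$split$val_fraction,
                      seed = (config$seed + 1L) %% .Machine$integer.max)
  fit_rows <- split$subject_id[split$role != "test"]
  fcols <- feature_manifest()$name
  train_tbl <- features[features$subject_id %in% fit_rows, ]
  sel <- mrmr_rank(train_tbl[fcols], train_tbl$group) |>
    select_top_fraction(config$selection$fraction) |>
    pearson_prune(train_tbl[fcols], config$selection$r_threshold)
  nn_fit <- train_feature_nn(features[c("subject_id", "group", sel$kept)],
                             sel$kept, split, config$nn)
  cnn_fit <- NULL; comparison <- NULL
  if (config$run_cnn) {
    cnn_fit <- train_cnn_3d(cohort$volumes, cohort$records, split, config$cnn)
    comparison <- compare_models(nn_fit$scores, cnn_fit$scores)
  }
  manifest <- list(
    seed = config$seed,
    n_subjects = nrow(cohort$records),
    n_features = length(fcols),
    n_kept = length(sel$kept),
    kept = sel$kept,
    test_subjects = sort(split$subject_id[split$role == "test"]),
    hash_records = rlang::hash(cohort$records),
    hash_features = rlang::hash(features),
    hash_scores_nn = rlang::hash(nn_fit$scores),
    hash_scores_cnn = if (!is.null(cnn_fit)) rlang::hash(cnn_fit$scores))
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_cohort(cohort, file.path(outdir, "cohort"), vs)
    write.csv(features, file.path(outdir, "features.csv"), row.names = FALSE)
    write.csv(split, file.path(outdir, "split.csv"), row.names = FALSE)
    write.csv(nn_fit$scores, file.path(outdir, "scores_radiomics.csv"),
              row.names = FALSE)
    if (!is.null(cnn_fit))
      write.csv(cnn_fit$scores, file.path(outdir, "scores_cnn.csv"),
                row.names = FALSE)
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  list(records = cohort$records, mask = cohort$mask, features = features,
       split = split, selection = sel, nn = nn_fit, cnn = cnn_fit,
       comparison = comparison, manifest = manifest)
}

#' Automated t-map quality check of a synthetic cohort
#'
#' For every patient, computes the voxel-wise GLM t-map against the cohort's
#' controls (age-adjusted) and extracts hypometabolic clusters; a patient
#' counts as detected when at least one retained cluster has its peak inside
#' the patient's own subtype pattern mask.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param config the [generator_config()] the cohort was built with.
#' @param p_threshold,min_extent,connectivity forwarded to
#'   [extract_clusters()].
#' @param max_controls cap on the number of controls entering each model
#'   (for speed; default all).
#' @return tibble per patient: `subject_id`, `subtype`, `n_clusters`,
#'   `detected`; the detection fraction is in attribute
#'   `"detection_fraction"`.
#' @export
tmap_qc <- function(cohort, config, p_threshold = 0.01, min_extent = 100,
                    connectivity = 18, max_controls = Inf) {
  rec <- cohort$records
  ctrl <- rec[rec$group == "control", ]
  pats <- rec[rec$group == "dementia", ]
  if (nrow(pats) == 0) {
    out <- tibble::tibble(subject_id = character(), subtype = character(),
                          n_clusters = integer(), detected = logical())
    attr(out, "detection_fraction") <- NA_real_
    return(out)
  }
  if (nrow(ctrl) > max_controls) ctrl <- ctrl[seq_len(max_controls), ]
  cvols <- cohort$volumes[ctrl$subject_id]
  rows <- lapply(seq_len(nrow(pats)), function(i) {
    p <- pats[i, ]
    tm <- voxelwise_glm_t(cohort$volumes[[p$subject_id]], cvols,
                          c(p$age, ctrl$age), cohort$mask)
    cl <- extract_clusters(tm, p_threshold = p_threshold,
                           min_extent = min_extent, direction = "hypo",
                           connectivity = connectivity)
    pm <- make_pattern_mask(p$subtype, config, cohort$mask)
    det <- nrow(cl) > 0 &&
      any(pm[cbind(cl$peak_x, cl$peak_y, cl$peak_z)])
    tibble::tibble(subject_id = p$subject_id, subtype = p$subtype,
                   n_clusters = nrow(cl), detected = det)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "detection_fraction") <- mean(out$detected)
  out
}

#' Write / read a run configuration as YAML
#'
#' @param config a [run_config()].
#' @param path YAML file path.
#' @return `path` invisibly / the restored `petrad_run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "petrad_run_config"))
  plain <- rapply(unclass(config), identity, how = "replace")
  # yaml drops names on named atomic vectors; keep the subtype map as a list
  plain$generator$n_patients_by_subtype <-
    as.list(config$generator$n_patients_by_subtype)
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  gen <- y$generator
  gen$n_patients_by_subtype <- unlist(gen$n_patients_by_subtype)
  gen$pattern_masks <- lapply(gen$pattern_masks, function(m)
    list(centre = unlist(m$centre), semi_axes = unlist(m$semi_axes)))
  run_config(
    generator = do.call(generator_config, gen),
    extraction = do.call(extraction_config, y$extraction),
    selection = y$selection,
    split = y$split,
    nn = do.call(nn_config, y$nn[c("hidden", "epochs", "lr", "seed")]),
    cnn = do.call(cnn_config, y$cnn[c("input_shape", "channels", "fc",
                                      "epochs", "lr", "batch_size", "seed")]),
    run_cnn = y$run_cnn, scale_target = y$scale_target, seed = y$seed)
}

#' Desk-scale configuration of the full study design
#'
#' The complete cohort design (125 controls, 85 patients as 38 AD + 2 MCI +
#' 25 DLB + 20 FTD, hypometabolism factor 0.75, default noise, 8 mm
#' smoothing) on a half-resolution template grid of 40 x 48 x 35 voxels of
#' 4 mm, with the CNN reading 32-cubed crops. This keeps a full two-arm run
#' within minutes on one CPU while preserving the cohort's statistical
#' structure; see the methods vignette for the choice of problem sizes.
#'
#' @param seed global seed.
#' @param run_cnn train the CNN arm too (default TRUE).
#' @return a `petrad_run_config`.
#' @export
desk_study_config <- function(seed = 42L, run_cnn = TRUE) {
  run_config(
    generator = generator_config(grid_shape = c(40, 48, 35),
                                 voxel_size_mm = c(4, 4, 4)),
    cnn = cnn_config(input_shape = c(32, 32, 32), epochs = 12),
    run_cnn = run_cnn,
    seed = seed)
}
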