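# The two classification arms. Both consume the same stratified split (a
# fixed balanced held-out test set shared between arms) and emit per-subject
# probability score tables on a 0-100 scale.

#' Stratified train/validation/test split with a shared balanced test set
#'
#' The test set is drawn first: `test_per_class` subjects per group (the
#' design uses 10 healthy controls and 10 patients). A validation set of
#' about `val_fraction` of the whole cohort is then drawn, stratified by
#' group, from the remainder; everything else trains. The same split object
#' is passed to both classification arms so their test subjects coincide.
#'
#' @param records tibble with `subject_id` and `group`.
#' @param test_per_class held-out test subjects per group (default 10).
#' @param val_fraction fraction of the cohort used for validation
#'   (default 0.10).
#' @param seed RNG seed.
#' @return tibble `subject_id`, `group`, `role` (`train`/`validation`/`test`).
#' @export
make_split <- function(records, test_per_class = 10, val_fraction = 0.10,
                       seed = 1L) {
  stopifnot(all(c("subject_id", "group") %in% names(records)))
  groups <- unique(records$group)
  if (length(groups) != 2) stop("need exactly two groups", call. = FALSE)
  set.seed(seed)
  role <- setNames(rep("train", nrow(records)), records$subject_id)
  for (g in groups) {
    ids <- records$subject_id[records$group == g]
    if (length(ids) < test_per_class + 2)
      stop("group ", g, " too small for the requested test set", call. = FALSE)
    role[sample(ids, test_per_class)] <- "test"
  }
  for (g in groups) {
    ids <- records$subject_id[records$group == g]
    pool <- ids[role[ids] == "train"]
    nval <- round(val_fraction * length(ids))
    nval <- min(nval, length(pool) - 1)
    if (nval > 0) role[sample(pool, nval)] <- "validation"
  }
  tibble::tibble(subject_id = records$subject_id, group = records$group,
                 role = unname(role[records$subject_id]))
}

#' Fit z-score normalization on training data and apply it elsewhere
#'
#' Per-feature mean 0 / SD 1 (sample SD, `n - 1`) on the training table; the
#' same parameters are applied to the other table, so no statistic leaks from
#' validation or test subjects.
#'
#' @param train numeric matrix/tibble of training features.
#' @param other matrix/tibble with the same columns (validation/test), or
#'   `NULL`.
#' @return list with `train`, `other` (normalized matrices), `center`, `scale`.
#' @export
zscore_fit_apply <- function(train, other = NULL) {
  Xt <- as.matrix(train)
  if (nrow(Xt) < 2) stop("need more than one training subject", call. = FALSE)
  ctr <- colMeans(Xt)
  scl <- apply(Xt, 2, sd)
  if (any(scl == 0))
    stop("zero-variance feature(s) in training data: ",
         paste(colnames(Xt)[scl == 0], collapse = ", "), call. = FALSE)
  app <- function(X) sweep(sweep(as.matrix(X), 2, ctr), 2, scl, `/`)
  list(train = app(Xt), other = if (!is.null(other)) app(other),
       center = ctr, scale = scl)
}

#' Configuration of the feature-input neural network
#'
#' A small feed-forward net (hidden layers 16 and 8, ReLU, softmax output)
#' on the selected radiomic features, trained full-batch with Adam.
#'
#' @param hidden hidden layer sizes.
#' @param epochs training epochs.
#' @param lr Adam learning rate.
#' @param seed RNG seed.
#' @return a `petrad_nn_config` list.
#' @export
nn_config <- function(hidden = c(16, 8), epochs = 300, lr = 0.01, seed = 7L) {
  stopifnot(length(hidden) >= 1)
  structure(list(hidden = as.integer(hidden), epochs = as.integer(epochs),
                 lr = lr, seed = as.integer(seed)),
            class = "petrad_nn_config")
}

# internal: order class levels so "dementia"/patient-like labels come second
class_levels <- function(groups) sort(unique(groups))

score_table <- function(ids, groups, probs, levels, model) {
  pred <- levels[max.col(probs, ties.method = "first")]
  tb <- tibble::tibble(subject_id = ids, group = groups,
                       predicted = pred,
                       score = apply(probs, 1, max) * 100)
  tb[[paste0("prob_", levels[1])]] <- probs[, 1] * 100
  tb[[paste0("prob_", levels[2])]] <- probs[, 2] * 100
  tb$model <- model
  dplyr::arrange(tb, .data$subject_id)
}

#' Train the radiomics-arm neural network
#'
#' Selects the training rows of `split`, z-scores the chosen feature columns
#' on training data only, trains the feed-forward network and scores the
#' held-out test subjects (and validation subjects for accuracy reporting).
#'
#' @param feature_tbl tibble with `subject_id`, `group` and feature columns
#'   (from [extract_cohort()]).
#' @param features character vector of feature columns to use (e.g. the kept
#'   set of [pearson_prune()]).
#' @param split a [make_split()] tibble.
#' @param config an [nn_config()].
#' @return a `petrad_nn` model: list with `layers`, `norm`, `features`,
#'   `levels`, `scores` (test [score table][predict_scores()]),
#'   `val_accuracy`, `test_accuracy`.
#' @export
train_feature_nn <- function(feature_tbl, features, split,
                             config = nn_config()) {
  stopifnot(all(features %in% names(feature_tbl)))
  d <- dplyr::inner_join(feature_tbl, split[c("subject_id", "role")],
                         by = "subject_id")
  lev <- class_levels(d$group)
  for (r in c("train", "test")) {
    gg <- d$group[d$role == r]
    if (length(unique(gg)) != 2)
      stop("degenerate split: ", r, " set lacks a class", call. = FALSE)
  }
  y <- match(d$group, lev)
  Xall <- as.matrix(d[features])
  tr <- d$role == "train"; va <- d$role == "validation"; te <- d$role == "test"
  nrm <- zscore_fit_apply(Xall[tr, , drop = FALSE], Xall)
  X <- nrm$other     # all rows, train-fitted normalization
  layers <- mlp_init(length(features), config$hidden, 2, config$seed)
  fit <- mlp_train(layers, X[tr, , drop = FALSE], y[tr],
                   if (any(va)) X[va, , drop = FALSE], if (any(va)) y[va],
                   epochs = config$epochs, lr = config$lr, seed = config$seed)
  model <- structure(list(layers = fit$layers,
                          center = nrm$center, scale = nrm$scale,
                          features = features, levels = lev,
                          config = config),
                     class = "petrad_nn")
  acc <- function(sel) {
    if (!any(sel)) return(NA_real_)
    P <- mlp_forward(fit$layers, X[sel, , drop = FALSE])
    mean(lev[max.col(P, ties.method = "first")] == d$group[sel])
  }
  model$val_accuracy <- acc(va)
  model$test_accuracy <- acc(te)
  model$scores <- score_table(d$subject_id[te], d$group[te],
                              mlp_forward(fit$layers, X[te, , drop = FALSE]),
                              lev, "radiomics_nn")
  model
}

#' Train the 3D-CNN arm
#'
#' Volumes are centre crop/padded to the configured input shape; training,
#' validation and test roles come from the same split object as the
#' radiomics arm.
#'
#' @param volumes named list of 3D arrays (names = subject ids).
#' @param records tibble with `subject_id`, `group`.
#' @param split a [make_split()] tibble.
#' @param config a [cnn_config()].
#' @return a `petrad_cnn` model with `scores`, `val_accuracy`,
#'   `test_accuracy`.
#' @export
train_cnn_3d <- function(volumes, records, split, config = cnn_config()) {
  d <- dplyr::inner_join(records, split[c("subject_id", "role")],
                         by = "subject_id")
  shp <- dim(volumes[[1]])
  if (!all(vapply(volumes, function(v) identical(dim(v), shp), logical(1))))
    stop("all volumes must share one shape", call. = FALSE)
  lev <- class_levels(d$group)
  y <- match(d$group, lev)
  vols <- volumes[d$subject_id]
  tr <- which(d$role == "train"); va <- which(d$role == "validation")
  te <- which(d$role == "test")
  fit <- cnn_train(vols, y, tr, va, config)
  model <- structure(list(params = fit$params, config = config,
                          levels = lev, val_loss = fit$val_loss),
                     class = "petrad_cnn")
  acc <- function(idx) {
    if (!length(idx)) return(NA_real_)
    P <- cnn_predict_probs(model, vols[idx])
    mean(lev[max.col(P, ties.method = "first")] == d$group[idx])
  }
  model$val_accuracy <- acc(va)
  model$test_accuracy <- acc(te)
  model$scores <- score_table(d$subject_id[te], d$group[te],
                              cnn_predict_probs(model, vols[te]),
                              lev, "cnn_3d")
  model
}

#' Score subjects with a trained model
#'
#' Returns the per-subject probability score table: the winning class's
#' posterior on a 0-100 scale (the two class scores always sum to 100), with
#' rows ordered by subject id.
#'
#' @param model a `petrad_nn` or `petrad_cnn`.
#' @param ... model-specific inputs, see methods.
#' @return a score tibble: `subject_id`, `group`, `predicted`, `score`,
#'   `prob_control`, `prob_dementia`, `model`.
#' @export
predict_scores <- function(model, ...) UseMethod("predict_scores")

#' @rdname predict_scores
#' @param feature_tbl tibble with `subject_id`, `group` and the model's
#'   feature columns.
#' @export
predict_scores.petrad_nn <- function(model, feature_tbl, ...) {
  X <- sweep(sweep(as.matrix(feature_tbl[model$features]), 2, model$center),
             2, model$scale, `/`)
  score_table(feature_tbl$subject_id, feature_tbl$group,
              mlp_forward(model$layers, X), model$levels, "radiomics_nn")
}

#' @rdname predict_scores
#' @param volumes named list of 3D arrays.
#' @param records tibble with `subject_id`, `group` matching `volumes`.
#' @export
predict_scores.petrad_cnn <- function(model, volumes, records, ...) {
  score_table(records$subject_id, records$group,
              cnn_predict_probs(model, volumes[records$subject_id]),
              model$levels, "cnn_3d")
}
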