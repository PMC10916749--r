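# broom-style tidiers and ggplot2 autoplot methods for the result objects.

#' Tidy an MRMR selection
#'
#' @param x a `petrad_selection`.
#' @param ... unused.
#' @return the ranking tibble with a `kept` flag.
#' @exportS3Method generics::tidy
tidy.petrad_selection <- function(x, ...) {
  out <- x$ranked
  out$selected <- out$rank <= (x$k_selected %||% nrow(out))
  out$kept <- out$feature %in% (x$kept %||% character(0))
  out
}

#' @rdname tidy.petrad_selection
#' @exportS3Method generics::glance
glance.petrad_selection <- function(x, ...) {
  cert <- if (!is.null(x$correlation_matrix))
    check_correlation_certificate(x$correlation_matrix,
                                  x$r_threshold %||% 0.30)
  tibble::tibble(
    n_features = x$n_features,
    n_dropped = length(x$dropped),
    k_selected = x$k_selected %||% NA_integer_,
    n_kept = length(x$kept %||% character(0)),
    max_abs_r = if (is.null(cert)) NA_real_ else cert$max_abs_r,
    certificate_pass = if (is.null(cert)) NA else cert$pass)
}

#' Tidy a model comparison
#'
#' @param x a `petrad_comparison`.
#' @param ... unused.
#' @return the per-group comparison tibble (already tidy).
#' @exportS3Method generics::tidy
tidy.petrad_comparison <- function(x, ...) tibble::as_tibble(x)

#' @rdname tidy.petrad_comparison
#' @exportS3Method generics::glance
glance.petrad_comparison <- function(x, ...) {
  tibble::tibble(n_groups = nrow(x),
                 n_subjects = sum(x$n),
                 min_p = suppressWarnings(min(x$p, na.rm = TRUE)),
                 any_significant = any(x$verdict == "significant"))
}

#' Tidy a t-map into a voxel table
#'
#' @param x a `petrad_tmap`.
#' @param ... unused.
#' @return tibble `x`, `y`, `z`, `t`, `p` for in-mask voxels.
#' @exportS3Method generics::tidy
tidy.petrad_tmap <- function(x, ...) {
  idx <- which(x$mask)
  co <- arrayInd(idx, dim(x$mask))
  tv <- x$t[idx]   # grab before the tibble columns shadow `x`
  pv <- x$p[idx]
  tibble::tibble(x = co[, 1], y = co[, 2], z = co[, 3], t = tv, p = pv)
}

#' Plot an axial slice of a t-map
#'
#' @param object a `petrad_tmap`.
#' @param slice axial (third-axis) slice index; default the middle slice.
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.petrad_tmap <- function(object, slice = NULL, ...) {
  d <- dim(object$t)
  slice <- slice %||% ceiling(d[3] / 2)
  df <- tidy.petrad_tmap(object)
  df <- df[df$z == slice, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$t)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("t-map, axial slice %d (df = %d)",
                                  slice, object$df),
                  x = NULL, y = NULL, fill = "t")
}

#' Plot an MRMR selection
#'
#' Bar chart of the MRMR scores of the selected features, kept features
#' highlighted.
#'
#' @param object a `petrad_selection`.
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.petrad_selection <- function(object, ...) {
  df <- tidy.petrad_selection(object)
  df <- df[df$selected, ]
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$feature, -.data$rank),
                                   y = .data$score, fill = .data$kept)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "MRMR score (relevance / redundancy)",
                  fill = "kept after pruning")
}

#' Plot a paired score comparison
#'
#' Per-subject probability scores of the two models, connected pairwise and
#' faceted by true group.
#'
#' @param object a `petrad_comparison`.
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.petrad_comparison <- function(object, ...) {
  sc <- attr(object, "scores")
  models <- attr(object, "models")
  long <- tidyr::pivot_longer(sc, c("score_a", "score_b"),
                              names_to = "model", values_to = "score")
  long$model <- ifelse(long$model == "score_a", models[["a"]], models[["b"]])
  ggplot2::ggplot(long, ggplot2::aes(x = .data$model, y = .data$score)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$subject_id), alpha = 0.4) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~group) +
    ggplot2::labs(x = NULL, y = "winning-class probability score (0-100)")
}
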