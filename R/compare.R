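# The headline statistical comparison: per-group means and SDs of the two
# models' probability scores, and a paired two-tailed Student's t-test on
# the per-subject score differences. The paired form is used because the
# same held-out subjects are scored by both models.

#' Mean and sample SD of a score column
#'
#' @param scores numeric vector, `n >= 2`.
#' @return named vector `c(mean, sd)` (SD uses the `n - 1` denominator).
#' @export
column_summary <- function(scores) {
  if (length(scores) < 2) stop("need at least 2 values", call. = FALSE)
  c(mean = mean(scores), sd = sd(scores))
}

#' Paired two-tailed Student's t-test
#'
#' `d_i = a_i - b_i`; `t = mean(d) / (sd(d) / sqrt(n))`, `df = n - 1`,
#' two-tailed p from the t distribution.
#'
#' @param a,b paired numeric vectors of equal length (`n >= 2`).
#' @return list with `t`, `df`, `p`, `mean_diff`, `sd_diff`.
#' @export
paired_ttest <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  if (n < 2) stop("need at least 2 pairs", call. = FALSE)
  d <- a - b
  s <- sd(d)
  if (s == 0) stop("zero variance of paired differences", call. = FALSE)
  t <- mean(d) / (s / sqrt(n))
  list(t = t, df = n - 1L, p = 2 * pt(-abs(t), n - 1),
       mean_diff = mean(d), sd_diff = s)
}

#' Compare two models' probability scores group by group
#'
#' Joins the two score tables by subject, splits by the true group, and for
#' each group reports each model's score mean and SD plus the paired t-test
#' on the per-subject differences. When the two models score every subject
#' identically within a group, the test is degenerate and the verdict is
#' reported as `"no difference"`.
#'
#' @param scores_a,scores_b score tibbles (see [predict_scores()]) covering
#'   the same subjects.
#' @param alpha significance level for the verdict (default 0.05).
#' @return a `petrad_comparison`: tibble with one row per group (`group`,
#'   `n`, `mean_a`, `sd_a`, `mean_b`, `sd_b`, `mean_diff`, `t`, `df`, `p`,
#'   `verdict`), with the joined per-subject scores in the
#'   `"scores"` attribute.
#' @export
compare_models <- function(scores_a, scores_b, alpha = 0.05) {
  j <- dplyr::inner_join(
    dplyr::select(scores_a, "subject_id", "group", score_a = "score"),
    dplyr::select(scores_b, "subject_id", score_b = "score"),
    by = "subject_id")
  if (nrow(j) != nrow(scores_a) || nrow(j) != nrow(scores_b))
    stop("score tables do not cover the same subjects", call. = FALSE)
  rows <- lapply(split(j, j$group), function(g) {
    sa <- column_summary(g$score_a); sb <- column_summary(g$score_b)
    tt <- tryCatch(paired_ttest(g$score_a, g$score_b), error = function(e) NULL)
    tibble::tibble(
      group = g$group[1], n = nrow(g),
      mean_a = unname(sa["mean"]), sd_a = unname(sa["sd"]),
      mean_b = unname(sb["mean"]), sd_b = unname(sb["sd"]),
      mean_diff = mean(g$score_a - g$score_b),
      t = if (is.null(tt)) NA_real_ else tt$t,
      df = if (is.null(tt)) NA_integer_ else tt$df,
      p = if (is.null(tt)) NA_real_ else tt$p,
      verdict = if (is.null(tt)) "no difference"
                else if (tt$p < alpha) "significant" else "NS")
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "scores") <- j
  attr(out, "alpha") <- alpha
  attr(out, "models") <- c(a = scores_a$model[1], b = scores_b$model[1])
  class(out) <- c("petrad_comparison", class(out))
  out
}

#' Reference per-subject probability scores
#'
#' The published worked example the comparison report is validated against:
#' probability scores (0-100) of 10 healthy controls and 10 dementia
#' patients, each scored by a radiomics-feature network and by a 3D CNN.
#'
#' @return tibble `subject_id`, `group`, `diagnosis`, `radiomics`, `cnn`.
#' @export
reference_scores <- function() {
  path <- system.file("extdata", "reference_scores.csv", package = "petrad")
  tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
}
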