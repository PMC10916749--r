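# Feature selection: greedy minimum-redundancy maximum-relevance ranking by
# mutual information (quotient criterion), truncation to the top fraction,
# then Pearson-correlation pruning in rank order. All selection statistics
# are meant to be computed on training subjects only.

# internal: equal-frequency discretization into at most `bins` levels
discretize_quantile <- function(x, bins = 4) {
  br <- unique(quantile(x, probs = seq(0, 1, length.out = bins + 1),
                        names = FALSE, type = 7))
  if (length(br) < 2) return(factor(rep(1L, length(x))))
  cut(x, breaks = br, include.lowest = TRUE)
}

# internal: mutual information (bits) between two discrete variables
mutual_information <- function(x, y) {
  tab <- table(x, y)
  n <- sum(tab)
  if (n == 0) return(0)
  p <- tab / n
  px <- rowSums(p); py <- colSums(p)
  e <- outer(px, py)
  sel <- p > 0
  sum(p[sel] * log2(p[sel] / e[sel]))
}

#' Greedy MRMR feature ranking
#'
#' Ranks features by the mutual-information quotient criterion: relevance is
#' the MI between the feature (discretized into 16 equal-frequency bins)
#' and the binary label;
#' redundancy is the mean MI with already-ranked features. The first pick is
#' the most relevant feature; later picks maximize
#' `relevance / max(redundancy, eps)`. Features containing `NaN`/`NA` in any
#' subject are dropped before ranking and reported in `dropped`. Ties break
#' by column (manifest) order, so the ranking is deterministic.
#'
#' @param features tibble or matrix of numeric feature columns
#'   (subjects x features).
#' @param labels binary label vector, one per subject.
#' @param k how many features to rank (default: all).
#' @param mi_bins equal-frequency bins for MI estimation (default 16).
#' @return a `petrad_selection`: list with `ranked` (tibble `rank`,
#'   `feature`, `score`, `relevance`, `redundancy`), `dropped`,
#'   `n_features`, and empty selection/pruning slots.
#' @export
mrmr_rank <- function(features, labels, k = NULL, mi_bins = 16) {
  X <- as.data.frame(features)
  stopifnot(nrow(X) == length(labels))
  if (nrow(X) < 10) stop("need at least 10 subjects to rank", call. = FALSE)
  if (length(unique(labels)) != 2) stop("labels must be binary", call. = FALSE)
  bad <- vapply(X, function(v) any(!is.finite(v)), logical(1))
  dropped <- names(X)[bad]
  X <- X[!bad]
  nf <- ncol(X)
  if (is.null(k)) k <- nf
  k <- min(k, nf)
  disc <- lapply(X, discretize_quantile, bins = mi_bins)
  rel <- vapply(disc, mutual_information, numeric(1), y = labels)
  # pairwise MI computed lazily against already-selected features
  mi_cache <- matrix(NA_real_, nf, nf)
  selected <- integer(0)
  avail <- seq_len(nf)
  rows <- vector("list", k)
  eps <- .Machine$double.eps
  for (step in seq_len(k)) {
    if (length(selected) == 0) {
      red <- rep(0, length(avail))
      score <- rel[avail]
    } else {
      red <- vapply(avail, function(a) {
        mis <- vapply(selected, function(s) {
          if (is.na(mi_cache[a, s]))
            mi_cache[a, s] <<- mi_cache[s, a] <<-
              mutual_information(disc[[a]], disc[[s]])
          mi_cache[a, s]
        }, numeric(1))
        mean(mis)
      }, numeric(1))
      score <- rel[avail] / pmax(red, eps)
    }
    pick <- avail[which.max(score)]   # which.max takes the first on ties
    rows[[step]] <- tibble::tibble(
      rank = step, feature = names(X)[pick],
      score = unname(score[match(pick, avail)]),
      relevance = unname(rel[pick]),
      redundancy = unname(if (length(selected)) red[match(pick, avail)] else 0))
    selected <- c(selected, pick)
    avail <- setdiff(avail, pick)
    if (length(avail) == 0) break
  }
  structure(list(ranked = dplyr::bind_rows(rows), dropped = dropped,
                 n_features = nf, k_selected = NULL, kept = NULL,
                 correlation_matrix = NULL, r_threshold = NULL),
            class = "petrad_selection")
}

#' Keep the top fraction of the MRMR ranking
#'
#' `k_selected = floor(fraction * n_features)` where `n_features` counts the
#' features that entered the ranking (215 features at the default 10% give
#' 21).
#'
#' @param selection a `petrad_selection` from [mrmr_rank()].
#' @param fraction fraction of features to keep (default 0.10).
#' @return the selection with `k_selected` set.
#' @export
select_top_fraction <- function(selection, fraction = 0.10) {
  stopifnot(inherits(selection, "petrad_selection"),
            fraction > 0, fraction <= 1)
  selection$k_selected <- max(1L, as.integer(floor(fraction * selection$n_features)))
  selection
}

#' Prune correlated features from the MRMR selection
#'
#' Walks the top-`k_selected` features in MRMR rank order and keeps a feature
#' only if its absolute Pearson correlation with every already-kept feature
#' is strictly below `r_threshold`. The kept set's correlation matrix is
#' attached as a certificate; its largest off-diagonal `|r|` is always below
#' the threshold.
#'
#' @param selection a `petrad_selection` with `k_selected` set (see
#'   [select_top_fraction()]).
#' @param features the feature table the correlations are computed on
#'   (training subjects only, by design).
#' @param r_threshold pairwise correlation bound (default 0.30).
#' @return the selection with `kept`, `correlation_matrix`, `r_threshold`.
#' @export
pearson_prune <- function(selection, features, r_threshold = 0.30) {
  stopifnot(inherits(selection, "petrad_selection"))
  if (is.null(selection$k_selected))
    selection <- select_top_fraction(selection)
  X <- as.data.frame(features)
  top <- head(selection$ranked$feature, selection$k_selected)
  kept <- character(0)
  for (f in top) {
    if (length(kept) == 0) { kept <- f; next }
    r <- vapply(kept, function(g) {
      v <- suppressWarnings(cor(X[[f]], X[[g]]))
      if (is.na(v)) 0 else v        # zero-variance features correlate with nothing
    }, numeric(1))
    if (max(abs(r)) < r_threshold) kept <- c(kept, f)
  }
  cm <- suppressWarnings(cor(as.matrix(X[kept])))
  cm[is.na(cm)] <- 0; diag(cm) <- 1
  cert <- check_correlation_certificate(cm, r_threshold)
  if (!cert$pass)
    stop("pruning failed its own certificate; this is a bug", call. = FALSE)
  selection$kept <- kept
  selection$correlation_matrix <- cm
  selection$r_threshold <- r_threshold
  selection
}

#' Check a correlation-certificate matrix against a threshold
#'
#' @param m square correlation matrix.
#' @param r_threshold strict bound on off-diagonal `|r|`.
#' @return list with `max_abs_r` (0 for a 1x1 matrix) and `pass`.
#' @export
check_correlation_certificate <- function(m, r_threshold = 0.30) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  off <- abs(m[row(m) != col(m)])
  mx <- if (length(off)) max(off) else 0
  list(max_abs_r = mx, pass = mx < r_threshold)
}

#' @export
print.petrad_selection <- function(x, ...) {
  cat(sprintf("<MRMR selection: %d features ranked", nrow(x$ranked)))
  if (!is.null(x$k_selected)) cat(sprintf(", top %d selected", x$k_selected))
  if (!is.null(x$kept))
    cat(sprintf(", %d kept after |r| < %.2f pruning", length(x$kept),
                x$r_threshold))
  cat(">\n")
  if (length(x$dropped))
    cat("dropped (non-finite):", paste(x$dropped, collapse = ", "), "\n")
  invisible(x)
}
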