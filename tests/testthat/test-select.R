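make_noise_table <- function(n = 60, p = 20, seed = 5) {
  set.seed(seed)
  labels <- rep(c("a", "b"), each = n / 2)
  X <- as.data.frame(matrix(rnorm(n * p), n, p))
  names(X) <- sprintf("noise%02d", seq_len(p))
  list(X = X, labels = labels)
}

test_that("a label-identical feature ranks first", {
  nt <- make_noise_table()
  nt$X$signal <- as.numeric(nt$labels == "a")
  sel <- mrmr_rank(nt$X, nt$labels)
  expect_equal(sel$ranked$feature[1], "signal")
  expect_gt(sel$ranked$relevance[1], max(sel$ranked$relevance[-1]))
})

test_that("an exact duplicate of the top feature is penalized by redundancy", {
  nt <- make_noise_table(seed = 6)
  set.seed(7)
  nt$X$signal <- as.numeric(nt$labels == "a") + rnorm(60, sd = 0.05)
  nt$X$signal_dup <- nt$X$signal
  # a second, independent informative feature
  nt$X$signal2 <- as.numeric(nt$labels == "a") * 2 +
    rnorm(60, sd = 0.3) + nt$X$noise01
  sel <- mrmr_rank(nt$X, nt$labels)
  expect_equal(sel$ranked$feature[1], "signal")
  expect_false(sel$ranked$feature[2] == "signal_dup")
})

test_that("ranking is a deterministic permutation of all features", {
  nt <- make_noise_table(n = 30, p = 8)
  s1 <- mrmr_rank(nt$X, nt$labels)
  s2 <- mrmr_rank(nt$X, nt$labels)
  expect_identical(s1$ranked, s2$ranked)
  expect_setequal(s1$ranked$feature, names(nt$X))
  expect_equal(nrow(s1$ranked), 8)
})

test_that("constant and NaN features are handled by the documented policy", {
  nt <- make_noise_table(n = 30, p = 5)
  nt$X$flat <- 1                      # constant: MI 0, ranks last
  nt$X$broken <- c(NaN, rnorm(29))    # dropped before ranking
  sel <- mrmr_rank(nt$X, nt$labels)
  expect_equal(sel$dropped, "broken")
  expect_equal(sel$ranked$feature[nrow(sel$ranked)], "flat")
  expect_equal(sel$ranked$relevance[nrow(sel$ranked)], 0)
})

test_that("top-fraction rule: floor(fraction * n)", {
  nt <- make_noise_table(n = 20, p = 10)
  sel <- mrmr_rank(nt$X, nt$labels)
  expect_equal(select_top_fraction(sel, 0.10)$k_selected, 1L)
  expect_equal(select_top_fraction(sel, 1.0)$k_selected, 10L)
  # 215 features at 10% give 21
  expect_equal(floor(0.10 * 215), 21)
})

test_that("pruning keeps the first member of each correlated clique", {
  set.seed(9)
  n <- 80
  labels <- rep(c("a", "b"), each = n / 2)
  base <- as.numeric(labels == "a") + rnorm(n, sd = 0.4)
  X <- data.frame(
    f1 = base,
    f2 = base + rnorm(n, sd = 0.1),               # |r| with f1 ~ 0.97
    f3 = rnorm(n) + 0.3 * as.numeric(labels == "a"))  # nearly independent
  expect_gt(abs(cor(X$f1, X$f2)), 0.9)
  expect_lt(abs(cor(X$f1, X$f3)), 0.3)
  sel <- mrmr_rank(X, labels) |> select_top_fraction(1.0) |>
    pearson_prune(X, 0.30)
  expect_true("f1" %in% sel$kept || "f2" %in% sel$kept)
  expect_false(all(c("f1", "f2") %in% sel$kept))
  expect_true("f3" %in% sel$kept)
  cert <- check_correlation_certificate(sel$correlation_matrix, 0.30)
  expect_true(cert$pass)
})

test_that("two identical features: only the first survives pruning", {
  set.seed(10)
  n <- 40
  labels <- rep(c("a", "b"), each = n / 2)
  X <- data.frame(g1 = rnorm(n) + as.numeric(labels == "a"))
  X$g2 <- X$g1
  sel <- mrmr_rank(X, labels) |> select_top_fraction(1.0) |>
    pearson_prune(X, 0.30)
  expect_length(sel$kept, 1)
})

test_that("the published 4x4 correlation matrix passes the certificate at 0.30", {
  m <- matrix(c(1, -0.1489, -0.2330, -0.0365,
                -0.1489, 1, 0.2994, -0.2223,
                -0.2330, 0.2994, 1, -0.2239,
                -0.0365, -0.2223, -0.2239, 1), 4, 4, byrow = TRUE,
              dimnames = rep(list(c("maximum", "ldlgle", "dn", "iqr")), 2))
  cert <- check_correlation_certificate(m, 0.30)
  expect_true(cert$pass)
  expect_equal(cert$max_abs_r, 0.2994)
})

test_that("planted informative features are recovered in the top ranks", {
  # Monte-Carlo recovery: 3 planted features among 27 noise columns
  hits <- vapply(1:20, function(r) {
    set.seed(100 + r)
    n <- 80
    labels <- rep(c("a", "b"), each = n / 2)
    X <- as.data.frame(matrix(rnorm(n * 27), n))
    names(X) <- sprintf("n%02d", 1:27)
    for (k in 1:3)
      X[[paste0("sig", k)]] <- as.numeric(labels == "a") * 1.5 + rnorm(n)
    sel <- mrmr_rank(X, labels)
    all(paste0("sig", 1:3) %in% head(sel$ranked$feature, 10))
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
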