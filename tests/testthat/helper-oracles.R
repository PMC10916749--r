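# Exhaustive brute-force oracles for the texture matrices, kept deliberately
# naive (triple loops, repeated scans) and independent of the package's
# compiled implementations. Levels arrays use 0 = outside mask.

oracle_dirs <- matrix(c(1,0,0, 0,1,0, 0,0,1,
                        1,1,0, 1,-1,0, 1,0,1, 1,0,-1, 0,1,1, 0,1,-1,
                        1,1,1, 1,1,-1, 1,-1,1, 1,-1,-1),
                      ncol = 3, byrow = TRUE)

oracle_in <- function(p, d) all(p >= 1) && all(p <= d)

# symmetric co-occurrence counts, per direction
oracle_glcm <- function(lev, nbins) {
  d <- dim(lev)
  out <- array(0, dim = c(nbins, nbins, 13))
  for (k in seq_len(13)) for (z in 1:d[3]) for (y in 1:d[2]) for (x in 1:d[1]) {
    i <- lev[x, y, z]
    if (i == 0) next
    q <- c(x, y, z) + oracle_dirs[k, ]
    if (!oracle_in(q, d)) next
    j <- lev[q[1], q[2], q[3]]
    if (j == 0) next
    out[i, j, k] <- out[i, j, k] + 1
    out[j, i, k] <- out[j, i, k] + 1
  }
  out
}

# maximal-run counts per direction
oracle_glrlm <- function(lev, nbins) {
  d <- dim(lev)
  lmax <- max(d)
  out <- array(0, dim = c(nbins, lmax, 13))
  for (k in seq_len(13)) {
    dir <- oracle_dirs[k, ]
    for (z in 1:d[3]) for (y in 1:d[2]) for (x in 1:d[1]) {
      i <- lev[x, y, z]
      if (i == 0) next
      prev <- c(x, y, z) - dir
      if (oracle_in(prev, d) && lev[prev[1], prev[2], prev[3]] == i) next
      len <- 1
      nxt <- c(x, y, z) + dir
      while (oracle_in(nxt, d) && lev[nxt[1], nxt[2], nxt[3]] == i) {
        len <- len + 1
        nxt <- nxt + dir
      }
      out[i, len, k] <- out[i, len, k] + 1
    }
  }
  out
}

# 26-connected equal-level zones by repeated region growing
oracle_zones <- function(lev) {
  d <- dim(lev)
  seen <- array(FALSE, dim = d)
  res <- list()
  for (start in which(lev > 0 & !seen)) {
    if (seen[start]) next
    i <- lev[start]
    zone <- start
    frontier <- start
    seen[start] <- TRUE
    while (length(frontier)) {
      nxt <- integer(0)
      for (f in frontier) {
        p <- arrayInd(f, d)[1, ]
        for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
          if (dx == 0 && dy == 0 && dz == 0) next
          q <- p + c(dx, dy, dz)
          if (!oracle_in(q, d)) next
          qi <- q[1] + d[1] * (q[2] - 1 + d[2] * (q[3] - 1))
          if (!seen[qi] && lev[qi] == i) {
            seen[qi] <- TRUE
            nxt <- c(nxt, qi)
          }
        }
      }
      zone <- c(zone, nxt)
      frontier <- nxt
    }
    res[[length(res) + 1]] <- list(level = i, voxels = zone)
  }
  res
}

# city-block distance to the nearest outside voxel, boundary counts as
# outside; O(n^2) pairwise scan
oracle_distance_map <- function(lev) {
  d <- dim(lev)
  out <- array(0L, dim = d)
  outside <- which(lev == 0)
  oc <- if (length(outside)) arrayInd(outside, d) else
    matrix(numeric(0), 0, 3)
  for (v in which(lev > 0)) {
    p <- arrayInd(v, d)[1, ]
    dist_edge <- min(p - 0, d - p + 1)     # steps to leave the grid
    dist_out <- if (nrow(oc))
      min(rowSums(abs(sweep(oc, 2, p)))) else Inf
    out[v] <- min(dist_edge, dist_out)
  }
  out
}

oracle_ngldm <- function(lev, nbins, alpha, delta) {
  d <- dim(lev)
  side <- 2 * delta + 1
  out <- matrix(0, nbins, side^3)
  for (z in 1:d[3]) for (y in 1:d[2]) for (x in 1:d[1]) {
    i <- lev[x, y, z]
    if (i == 0) next
    k <- 0
    for (dx in -delta:delta) for (dy in -delta:delta) for (dz in -delta:delta) {
      if (dx == 0 && dy == 0 && dz == 0) next
      q <- c(x + dx, y + dy, z + dz)
      if (!oracle_in(q, d)) next
      j <- lev[q[1], q[2], q[3]]
      if (j > 0 && abs(j - i) <= alpha) k <- k + 1
    }
    out[i, k + 1] <- out[i, k + 1] + 1
  }
  out
}

oracle_ngtdm <- function(lev, nbins, delta) {
  d <- dim(lev)
  s <- numeric(nbins); n <- numeric(nbins)
  for (z in 1:d[3]) for (y in 1:d[2]) for (x in 1:d[1]) {
    i <- lev[x, y, z]
    if (i == 0) next
    nb <- c()
    for (dx in -delta:delta) for (dy in -delta:delta) for (dz in -delta:delta) {
      if (dx == 0 && dy == 0 && dz == 0) next
      q <- c(x + dx, y + dy, z + dz)
      if (!oracle_in(q, d)) next
      j <- lev[q[1], q[2], q[3]]
      if (j > 0) nb <- c(nb, j)
    }
    if (length(nb) == 0) next
    s[i] <- s[i] + abs(i - mean(nb))
    n[i] <- n[i] + 1
  }
  list(s = s, n = n)
}

# random small binned fixture (levels with 0 = outside)
random_fixture <- function(seed) {
  set.seed(seed)
  d <- sample(3:6, 3, replace = TRUE)
  nbins <- sample(2:4, 1)
  lev <- array(sample(0:nbins, prod(d), replace = TRUE,
                      prob = c(0.25, rep(0.75 / nbins, nbins))),
               dim = d)
  if (all(lev == 0)) lev[1] <- 1L
  storage.mode(lev) <- "integer"
  list(levels = lev, n_bins = nbins)
}
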