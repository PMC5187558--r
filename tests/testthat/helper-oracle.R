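# Naive window-by-window counting oracle, written directly from the
# neighbor offset convention (0-based: unit (r, c) has down-neighbors
# (r+1, c) and (r+1, c+1) for even r, (r+1, c-1) and (r+1, c) for odd r,
# indices wrapped). Deliberately loop-based and independent of the
# package's row-pair-chain implementation.

oracleClassifyTriplet <- function(a, b, c) {
  key <- paste0(a, b, c)
  switch(key,
    AAA = 1L, AAB = 2L, BAA = 2L, ABA = 3L, BAB = 4L,
    ABB = 5L, BBA = 5L, BBB = 6L)
}

oracleClassifyPair <- function(a, b) {
  if (a == "A" && b == "A") 1L else if (a == "B" && b == "B") 3L else 2L
}

# All triplet windows of a circular chain, one per starting unit.
oracleChainTriplets <- function(u) {
  n <- length(u)
  Z <- integer(6)
  for (i in seq_len(n)) {
    j <- i %% n + 1L
    k <- j %% n + 1L
    cl <- oracleClassifyTriplet(u[i], u[j], u[k])
    Z[cl] <- Z[cl] + 1L
  }
  Z
}

oracleChainPairs <- function(u, gap = 1L) {
  n <- length(u)
  Y <- integer(3)
  for (i in seq_len(n)) {
    j <- (i - 1L + gap) %% n + 1L
    cl <- oracleClassifyPair(u[i], u[j])
    Y[cl] <- Y[cl] + 1L
  }
  Y
}

# 2-D oracle: for every unit, one "V" window with its two down-neighbors
# (apex on top) and one "Lambda" window with its two up-neighbors (apex on
# the bottom); 2N windows in all. Pairs: every down-diagonal link once
# (2N); next-nearest: the end pairs of every triplet window (2N).
oracleGridDownNeighbors <- function(r, c, R, C) {
  # 0-based in, 0-based out
  r2 <- (r + 1L) %% R
  if (r %% 2L == 0L) {
    cbind(r2, c(c, (c + 1L) %% C))
  } else {
    cbind(r2, c((c - 1L) %% C, c))
  }
}

oracleGridCounts <- function(g) {
  R <- nrow(g); C <- ncol(g)
  Z <- integer(6); Y <- integer(3); W <- integer(3)
  for (r in 0:(R - 1L)) {
    for (c in 0:(C - 1L)) {
      u <- g[r + 1L, c + 1L]
      dn <- oracleGridDownNeighbors(r, c, R, C)
      d1 <- g[dn[1, 1] + 1L, dn[1, 2] + 1L]
      d2 <- g[dn[2, 1] + 1L, dn[2, 2] + 1L]
      # V window: apex (middle) on top, ends below
      cl <- oracleClassifyTriplet(d1, u, d2)
      Z[cl] <- Z[cl] + 1L
      W[oracleClassifyPair(d1, d2)] <- W[oracleClassifyPair(d1, d2)] + 1L
      # the two down links, each counted once here and never elsewhere
      Y[oracleClassifyPair(u, d1)] <- Y[oracleClassifyPair(u, d1)] + 1L
      Y[oracleClassifyPair(u, d2)] <- Y[oracleClassifyPair(u, d2)] + 1L
      # Lambda window: apex below, ends on top. (r-1, c') is an
      # up-neighbor of (r, c) iff (r, c) is among its down-neighbors;
      # found by scanning the row above with the down rule.
      rp <- (r - 1L) %% R
      ups <- character(0)
      for (cp in 0:(C - 1L)) {
        dnp <- oracleGridDownNeighbors(rp, cp, R, C)
        for (k in 1:2) {
          if (dnp[k, 1] == r && dnp[k, 2] == c) {
            ups <- c(ups, g[rp + 1L, cp + 1L])
          }
        }
      }
      stopifnot(length(ups) == 2L)
      cl2 <- oracleClassifyTriplet(ups[1], u, ups[2])
      Z[cl2] <- Z[cl2] + 1L
      W[oracleClassifyPair(ups[1], ups[2])] <-
        W[oracleClassifyPair(ups[1], ups[2])] + 1L
    }
  }
  list(Y = Y, W = W, Z = Z)
}

randomLattice <- function(n, dims = 1L, seed) {
  set.seed(seed)
  if (dims == 1L) {
    BistateLattice(sample(c("A", "B"), n, replace = TRUE))
  } else {
    dims2 <- c(2L * sample(1:3, 1L), sample(3:8, 1L))
    BistateLattice(matrix(sample(c("A", "B"), prod(dims2), replace = TRUE),
                          nrow = dims2[1L]))
  }
}
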