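## Configuration-variable counting: singles, nearest-neighbor pairs,
## next-nearest-neighbor pairs, triplet windows.
##
## Conventions:
##  * 1-D: windows are taken over the circular zigzag-order chain; a chain
##    of N units has N pair windows (i, i+1), N next-nearest windows
##    (i, i+2), and N triplet windows (i, i+1, i+2).
##  * 2-D: odd-indexed rows (0-based) are offset half a cell; unit (r, c)
##    has diagonal down-neighbors (r+1, c) and (r+1, c+1) when r is even,
##    (r+1, c-1) and (r+1, c) when r is odd, all indices wrapped. Each
##    adjacent row pair, traversed in zigzag order, is a circular chain of
##    2C units; counting every row pair (with the vertical envelope wrap)
##    gives 2N windows of each kind. Next-nearest-neighbor windows are the
##    end pairs of triplet windows, so #w = #z by construction.

## Triplet class of window codes 4*first + 2*mid + 1*last (A = 1, B = 0):
## AAA->z1, {AAB,BAA}->z2, ABA->z3, BAB->z4, {ABB,BBA}->z5, BBB->z6.
.tripletClass <- c(6L, 5L, 4L, 2L, 5L, 3L, 2L, 1L)  # codes 0..7
## Pair class of codes 2*first + last: BB->3, {BA,AB}->2, AA->1.
.pairClass <- c(3L, 2L, 2L, 1L)                      # codes 0..3

## Class counts on one circular chain given as a 0/1 vector (A = 1).
.chainCounts <- function(a) {
  n <- length(a)
  i2 <- c(2:n, 1L)
  i3 <- c(3:n, 1L, 2L)
  list(
    Y = tabulate(.pairClass[2L * a + a[i2] + 1L], nbins = 3L),
    W = tabulate(.pairClass[2L * a + a[i3] + 1L], nbins = 3L),
    Z = tabulate(.tripletClass[4L * a + 2L * a[i2] + a[i3] + 1L], nbins = 6L)
  )
}

## Zigzag-order traversal of the row pair (r, r+1 mod R), 1-based r.
## For 0-based even r the chain starts on the lower row, for odd r on the
## upper row, so that consecutive chain positions are exactly the diagonal
## nearest-neighbor links of the offset convention.
.rowPairChain <- function(units, r) {
  R <- nrow(units)
  r2 <- if (r == R) 1L else r + 1L
  top <- units[r, ]
  bot <- units[r2, ]
  C <- length(top)
  out <- character(2L * C)
  if ((r - 1L) %% 2L == 0L) {
    out[seq(1L, 2L * C, by = 2L)] <- bot
    out[seq(2L, 2L * C, by = 2L)] <- top
  } else {
    out[seq(1L, 2L * C, by = 2L)] <- top
    out[seq(2L, 2L * C, by = 2L)] <- bot
  }
  out
}

#' Count all configuration variables on a lattice
#'
#' Counts single units, nearest-neighbor pairs, next-nearest-neighbor pairs
#' (triplet end pairs), and triplet windows, pooled over orderings within
#' each class, under full periodic wraparound. A 1-D chain of N units
#' yields N windows of each kind; a 2-D grid of N units yields 2N (one "V"
#' and one "Lambda" window per unit).
#'
#' @param lattice a [BistateLattice-class].
#' @return a [ConfigurationCounts-class].
#' @examples
#' countConfigurations(generatePattern("equilibrium_motif", 32))
#' @export
countConfigurations <- function(lattice) {
  stopifnot(is(lattice, "BistateLattice"))
  u <- lattice@units
  N <- length(u)
  X <- c(sum(u == "A"), sum(u == "B"))
  if (lattice@dims == 1L) {
    cc <- .chainCounts(as.integer(as.vector(u) == "A"))
    Y <- cc$Y; W <- cc$W; Z <- cc$Z
    total <- N
  } else {
    Y <- integer(3L); W <- integer(3L); Z <- integer(6L)
    for (r in seq_len(nrow(u))) {
      cc <- .chainCounts(as.integer(.rowPairChain(u, r) == "A"))
      Y <- Y + cc$Y; W <- W + cc$W; Z <- Z + cc$Z
    }
    total <- 2L * N
  }
  new("ConfigurationCounts",
      X = as.integer(X), Y = as.integer(Y), W = as.integer(W),
      Z = as.integer(Z),
      nWindows = c(pair = total, nnn = total, triplet = total),
      N = as.integer(N), dims = lattice@dims)
}

#' Single-unit fractions of a lattice
#'
#' @param lattice a [BistateLattice-class].
#' @return named numeric `c(x1, x2)` with `x1` the fraction of A units.
#' @examples
#' countSingles(readLattice(text = "AAAB"))
#' @export
countSingles <- function(lattice) {
  cc <- countConfigurations(lattice)
  c(x1 = cc@X[1L] / cc@N, x2 = cc@X[2L] / cc@N)
}

#' Pair-class counts and fractions of a lattice
#'
#' Nearest-neighbor pairs are consecutive units in zigzag order (the
#' diagonal links of the staggered drawing); next-nearest-neighbor pairs
#' are the two end units of each triplet window (within-row links).
#' Fractions are per-arrangement: the mixed class is divided by its
#' degeneracy 2.
#'
#' @param lattice a [BistateLattice-class].
#' @param kind `"nearest"` or `"next_nearest"`.
#' @return a list with integer `counts` (length 3), numeric per-arrangement
#'   `fractions` (length 3), and the window `total`.
#' @examples
#' countPairs(readLattice(text = "ABABABAB"))
#' @export
countPairs <- function(lattice, kind = c("nearest", "next_nearest")) {
  kind <- match.arg(kind)
  cc <- countConfigurations(lattice)
  counts <- if (kind == "nearest") cc@Y else cc@W
  total <- cc@nWindows[["pair"]]
  names(counts) <- if (kind == "nearest") c("Y1", "Y2", "Y3") else c("W1", "W2", "W3")
  fr <- counts / (.beta * total)
  names(fr) <- tolower(names(counts))
  list(counts = counts, fractions = fr, total = total)
}

#' Triplet-class counts and fractions of a lattice
#'
#' Triplet windows are three consecutive units in zigzag order (1-D: all N
#' circular windows; 2-D: one "V" and one "Lambda" window per unit, 2N in
#' all). Classes pool orderings: `z2` covers A-A-B and B-A-A, `z5` covers
#' B-B-A and A-B-B. Fractions are per-arrangement (`z2`, `z5` divided by
#' their degeneracy 2); `aggregated` gives the degeneracy-weighted values.
#'
#' @param lattice a [BistateLattice-class].
#' @return a list with integer `counts` (`Z1..Z6`), per-arrangement
#'   `fractions`, `aggregated` fractions (\eqn{\gamma_i z_i}), and the
#'   window `total`.
#' @examples
#' countTriplets(generatePattern("ferro_defect", 32))$counts
#' @export
countTriplets <- function(lattice) {
  cc <- countConfigurations(lattice)
  counts <- cc@Z
  names(counts) <- paste0("Z", 1:6)
  total <- cc@nWindows[["triplet"]]
  fr <- counts / (.gamma * total)
  names(fr) <- paste0("z", 1:6)
  list(counts = counts, fractions = fr, aggregated = .gamma * fr,
       total = total)
}

#' Normalize raw counts into configuration fractions
#'
#' Divides each class count by (degeneracy x window total), giving the
#' per-arrangement convention in which \eqn{\sum_i \gamma_i z_i = 1}.
#'
#' @param counts a [ConfigurationCounts-class].
#' @return a [ConfigurationFractions-class].
#' @examples
#' configFractions(countConfigurations(generatePattern("equilibrium_motif", 32)))
#' @export
configFractions <- function(counts) {
  stopifnot(is(counts, "ConfigurationCounts"))
  total <- counts@nWindows[["triplet"]]
  new("ConfigurationFractions",
      x = counts@X / counts@N,
      y = counts@Y / (.beta * total),
      w = counts@W / (.beta * total),
      z = counts@Z / (.gamma * total),
      nWindows = as.numeric(total),
      dims = counts@dims)
}

## Builds a ConfigurationFractions from bare component vectors.
.makeFractions <- function(x, y, w, z, dims, nWindows = NA_real_) {
  new("ConfigurationFractions", x = unname(x), y = unname(y), w = unname(w),
      z = unname(z), nWindows = nWindows, dims = as.integer(dims))
}

.fractionVector <- function(x, y, w, z, aggregated = FALSE) {
  if (aggregated) {
    y <- .beta * y
    w <- .beta * w
    z <- .gamma * z
  }
  c(x1 = x[1L], x2 = x[2L],
    y1 = y[1L], y2 = y[2L], y3 = y[3L],
    w1 = w[1L], w2 = w[2L], w3 = w[3L],
    z1 = z[1L], z2 = z[2L], z3 = z[3L], z4 = z[4L], z5 = z[5L], z6 = z[6L])
}

#' @describeIn fractions per-arrangement (or aggregated) fractions.
#' @export
setMethod("fractions", "ConfigurationFractions",
  function(x, aggregated = FALSE) {
    .fractionVector(x@x, x@y, x@w, x@z, aggregated)
  })

#' @describeIn fractions fractions computed from raw counts.
#' @export
setMethod("fractions", "ConfigurationCounts",
  function(x, aggregated = FALSE) {
    fractions(configFractions(x), aggregated = aggregated)
  })

#' @describeIn nUnits unit count behind the counts.
#' @export
setMethod("nUnits", "ConfigurationCounts", function(x) x@N)

#' @describeIn latticeDims dimensionality behind the counts.
#' @export
setMethod("latticeDims", "ConfigurationCounts", function(x) x@dims)

#' @describeIn latticeDims dimensionality behind the fractions.
#' @export
setMethod("latticeDims", "ConfigurationFractions", function(x) x@dims)

#' @describeIn swapStates relabel fractions (x1 <-> x2, y1 <-> y3,
#'   w1 <-> w3, z1 <-> z6, z2 <-> z5, z3 <-> z4).
#' @export
setMethod("swapStates", "ConfigurationFractions", function(x) {
  new("ConfigurationFractions",
      x = rev(x@x), y = rev(x@y), w = rev(x@w),
      z = x@z[c(6L, 5L, 4L, 3L, 2L, 1L)],
      nWindows = x@nWindows, dims = x@dims)
})

setMethod("show", "ConfigurationCounts", function(object) {
  cat(sprintf("ConfigurationCounts: %d-D lattice, N = %d units, %d windows per kind\n",
              object@dims, object@N, object@nWindows[["triplet"]]))
  cat("  X:", paste(sprintf("%s=%d", c("A", "B"), object@X), collapse = " "), "\n")
  cat("  Y:", paste(sprintf("Y%d=%d", 1:3, object@Y), collapse = " "), "\n")
  cat("  W:", paste(sprintf("W%d=%d", 1:3, object@W), collapse = " "), "\n")
  cat("  Z:", paste(sprintf("Z%d=%d", 1:6, object@Z), collapse = " "), "\n")
})

setMethod("show", "ConfigurationFractions", function(object) {
  cat(sprintf("ConfigurationFractions (%d-D, per-arrangement convention)\n",
              object@dims))
  v <- fractions(object)
  cat("  ", paste(sprintf("%s=%.4f", names(v), v), collapse = " "), "\n",
      sep = "")
})
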