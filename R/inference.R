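## Inversion of observed triplet fractions to interaction-parameter
## estimates h1, h3, havg.

#' Invert an observed alternating-triplet fraction z3 to h
#'
#' Exact inversion of the equilibrium relation between `h` and the
#' alternating-triplet fraction. In 1-D, \eqn{1/(2 z_3) = (\sqrt s + 1)^2}
#' with \eqn{s = h^4}, so \eqn{\sqrt s = \sqrt{1/(2 z_3)} - 1} and
#' \eqn{h_3 = s^{1/4}}. In 2-D the analytic expression is a quadratic in
#' \eqn{u = h^2}: \eqn{(1 - 8 z_3) u^2 + (48 z_3 - 2) u - (3 + 8 z_3) = 0},
#' solved for the root with \eqn{u \in [1/3, 3]} (the valid branch);
#' \eqn{h_3 = \sqrt u}. The closed forms replace the look-up-table
#' procedure exactly; a table-with-interpolation path is retained for
#' parity experiments via [estimateH()]'s `method` argument.
#'
#' @param z3Obs observed per-arrangement z3, in `(0, 0.5]`.
#' @param dims 1 or 2.
#' @return the estimate `h3` (non-negative; 0 at `z3Obs = 0.5`).
#' @examples
#' invertZ3(0.125, dims = 1)  # 1
#' invertZ3(1 / 32, dims = 1) # sqrt(3)
#' @export
invertZ3 <- function(z3Obs, dims = 1) {
  if (!is.finite(z3Obs) || z3Obs <= 0 || z3Obs > 0.5 + 1e-12) {
    stop("'z3Obs' must lie in (0, 0.5]")
  }
  z3Obs <- min(z3Obs, 0.5)
  dims <- as.integer(dims)
  if (dims == 1L) {
    rootS <- sqrt(1 / (2 * z3Obs)) - 1  # = h^2
    return(sqrt(rootS))
  }
  ## 2-D: quadratic in u = h^2.
  a <- 1 - 8 * z3Obs
  b <- 48 * z3Obs - 2
  cc <- -(3 + 8 * z3Obs)
  if (abs(a) < 1e-12) {
    u <- -cc / b
  } else {
    disc <- b^2 - 4 * a * cc
    if (disc < 0) {
      stop("no real root: z3Obs is not attainable by the 2-D equilibrium")
    }
    roots <- (-b + c(1, -1) * sqrt(disc)) / (2 * a)
    inBranch <- roots >= 1 / 3 - 1e-9 & roots <= 3 + 1e-9
    if (!any(inBranch)) {
      stop(sprintf(
        "no root of the 2-D inversion lies in the valid branch u = h^2 in [1/3, 3] (roots %.6g, %.6g)",
        roots[1L], roots[2L]))
    }
    u <- roots[inBranch][1L]
  }
  sqrt(max(u, 0))
}

#' Invert an observed like-triplet fraction z1 to h
#'
#' In 1-D the inversion of \eqn{z_1 = s z_3} is exact:
#' \eqn{u = h^2 = \frac{2 z_1 + \sqrt{2 z_1}}{1 - 2 z_1}}, so
#' \eqn{h_1 = \sqrt u} (0 at \eqn{z_1 = 0}, with a `"z1_zero"` note for
#' degenerate observations handled by [estimateH()]). In 2-D no closed
#' form for \eqn{z_1(h)} is available, so the estimate is obtained by
#' root-finding `h` against the numerical equilibrium solution
#' [equilibrium2DNumeric()] on the valid branch.
#'
#' @param z1Obs observed per-arrangement z1, in `[0, 0.5)`.
#' @param dims 1 or 2.
#' @return the estimate `h1` (non-negative).
#' @examples
#' invertZ1(0.125, dims = 1)   # 1
#' invertZ1(11 / 32, dims = 1) # 2.2030
#' @export
invertZ1 <- function(z1Obs, dims = 1) {
  if (!is.finite(z1Obs) || z1Obs < 0 || z1Obs >= 0.5) {
    stop("'z1Obs' must lie in [0, 0.5)")
  }
  dims <- as.integer(dims)
  if (dims == 1L) {
    if (z1Obs == 0) return(0)
    u <- (2 * z1Obs + sqrt(2 * z1Obs)) / (1 - 2 * z1Obs)
    return(sqrt(u))
  }
  ## 2-D: root-find against the numerical minimizer on the valid branch.
  if (z1Obs == 0) return(1 / sqrt(3))
  ## Bracket well inside the branch: the minimizer loses conditioning as
  ## the fractions vanish at the endpoints.
  lo <- .branch2D[["lo"]] + 1e-3
  hi <- .branch2D[["hi"]] - 1e-3
  f <- function(h) suppressWarnings(equilibrium2DNumeric(h)@fractions@z[1L]) - z1Obs
  flo <- f(lo); fhi <- f(hi)
  if (flo > 0 || fhi < 0) {
    stop(sprintf(
      "z1Obs = %.6g is outside the range attainable on the valid 2-D branch (%.6g .. %.6g)",
      z1Obs, flo + z1Obs, fhi + z1Obs))
  }
  uniroot(f, c(lo, hi), tol = 1e-12)$root
}

## Table-with-interpolation inversion retained for parity experiments with
## the closed forms.
.tableInvert <- function(obs, which = c("z1", "z3"), dims = 1L,
                         gridSize = 2001L) {
  which <- match.arg(which)
  if (dims == 1L) {
    hs <- seq(1e-3, 6, length.out = gridSize)
    vals <- vapply(hs, function(h) {
      s <- h^4
      z3 <- 1 / (2 * (s + 1) + 4 * sqrt(s))
      if (which == "z1") s * z3 else z3
    }, numeric(1))
  } else {
    hs <- seq(.branch2D[["lo"]] + 1e-4, .branch2D[["hi"]] - 1e-4,
              length.out = 201L)
    vals <- vapply(hs, function(h) {
      suppressWarnings(equilibrium2DNumeric(h)@fractions@z[
        if (which == "z1") 1L else 3L])
    }, numeric(1))
  }
  o <- order(vals)
  stats::approx(vals[o], hs[o], xout = obs, rule = 2)$y
}

#' Estimate the interaction parameter from an observed lattice
#'
#' Counts the triplet windows of a lattice, forms the observed
#' per-arrangement fractions z1 and z3, and inverts the equilibrium
#' relations for the lattice's dimensionality to obtain `h1` (from z1) and
#' `h3` (from z3); `havg` is their arithmetic mean. The two estimates may
#' differ for small patterns, since a single flipped unit moves such a
#' system off equilibrium.
#'
#' The inversion presumes the equiprobable regime; if the observed `x1`
#' strays from 0.5 by more than `x1Tol` the result is flagged
#' (`"non_equiprobable"`, with a warning) or, with `strict = TRUE`,
#' rejected. By default z1 is pooled with its swap image z6 (and z3 with
#' z4) before inversion, which makes the estimate invariant under global
#' A/B relabeling; any pooled/unpooled asymmetry is reported in the flags,
#' never averaged silently.
#'
#' @param lattice a [BistateLattice-class].
#' @param pooled pool z1 with z6 and z3 with z4 before inversion.
#' @param x1Tol allowed deviation of x1 from 0.5.
#' @param strict reject (rather than flag) non-equiprobable input.
#' @param method `"closed_form"` (exact inversion) or `"table"`
#'   (look-up-table with interpolation, for parity experiments).
#' @return an [HEstimate-class].
#' @examples
#' estimateH(generatePattern("ferro_defect", 32))      # havg ~ 1.97
#' estimateH(generatePattern("equilibrium_motif", 32)) # havg = 1
#' @export
estimateH <- function(lattice, pooled = TRUE, x1Tol = 0.05, strict = FALSE,
                      method = c("closed_form", "table")) {
  stopifnot(is(lattice, "BistateLattice"))
  method <- match.arg(method)
  cc <- countConfigurations(lattice)
  flags <- character(0)
  x1 <- cc@X[1L] / cc@N
  if (abs(x1 - 0.5) > x1Tol) {
    msg <- sprintf(
      "x1 = %.3f deviates from the equiprobable premise (|x1 - 0.5| > %.3g)",
      x1, x1Tol)
    if (strict) stop(msg)
    warning(msg)
    flags <- c(flags, "non_equiprobable")
  }
  total <- cc@nWindows[["triplet"]]
  Z <- cc@Z
  if (pooled) {
    z1Obs <- (Z[1L] + Z[6L]) / (2 * total)
    z3Obs <- (Z[3L] + Z[4L]) / (2 * total)
    if (Z[1L] != Z[6L]) flags <- c(flags, "z1_pool_asymmetry")
    if (Z[3L] != Z[4L]) flags <- c(flags, "z3_pool_asymmetry")
  } else {
    z1Obs <- Z[1L] / total
    z3Obs <- Z[3L] / total
  }
  dims <- cc@dims
  ## Degenerate observations return boundary estimates with a flag rather
  ## than erroring, so alternation-like inputs remain processable.
  if (z1Obs == 0) flags <- c(flags, "z1_zero")
  if (z3Obs == 0) flags <- c(flags, "z3_zero")
  h1 <- if (method == "table" && z1Obs > 0) {
    .tableInvert(z1Obs, "z1", dims)
  } else {
    invertZ1(z1Obs, dims)
  }
  h3 <- if (z3Obs == 0) {
    if (dims == 1L) Inf else sqrt(3)  # limit of the valid branch
  } else if (method == "table") {
    .tableInvert(z3Obs, "z3", dims)
  } else {
    invertZ3(z3Obs, dims)
  }
  new("HEstimate", h1 = unname(h1), h3 = unname(h3),
      havg = unname((h1 + h3) / 2), z1 = unname(z1Obs), z3 = unname(z3Obs),
      nWindows = as.numeric(total), dims = dims, flags = flags)
}

#' Interaction-parameter estimates as a named vector
#'
#' @param x an [HEstimate-class].
#' @return named numeric `c(h1, h3, havg)`.
#' @export
hEstimates <- function(x) {
  stopifnot(is(x, "HEstimate"))
  c(h1 = x@h1, h3 = x@h3, havg = x@havg)
}

#' @describeIn latticeDims dimensionality behind an estimate.
#' @export
setMethod("latticeDims", "HEstimate", function(x) x@dims)

setMethod("show", "HEstimate", function(object) {
  cat(sprintf("HEstimate (%d-D, %g triplet windows)\n",
              object@dims, object@nWindows))
  cat(sprintf("  observed z1 = %.6f, z3 = %.6f\n", object@z1, object@z3))
  cat(sprintf("  h1 = %.4f  h3 = %.4f  havg = %.4f\n",
              object@h1, object@h3, object@havg))
  if (length(object@flags)) {
    cat("  flags:", paste(object@flags, collapse = ", "), "\n")
  }
})
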