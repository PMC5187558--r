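## Equilibrium configuration variables as functions of the interaction
## parameter h, for the equiprobable case x1 = x2 = 0.5.

## 2-D analytic branch: z3(h) runs from 0.5 down to 0 as h goes from
## 1/sqrt(3) to sqrt(3); outside this interval the printed expression
## leaves [0, 0.5] and eventually diverges at h^2 = 3 +/- 2*sqrt(2).
.branch2D <- c(lo = 1 / sqrt(3), hi = sqrt(3))
.sing2D <- c(sqrt(3 - 2 * sqrt(2)), sqrt(3 + 2 * sqrt(2)))

## Builds the full symmetric fraction set from (z1, z2, z3);
## z4 = z3, z5 = z2, z6 = z1, y from the counting identities, w as triplet
## end pairs.
.symmetricFractions <- function(z1, z2, z3, dims) {
  z <- c(z1, z2, z3, z3, z2, z1)
  y <- c(z1 + z2, z2 + z3, z1 + z2)
  w <- c(z1 + z3, 2 * z2, z1 + z3)
  .makeFractions(c(0.5, 0.5), y, w, z, dims = dims)
}

#' Closed-form 1-D equilibrium solution
#'
#' Equilibrium configuration variables of the 1-D zigzag chain at
#' interaction parameter `h`, in the equiprobable case: with
#' \eqn{s = h^4},
#' \deqn{z_3 = \frac{1}{2(s + 1) + 4\sqrt{s}}, \qquad z_1 = s\, z_3,}
#' (the positive root of the quadratic; the negative root contradicts
#' \eqn{z_3 = 0.125} at \eqn{h = 1}), with
#' \eqn{z_2 = (0.5 - z_1 - z_3)/2} from normalization and the equilibrium
#' symmetry \eqn{z_4 = z_3, z_5 = z_2, z_6 = z_1},
#' \eqn{y_1 = y_3 = z_1 + z_2}, \eqn{y_2 = z_2 + z_3}.
#'
#' @param h positive interaction parameter.
#' @return an [EquilibriumSolution-class].
#' @examples
#' equilibrium1D(1)        # all z_i = 0.125, y2 = 0.25
#' equilibrium1D(3)@fractions@z[1]  # 0.405
#' @export
equilibrium1D <- function(h) {
  if (!is.numeric(h) || length(h) != 1L || !is.finite(h) || h <= 0) {
    stop("'h' must be a single finite value > 0")
  }
  s <- h^4
  z3 <- 1 / (2 * (s + 1) + 4 * sqrt(s))
  z1 <- s * z3
  z2 <- (0.5 - z1 - z3) / 2
  fr <- .symmetricFractions(z1, z2, z3, dims = 1L)
  g <- reducedFreeEnergy(fr, thermoParams(h = h), dims = 1L)
  new("EquilibriumSolution", h = h, s = s, fractions = fr,
      gReduced = g@gReduced, dims = 1L, method = "closed_form",
      gradNorm = NA_real_, flags = character(0))
}

#' Analytic 2-D equilibrium triplet fraction z3
#'
#' The closed-form alternating-triplet fraction of the 2-D staggered grid,
#' \deqn{z_3(h) = \frac{(h^2 - 3)(h^2 + 1)}{8\,[h^4 - 6h^2 + 1]}.}
#' The expression is physically valid on the branch
#' \eqn{h \in [3^{-1/2}, 3^{1/2}]}, where \eqn{z_3} runs from 0.5 down to
#' 0; outside it the value leaves `[0, 0.5]` (flagged) and the denominator
#' vanishes at \eqn{h^2 = 3 \pm 2\sqrt 2} (an error within `singTol` of a
#' singularity).
#'
#' @param h positive interaction parameter.
#' @param singTol guard distance from the two singularities.
#' @return the fraction `z3`, with attributes `branch`
#'   (`"valid"`/`"outside"`) and `branchInterval`.
#' @examples
#' equilibrium2DZ3(1)    # 0.125
#' equilibrium2DZ3(sqrt(3))  # 0
#' @export
equilibrium2DZ3 <- function(h, singTol = 1e-6) {
  if (!is.numeric(h) || length(h) != 1L || !is.finite(h) || h <= 0) {
    stop("'h' must be a single finite value > 0")
  }
  if (any(abs(h - .sing2D) < singTol)) {
    stop(sprintf(
      "h = %.8g is within %.1g of a singularity of the 2-D expression (h = %.8g or %.8g)",
      h, singTol, .sing2D[1L], .sing2D[2L]))
  }
  u <- h^2
  z3 <- (u - 3) * (u + 1) / (8 * (u^2 - 6 * u + 1))
  inside <- h >= .branch2D[["lo"]] - 1e-12 && h <= .branch2D[["hi"]] + 1e-12
  structure(z3,
            branch = if (inside) "valid" else "outside",
            branchInterval = unname(.branch2D))
}

## ---- 2-D functional on the symmetric reduced parameterization ----------
##
## Free variables (z1, z3) with z2 = (0.5 - z1 - z3)/2 eliminated by the
## normalization constraint. Values and feasible-direction gradients of
## the reduced free energy.

.g2dValue <- function(z1, z3, eps) {
  z2 <- (0.5 - z1 - z3) / 2
  y1 <- z1 + z2; y2 <- z2 + z3
  w1 <- z1 + z3; w2 <- 2 * z2
  eps * 2 * (z2 + z3) -
    4 * (lf(y1) + lf(y2)) -
    2 * (lf(w1) + lf(w2)) + 2 * lf(0.5) +
    2 * (2 * lf(z1) + 4 * lf(z2) + 2 * lf(z3))
}

.g2dGrad <- function(z1, z3, eps) {
  z2 <- (0.5 - z1 - z3) / 2
  y1 <- z1 + z2; y2 <- z2 + z3
  w1 <- z1 + z3; w2 <- 2 * z2
  ly <- log(y1 / y2); lw <- log(w1 / w2)
  c(-eps - 2 * ly - 2 * lw + 4 * log(z1 / z2),
    +eps + 2 * ly - 2 * lw + 4 * log(z3 / z2))
}

## Unconstrained parameterization theta = log(z1/z2), phi = log(z3/z2):
## z2 = 0.5 / (e^theta + 2 + e^phi) keeps every fraction positive.
.thetaToZ <- function(p) {
  e1 <- exp(p[1L]); e3 <- exp(p[2L])
  d <- e1 + 2 + e3
  c(z1 = 0.5 * e1 / d, z3 = 0.5 * e3 / d)
}

.g2dObj <- function(p, eps) {
  z <- .thetaToZ(p)
  .g2dValue(z[1L], z[2L], eps)
}

.g2dObjGrad <- function(p, eps) {
  z <- .thetaToZ(p)
  g <- .g2dGrad(z[1L], z[2L], eps)
  z1 <- z[1L]; z3 <- z[2L]
  ## Jacobian of (z1, z3) wrt (theta, phi)
  c(g[1L] * z1 * (1 - 2 * z1) + g[2L] * (-2 * z1 * z3),
    g[1L] * (-2 * z1 * z3) + g[2L] * z3 * (1 - 2 * z3))
}

#' Numerical 2-D equilibrium solution
#'
#' Minimizes the 2-D reduced free-energy functional over the symmetric
#' reduced parameterization \eqn{(z_1, z_2, z_3)} subject to normalization
#' (\eqn{\sum \gamma_i z_i = 1}), the pair-triplet consistency relations,
#' \eqn{x_1 = x_2 = 0.5} and the equilibrium symmetry. Positivity is
#' enforced by an unconstrained log-ratio reparameterization; BFGS with
#' analytic gradients is started from both the uniform \eqn{h = 1} point
#' and the 1-D closed-form solution, then polished with Newton steps to a
#' feasible-direction gradient norm below `gradTol`. The returned `z3` is
#' cross-checked against the analytic [equilibrium2DZ3()] value: a
#' discrepancy beyond `tol` is flagged (`"analytic_mismatch"`) and warned
#' about, never silently accepted.
#'
#' @param h interaction parameter inside the valid 2-D branch
#'   \eqn{[3^{-1/2}, 3^{1/2}]}.
#' @param tol allowed discrepancy between the numerical and analytic `z3`.
#' @param gradTol convergence threshold on the gradient norm.
#' @return an [EquilibriumSolution-class] with `method = "numeric"`.
#' @examples
#' equilibrium2DNumeric(1.2)@fractions@z[3]  # ~0.0855
#' @export
equilibrium2DNumeric <- function(h, tol = 1e-6, gradTol = 1e-9) {
  if (!is.numeric(h) || length(h) != 1L || !is.finite(h) || h <= 0) {
    stop("'h' must be a single finite value > 0")
  }
  margin <- 1e-5
  if (h < .branch2D[["lo"]] + margin || h > .branch2D[["hi"]] - margin) {
    stop(sprintf(
      "h = %.8g is outside the valid 2-D branch (%.6f, %.6f); the analytic solution leaves [0, 0.5] there",
      h, .branch2D[["lo"]], .branch2D[["hi"]]))
  }
  eps <- 4 * log(h)
  ## Multi-starts: uniform point and the 1-D closed form.
  oneD <- equilibrium1D(h)@fractions
  starts <- list(c(0, 0),
                 log(c(oneD@z[1L], oneD@z[3L]) / oneD@z[2L]))
  best <- NULL
  for (p0 in starts) {
    fit <- optim(p0, .g2dObj, .g2dObjGrad, eps = eps, method = "BFGS",
                 control = list(reltol = 1e-15, maxit = 500L))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  p <- best$par
  ## Newton polish on the analytic gradient (finite-difference Jacobian).
  for (it in seq_len(60L)) {
    g <- .g2dObjGrad(p, eps)
    if (sqrt(sum(g^2)) < 1e-13) break
    hstep <- 1e-6
    J <- matrix(0, 2L, 2L)
    for (j in 1:2) {
      dp <- p; dp[j] <- dp[j] + hstep
      J[, j] <- (.g2dObjGrad(dp, eps) - g) / hstep
    }
    step <- tryCatch(solve(J, -g), error = function(e) -g)
    if (max(abs(step)) > 1) step <- step / max(abs(step))
    p <- p + step
  }
  z <- .thetaToZ(p)
  z1 <- unname(z[1L]); z3 <- unname(z[2L])
  z2 <- (0.5 - z1 - z3) / 2
  gradNorm <- sqrt(sum(.g2dGrad(z1, z3, eps)^2))
  flags <- character(0)
  if (gradNorm > gradTol) {
    stop(sprintf(
      "2-D minimizer did not converge: gradient norm %.3g > %.3g at h = %g",
      gradNorm, gradTol, h))
  }
  z3Ref <- as.numeric(equilibrium2DZ3(h))
  if (abs(z3 - z3Ref) > tol) {
    flags <- c(flags, "analytic_mismatch")
    warning(sprintf(
      "numerical z3 = %.10f differs from the analytic value %.10f by %.3g at h = %g",
      z3, z3Ref, abs(z3 - z3Ref), h))
  }
  fr <- .symmetricFractions(z1, z2, z3, dims = 2L)
  g <- reducedFreeEnergy(fr, thermoParams(h = h), dims = 2L)
  new("EquilibriumSolution", h = h, s = h^4, fractions = fr,
      gReduced = g@gReduced, dims = 2L, method = "numeric",
      gradNorm = gradNorm, flags = flags)
}

#' Equilibrium configuration variables over a grid of h values
#'
#' Tabulates the equilibrium solution on an equally spaced `h` grid. For
#' `dims = 1` the closed form is used; for `dims = 2` the full fraction
#' set comes from the numerical minimizer inside the valid branch, and
#' rows outside it (or near the singularities) are kept with `NA`
#' fractions and a non-empty `flags` entry rather than dropped.
#'
#' @param hMin,hMax positive grid range, `hMin < hMax`.
#' @param steps number of grid points, at least 2.
#' @param dims 1 or 2.
#' @return a `data.frame` with columns `h`, `x1`, `y1..y3`, `w1..w3`,
#'   `z1..z6`, `g_reduced`, `flags`.
#' @examples
#' equilibriumCurve(0.5, 2, steps = 4, dims = 1)
#' @export
equilibriumCurve <- function(hMin, hMax, steps, dims = 1) {
  if (!is.finite(hMin) || !is.finite(hMax) || hMin <= 0 || hMin >= hMax) {
    stop("need 0 < hMin < hMax")
  }
  if (steps < 2L) {
    stop("'steps' must be at least 2")
  }
  dims <- as.integer(dims)
  hs <- seq(hMin, hMax, length.out = as.integer(steps))
  rows <- lapply(hs, function(h) {
    sol <- if (dims == 1L) {
      equilibrium1D(h)
    } else {
      tryCatch(suppressWarnings(equilibrium2DNumeric(h)),
               error = function(e) NULL)
    }
    if (is.null(sol)) {
      v <- rep(NA_real_, 14L)
      names(v) <- names(.fractionVector(c(NA, NA), rep(NA, 3), rep(NA, 3),
                                        rep(NA, 6)))
      flag <- if (any(abs(h - .sing2D) < 1e-3)) "near_singularity" else "outside_branch"
      data.frame(h = h, t(v)[, -2, drop = FALSE], g_reduced = NA_real_,
                 flags = flag, stringsAsFactors = FALSE)
    } else {
      v <- fractions(sol@fractions)
      data.frame(h = h, t(v)[, -2, drop = FALSE],
                 g_reduced = sol@gReduced,
                 flags = paste(sol@flags, collapse = ";"),
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @describeIn fractions fractions at an equilibrium solution.
#' @export
setMethod("fractions", "EquilibriumSolution",
  function(x, aggregated = FALSE) fractions(x@fractions, aggregated))

#' @describeIn gReduced value at an equilibrium solution.
#' @export
setMethod("gReduced", "EquilibriumSolution", function(x) x@gReduced)

#' @describeIn latticeDims dimensionality of an equilibrium solution.
#' @export
setMethod("latticeDims", "EquilibriumSolution", function(x) x@dims)

setMethod("show", "EquilibriumSolution", function(object) {
  cat(sprintf("EquilibriumSolution (%d-D, %s) at h = %.6g (s = h^4 = %.6g)\n",
              object@dims, object@method, object@h, object@s))
  z <- object@fractions@z
  y <- object@fractions@y
  cat(sprintf("  z1 = %.6f  z2 = %.6f  z3 = %.6f  y2 = %.6f\n",
              z[1L], z[2L], z[3L], y[2L]))
  cat(sprintf("  G_reduced = %.6f", object@gReduced))
  if (!is.na(object@gradNorm)) {
    cat(sprintf("  (gradient norm %.2g)", object@gradNorm))
  }
  cat("\n")
  if (length(object@flags)) cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})
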