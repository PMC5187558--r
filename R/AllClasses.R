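## S4 classes for lattices, configuration statistics, thermodynamic
## parameters, and results.

#' BistateLattice: a two-state lattice with wraparound conventions
#'
#' Represents a 1-D zigzag chain or a 2-D staggered grid of units in states
#' `"A"` (on) or `"B"` (off). Units are stored as a character matrix: one
#' row for a 1-D chain (the linear zigzag order; the two staggered rows of
#' the usual drawing are a rendering, not a storage concern), R rows for a
#' 2-D grid. All counting operations use periodic (envelope) wraparound, so
#' a 2-D grid must have an even number of rows for the vertical wrap to
#' close on the staggered geometry.
#'
#' @slot units character matrix of `"A"`/`"B"`; 1 row for a chain, R rows
#'   (R even) by C columns for a grid.
#' @slot dims integer, 1 or 2.
#'
#' @section Validity:
#' Every unit must be exactly `"A"` or `"B"`; a chain needs at least 3
#' units (one triplet window); a grid needs even R >= 2 and C >= 3.
#'
#' @seealso [readLattice()], [generatePattern()], [countConfigurations()]
#' @export
setClass("BistateLattice",
  representation(units = "matrix", dims = "integer"),
  validity = function(object) {
    u <- object@units
    if (!is.character(u)) {
      return("'units' must be a character matrix")
    }
    bad <- which(!(u %in% c("A", "B")))
    if (length(bad) > 0L) {
      return(sprintf("unit %d is '%s'; every unit must be 'A' or 'B'",
                     bad[1L], u[bad[1L]]))
    }
    if (!(object@dims %in% c(1L, 2L))) {
      return("'dims' must be 1 or 2")
    }
    if (object@dims == 1L) {
      if (nrow(u) != 1L) {
        return("a 1-D chain must be stored as a single row")
      }
      if (ncol(u) < 3L) {
        return("a 1-D chain needs at least 3 units (one triplet window)")
      }
    } else {
      if (nrow(u) < 2L || nrow(u) %% 2L != 0L) {
        return(sprintf(
          "a 2-D grid needs an even number of rows >= 2 for the vertical envelope wrap (got R = %d)",
          nrow(u)))
      }
      if (ncol(u) < 3L) {
        return(sprintf("a 2-D grid needs at least 3 columns (got C = %d)",
                       ncol(u)))
      }
    }
    TRUE
  }
)

#' ConfigurationCounts: raw window counts of configuration variables
#'
#' Integer counts of single units, nearest-neighbor pairs,
#' next-nearest-neighbor pairs, and triplet windows on a lattice, pooled
#' over orderings within each class (e.g. A-A-B and B-A-A both count toward
#' Z2). On a 1-D chain of N units there are N windows of each kind
#' (circular); on a 2-D grid of N units there are 2N of each (one "V" and
#' one "Lambda" window per unit).
#'
#' @slot X integer length 2: counts of A and B units.
#' @slot Y integer length 3: nearest-neighbor pair class counts.
#' @slot W integer length 3: next-nearest-neighbor (triplet end-pair) class
#'   counts.
#' @slot Z integer length 6: triplet class counts.
#' @slot nWindows named integer: window totals for `pair`, `nnn`, `triplet`.
#' @slot N integer: total number of units.
#' @slot dims integer, 1 or 2.
#' @seealso [countConfigurations()], [configFractions()]
#' @export
setClass("ConfigurationCounts",
  representation(X = "integer", Y = "integer", W = "integer", Z = "integer",
                 nWindows = "integer", N = "integer", dims = "integer"),
  validity = function(object) {
    if (length(object@X) != 2L || length(object@Y) != 3L ||
        length(object@W) != 3L || length(object@Z) != 6L) {
      return("X, Y, W, Z must have lengths 2, 3, 3, 6")
    }
    if (sum(object@X) != object@N) {
      return("X1 + X2 must equal N")
    }
    tw <- object@nWindows[["triplet"]]
    expected <- if (object@dims == 1L) object@N else 2L * object@N
    if (tw != expected) {
      return(sprintf("triplet window total must be %d (got %d)", expected, tw))
    }
    if (object@nWindows[["pair"]] != tw || object@nWindows[["nnn"]] != tw) {
      return("pair and next-nearest window totals must equal the triplet total")
    }
    if (sum(object@Y) != tw || sum(object@W) != tw || sum(object@Z) != tw) {
      return("class counts must sum to the window total")
    }
    TRUE
  }
)

#' ConfigurationFractions: normalized per-arrangement fractions
#'
#' Per-arrangement configuration-variable fractions: each class count is
#' divided by (degeneracy x window total), so the mixed classes y2, w2, z2,
#' z5 are the fraction of a *single* ordering. The normalizations
#' \eqn{x_1 + x_2 = 1}, \eqn{\sum_i \beta_i y_i = 1},
#' \eqn{\sum_i \beta_i w_i = 1}, \eqn{\sum_i \gamma_i z_i = 1} then hold.
#' Use [fractions()] with `aggregated = TRUE` for degeneracy-weighted values
#' (e.g. \eqn{\gamma_2 z_2}, the total fraction of A-A-B plus B-A-A
#' triplets).
#'
#' @slot x numeric length 2.
#' @slot y numeric length 3.
#' @slot w numeric length 3.
#' @slot z numeric length 6.
#' @slot nWindows numeric: triplet window total behind the fractions
#'   (`NA` for analytic fractions not derived from a finite lattice).
#' @slot dims integer, 1 or 2.
#' @seealso [configFractions()], [fractions()], [equilibrium1D()]
#' @export
setClass("ConfigurationFractions",
  representation(x = "numeric", y = "numeric", w = "numeric", z = "numeric",
                 nWindows = "numeric", dims = "integer"),
  validity = function(object) {
    if (length(object@x) != 2L || length(object@y) != 3L ||
        length(object@w) != 3L || length(object@z) != 6L) {
      return("x, y, w, z must have lengths 2, 3, 3, 6")
    }
    vals <- c(object@x, object@y, object@w, object@z)
    if (any(vals < -1e-12 | vals > 1 + 1e-12)) {
      return("all fractions must lie in [0, 1]")
    }
    tol <- 1e-8
    if (abs(sum(object@x) - 1) > tol) {
      return("x1 + x2 must equal 1")
    }
    if (abs(sum(.beta * object@y) - 1) > tol) {
      return("sum(beta * y) must equal 1")
    }
    if (abs(sum(.beta * object@w) - 1) > tol) {
      return("sum(beta * w) must equal 1")
    }
    if (abs(sum(.gamma * object@z) - 1) > tol) {
      return("sum(gamma * z) must equal 1")
    }
    TRUE
  }
)

#' ThermoParams: interaction enthalpy and its exponentiated parameter
#'
#' The pairwise interaction enthalpy \eqn{\varepsilon} between unlike
#' nearest neighbors (like pairs cost zero; \eqn{k_\beta T \equiv 1}) and
#' the equivalent parameter \eqn{h = e^{\varepsilon/4}}. `h = 1` means no
#' interaction; `h > 1` favors like-near-like ("ferromagnetic") patterns;
#' `h < 1` favors alternation.
#'
#' @slot eps numeric, dimensionless interaction enthalpy.
#' @slot h numeric, `exp(eps/4)`, strictly positive.
#' @seealso [thermoParams()]
#' @export
setClass("ThermoParams",
  representation(eps = "numeric", h = "numeric"),
  validity = function(object) {
    if (!is.finite(object@h) || object@h <= 0) {
      return("h must be finite and > 0")
    }
    if (abs(object@h - exp(object@eps / 4)) > 1e-9 * max(1, object@h)) {
      return("h and eps are inconsistent: h must equal exp(eps/4)")
    }
    TRUE
  }
)

#' FreeEnergyBreakdown: terms of the reduced CVM free energy
#'
#' The reduced free energy \eqn{\bar G = G/N} split into its enthalpy and
#' entropy terms, together with the residuals of the normalization and
#' consistency constraints of the input fractions. For consistent fractions
#' the residuals are zero and `gReduced = enthalpyTerm - entropyTerm`.
#'
#' @slot enthalpyTerm numeric, \eqn{\varepsilon (z_2 + z_3 + z_4 + z_5)}.
#' @slot entropyTerm numeric, the configuration-variable entropy.
#' @slot gReduced numeric.
#' @slot residuals named numeric: constraint residuals.
#' @slot dims integer, 1 or 2.
#' @slot note character: sign-convention metadata for the 2-D functional.
#' @seealso [reducedFreeEnergy()]
#' @export
setClass("FreeEnergyBreakdown",
  representation(enthalpyTerm = "numeric", entropyTerm = "numeric",
                 gReduced = "numeric", residuals = "numeric",
                 dims = "integer", note = "character"))

#' EquilibriumSolution: configuration variables at the free-energy minimum
#'
#' The full set of equilibrium configuration fractions at a given
#' interaction parameter `h`, with the derived quantity \eqn{s = h^4} and
#' the reduced free energy at the minimum. Equilibrium solutions in the
#' equiprobable case are symmetric: \eqn{y_1 = y_3}, \eqn{z_1 = z_6},
#' \eqn{z_2 = z_5}, \eqn{z_3 = z_4}, \eqn{x_1 = x_2 = 0.5}.
#'
#' @slot h numeric.
#' @slot s numeric, `h^4` (equals \eqn{z_1/z_3} at the 1-D equilibrium).
#' @slot fractions a [ConfigurationFractions-class].
#' @slot gReduced numeric.
#' @slot dims integer, 1 or 2.
#' @slot method character, `"closed_form"` or `"numeric"`.
#' @slot gradNorm numeric, feasible-direction gradient norm at the reported
#'   solution (`NA` for closed forms).
#' @slot flags character, branch/validity flags.
#' @seealso [equilibrium1D()], [equilibrium2DNumeric()]
#' @export
setClass("EquilibriumSolution",
  representation(h = "numeric", s = "numeric",
                 fractions = "ConfigurationFractions", gReduced = "numeric",
                 dims = "integer", method = "character", gradNorm = "numeric",
                 flags = "character"),
  validity = function(object) {
    fr <- object@fractions
    if (max(c(fr@y, fr@w, fr@z)) > 0.5 + 1e-9) {
      return("equilibrium fractions must lie in [0, 0.5]")
    }
    if (abs(fr@x[1L] - 0.5) > 1e-9) {
      return("equilibrium solutions are equiprobable: x1 = x2 = 0.5")
    }
    TRUE
  }
)

#' HEstimate: interaction parameter inferred from an observed lattice
#'
#' Estimates of the interaction parameter obtained by inverting the
#' equilibrium relations at the observed z1 (like triplets) and z3
#' (alternating triplets) separately. The two may differ for small or
#' out-of-equilibrium patterns; `havg` is their arithmetic mean.
#'
#' @slot h1 numeric, estimate from z1.
#' @slot h3 numeric, estimate from z3.
#' @slot havg numeric, `(h1 + h3)/2`.
#' @slot z1 numeric, observed per-arrangement z1.
#' @slot z3 numeric, observed per-arrangement z3.
#' @slot nWindows numeric, triplet window total behind the observation.
#' @slot dims integer.
#' @slot flags character (e.g. `"z1_zero"` for degenerate observations,
#'   `"non_equiprobable"` when x1 strays from 0.5).
#' @seealso [estimateH()], [invertZ1()], [invertZ3()]
#' @export
setClass("HEstimate",
  representation(h1 = "numeric", h3 = "numeric", havg = "numeric",
                 z1 = "numeric", z3 = "numeric", nWindows = "numeric",
                 dims = "integer", flags = "character"),
  validity = function(object) {
    if (object@h1 < 0 || object@h3 < 0) {
      return("h1 and h3 must be non-negative")
    }
    if (is.finite(object@h1) && is.finite(object@h3) &&
        abs(object@havg - (object@h1 + object@h3) / 2) > 1e-12) {
      return("havg must be the arithmetic mean of h1 and h3")
    }
    TRUE
  }
)
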