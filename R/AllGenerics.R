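## Generics shared across classes.

#' Number of units in a lattice-derived object
#'
#' @param x a [BistateLattice-class], [ConfigurationCounts-class], or other
#'   object carrying a unit count.
#' @return integer unit count.
#' @export
setGeneric("nUnits", function(x) standardGeneric("nUnits"))

#' Lattice dimensionality (1 or 2)
#'
#' @param x an object carrying a dimensionality.
#' @return integer, 1 or 2.
#' @export
setGeneric("latticeDims", function(x) standardGeneric("latticeDims"))

#' Extract configuration fractions as a named vector
#'
#' Returns the configuration-variable fractions of an object as a flat
#' named numeric vector `x1, x2, y1..y3, w1..w3, z1..z6`. By default the
#' per-arrangement convention is used (mixed classes divided by their
#' degeneracy); with `aggregated = TRUE` each value is multiplied by its
#' degeneracy factor, so e.g. the aggregated `z2` is the total fraction of
#' A-A-B plus B-A-A triplet windows.
#'
#' @param x a [ConfigurationFractions-class], [ConfigurationCounts-class],
#'   or [EquilibriumSolution-class].
#' @param aggregated logical; multiply by degeneracy factors.
#' @return named numeric vector of length 14.
#' @examples
#' fractions(equilibrium1D(1))
#' fractions(equilibrium1D(1), aggregated = TRUE)
#' @export
setGeneric("fractions",
           function(x, aggregated = FALSE) standardGeneric("fractions"))

#' Reduced free energy value of a result object
#'
#' @param x a [FreeEnergyBreakdown-class] or [EquilibriumSolution-class].
#' @return numeric reduced free energy \eqn{\bar G}.
#' @export
setGeneric("gReduced", function(x) standardGeneric("gReduced"))

#' Swap the two states everywhere (A <-> B)
#'
#' Relabels A as B and vice versa. For fractions this exchanges
#' `x1 <-> x2`, `y1 <-> y3`, `w1 <-> w3`, `z1 <-> z6`, `z2 <-> z5`,
#' `z3 <-> z4`; the mixed-class values `y2` and `w2` are fixed.
#'
#' @param x a [BistateLattice-class] or [ConfigurationFractions-class].
#' @return an object of the same class with states swapped.
#' @examples
#' swapStates(readLattice(text = "AABB"))
#' @export
setGeneric("swapStates", function(x) standardGeneric("swapStates"))
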