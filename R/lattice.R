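## Lattice construction, text I/O, and reference-pattern generators.

#' Construct a BistateLattice
#'
#' @param units character vector (1-D chain) or character matrix (2-D grid,
#'   row-major) of `"A"`/`"B"` labels. `"1"`/`"0"` are accepted as aliases
#'   and mapped to `"A"`/`"B"`.
#' @return a validated [BistateLattice-class].
#' @examples
#' BistateLattice(c("A", "A", "B", "B"))
#' @export
BistateLattice <- function(units) {
  if (!is.matrix(units)) {
    units <- matrix(units, nrow = 1L)
  }
  units[units == "1"] <- "A"
  units[units == "0"] <- "B"
  dims <- if (nrow(units) == 1L) 1L else 2L
  new("BistateLattice", units = units, dims = dims)
}

#' Read a bistate lattice from text
#'
#' The text format is UTF-8 lines of `A`/`B` characters (`1`/`0` accepted
#' as aliases for on/off): a single line is a 1-D zigzag chain, k > 1 lines
#' form a 2-D staggered grid with k rows. All lines must have equal length;
#' a 2-D grid must have an even number of rows (vertical envelope wrap) and
#' at least 3 columns.
#'
#' @param file path to a lattice text file.
#' @param text a character scalar holding the lattice text directly (lines
#'   separated by newlines), or a character vector of lines; used when
#'   `file` is `NULL`.
#' @return a [BistateLattice-class].
#' @examples
#' readLattice(text = "AABB")
#' readLattice(text = "ABAB\nBABA")
#' @seealso [writeLattice()]
#' @export
readLattice <- function(file = NULL, text = NULL) {
  if (is.null(file) && is.null(text)) {
    stop("supply either 'file' or 'text'")
  }
  lines <- if (!is.null(file)) {
    readLines(file, warn = FALSE)
  } else if (length(text) == 1L && grepl("\n", text, fixed = TRUE)) {
    strsplit(text, "\n", fixed = TRUE)[[1L]]
  } else {
    as.character(text)
  }
  lines <- lines[nzchar(lines) | seq_along(lines) < length(lines)]
  if (length(lines) == 0L || all(!nzchar(lines))) {
    stop("lattice text is empty")
  }
  widths <- nchar(lines)
  if (length(unique(widths)) != 1L) {
    bad <- which(widths != widths[1L])[1L]
    stop(sprintf("ragged rows: line %d has %d characters, expected %d",
                 bad, widths[bad], widths[1L]))
  }
  chars <- do.call(rbind, strsplit(lines, "", fixed = TRUE))
  ok <- chars %in% c("A", "B", "1", "0")
  if (!all(ok)) {
    bad <- which(!ok)[1L]
    r <- (bad - 1L) %% nrow(chars) + 1L
    c0 <- (bad - 1L) %/% nrow(chars) + 1L
    stop(sprintf("illegal character '%s' at line %d, column %d (allowed: A B 1 0)",
                 chars[bad], r, c0))
  }
  BistateLattice(chars)
}

#' Write a bistate lattice as text
#'
#' Inverse of [readLattice()]: the round-trip through text is byte-exact.
#'
#' @param lattice a [BistateLattice-class].
#' @param file path to write to, or `NULL` to return the text invisibly.
#' @return the lattice text (a character scalar ending in a newline),
#'   invisibly.
#' @examples
#' writeLattice(readLattice(text = "AABB"))
#' @export
writeLattice <- function(lattice, file = NULL) {
  stopifnot(is(lattice, "BistateLattice"))
  lines <- apply(lattice@units, 1L, paste0, collapse = "")
  txt <- paste0(paste(lines, collapse = "\n"), "\n")
  if (!is.null(file)) {
    writeChar(txt, file, eos = NULL)
  }
  invisible(txt)
}

## Restores the caller's RNG stream after seeded generation.
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Generate a reference 1-D pattern
#'
#' Deterministic and random generators for the reference 32-unit-style
#' chain patterns used throughout the package:
#'
#' \describe{
#'   \item{`ferro_defect`}{a circular chain of two like-domains — `size/2 - 1`
#'     A's with one B inserted at the domain midpoint, then `size/2 - 1` B's
#'     with one A likewise ("ferromagnetic-like with one inserted non-like
#'     unit in each domain"). Requires even `size >= 12` so each defect sits
#'     at least 2 positions from its domain boundaries.}
#'   \item{`equilibrium_motif`}{repeats of the 8-unit motif
#'     `A,A,A,B,A,B,B,B`, whose circular triplet census is exactly the
#'     zero-interaction equilibrium distribution. Requires `size` divisible
#'     by 8.}
#'   \item{`antiferro_defect`}{strict alternation except for exactly one A-A
#'     and one B-B adjacency, placed away from each other (an
#'     "antiferromagnetic-like" chain with one like-near-like defect of each
#'     type). Requires even `size >= 8`.}
#'   \item{`random`}{independent unit draws with P(A) = 0.5 from the given
#'     seed.}
#' }
#'
#' The three deterministic kinds have equal A and B counts (`x1 = 0.5`),
#' matching the equiprobable premise of the closed-form equilibrium theory.
#'
#' @param kind one of `"ferro_defect"`, `"equilibrium_motif"`,
#'   `"antiferro_defect"`, `"random"`.
#' @param size total unit count.
#' @param seed integer seed, used (and required) only for `kind = "random"`;
#'   the caller's RNG stream is left untouched.
#' @return a 1-D [BistateLattice-class].
#' @examples
#' generatePattern("equilibrium_motif", 32)
#' generatePattern("random", 32, seed = 1)
#' @export
generatePattern <- function(kind = c("ferro_defect", "equilibrium_motif",
                                     "antiferro_defect", "random"),
                            size, seed = NULL) {
  kind <- match.arg(kind)
  size <- as.integer(size)
  units <- switch(kind,
    ferro_defect = {
      if (size %% 2L != 0L || size < 12L) {
        stop("'ferro_defect' needs an even size >= 12 (interior defect placement)")
      }
      D <- size %/% 2L
      p <- (D + 1L) %/% 2L  # domain midpoint; counts invariant to interior placement
      domA <- rep("A", D); domA[p] <- "B"
      domB <- rep("B", D); domB[p] <- "A"
      c(domA, domB)
    },
    equilibrium_motif = {
      if (size %% 8L != 0L) {
        stop("'equilibrium_motif' needs a size divisible by 8")
      }
      rep(c("A", "A", "A", "B", "A", "B", "B", "B"), size %/% 8L)
    },
    antiferro_defect = {
      if (size %% 2L != 0L || size < 8L) {
        stop("'antiferro_defect' needs an even size >= 8")
      }
      ## Runs alternate A,B,...; one A-run and one B-run have length 2,
      ## all others length 1, so there is exactly one A-A and one B-B
      ## adjacency. The B double-run is placed half-way around the circle
      ## from the A double-run, making the B-run profile a cyclic shift of
      ## the A-run profile (the pattern is its own A<->B swap image up to
      ## rotation).
      k <- size %/% 2L - 1L
      runsA <- c(2L, rep(1L, k - 1L))
      runsB <- rep(1L, k); runsB[k %/% 2L + 1L] <- 2L
      unlist(lapply(seq_len(k), function(i) {
        c(rep("A", runsA[i]), rep("B", runsB[i]))
      }))
    },
    random = {
      if (is.null(seed)) {
        stop("'random' needs a seed")
      }
      if (size < 3L) {
        stop("a chain needs at least 3 units")
      }
      .withSeed(seed, ifelse(runif(size) < 0.5, "A", "B"))
    }
  )
  BistateLattice(units)
}

#' @describeIn nUnits total unit count of a lattice.
#' @export
setMethod("nUnits", "BistateLattice", function(x) length(x@units))

#' @describeIn latticeDims dimensionality of a lattice.
#' @export
setMethod("latticeDims", "BistateLattice", function(x) x@dims)

#' Unit labels of a lattice
#'
#' @param x a [BistateLattice-class].
#' @return for a chain, a character vector in zigzag order; for a grid, the
#'   R x C character matrix.
#' @export
latticeUnits <- function(x) {
  stopifnot(is(x, "BistateLattice"))
  if (x@dims == 1L) as.vector(x@units) else x@units
}

#' @describeIn swapStates relabel every unit.
#' @export
setMethod("swapStates", "BistateLattice", function(x) {
  u <- x@units
  u[] <- ifelse(u == "A", "B", "A")
  new("BistateLattice", units = u, dims = x@dims)
})

setMethod("show", "BistateLattice", function(object) {
  if (object@dims == 1L) {
    cat(sprintf("BistateLattice: 1-D zigzag chain, N = %d units\n",
                nUnits(object)))
  } else {
    cat(sprintf("BistateLattice: 2-D staggered grid, %d x %d (N = %d units)\n",
                nrow(object@units), ncol(object@units), nUnits(object)))
  }
  nA <- sum(object@units == "A")
  cat(sprintf("  A: %d  B: %d  (x1 = %.3f)\n", nA, nUnits(object) - nA,
              nA / nUnits(object)))
  txt <- apply(object@units, 1L, paste0, collapse = "")
  if (nchar(txt[1L]) > 60L) txt <- paste0(substr(txt, 1L, 57L), "...")
  for (line in utils::head(txt, 6L)) cat(" ", line, "\n")
  if (length(txt) > 6L) cat("  ...\n")
})
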