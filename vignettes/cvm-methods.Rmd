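---
title: "The cluster variation method on bistate zigzag lattices: models, conventions, and numerics"
author: "cvmlattice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CVM methods and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cvmlattice)
```

## Why configuration variables

The mean-field entropy of a two-state system, $-\sum_i x_i \ln x_i$,
sees only the split of units into *on* (**A**) and *off* (**B**). It
assigns the same entropy to a striped, a blocky, and a random pattern
with equal state counts. The cluster variation method (CVM) extends the
entropy with the statistics of local clusters — nearest-neighbor pairs,
next-nearest-neighbor pairs, and triplets — so that local order enters
the free energy. This package implements the bistate CVM on the two
geometries with tractable equilibrium theory: the 1-D zigzag chain and
the 2-D staggered grid (topologically a triangular lattice).

## Lattices and counting conventions

A **1-D zigzag chain** is stored as the linear sequence of its units; the
two staggered rows of the usual drawing are a rendering. Nearest
neighbors are consecutive units (the diagonal links of the drawing),
next-nearest neighbors are units two apart (the within-row links), and
triplets are three consecutive units. All windows wrap circularly, so a
chain of $N$ units has exactly $N$ windows of each kind.

A **2-D staggered grid** has $R$ rows (even, for the vertical envelope
wrap to close) of $C \ge 3$ columns. Odd-indexed rows are offset by half
a cell: unit $(r, c)$ has diagonal down-neighbors $(r+1, c)$ and
$(r+1, c+1)$ for even $r$, $(r+1, c-1)$ and $(r+1, c)$ for odd $r$, all
indices wrapped. Every adjacent row pair, traversed in zigzag order, is a
circular chain of $2C$ units; counting all $R$ row pairs gives $2N$
windows of each kind — every unit is the apex of one "V" and one
"$\Lambda$" triplet. Next-nearest-neighbor windows are defined as the end
pairs of triplet windows, which makes the pair, next-nearest, and triplet
window totals identical in both geometries.

Class counts pool orderings (A-A-B with B-A-A, etc.) and fractions are
**per-arrangement**: each class count is divided by degeneracy times
window total, with $\beta = (1,2,1)$ and $\gamma = (1,2,1,1,2,1)$. This
is the convention under which the normalizations
$\sum_i \beta_i y_i = \sum_i \gamma_i z_i = 1$ and the consistency
relations $y_2 = z_2 + z_4 = z_3 + z_5$ hold; degeneracy-weighted
("aggregated") values are available via `fractions(x, aggregated = TRUE)`.
Statements like "$z_2 = 0.250$ at equilibrium" refer to the aggregated
value $\gamma_2 z_2$; storing per-arrangement values and exposing both
reconciles the two usages without ambiguity.

## Free energy

With the interaction enthalpy $\varepsilon$ charged to unlike
nearest-neighbor pairs only (like pairs cost zero, $k_\beta T \equiv 1$)
and $Lf(p) = p\ln p - p$, the reduced free energy per unit is

$$\bar G_{1D} = \varepsilon (z_2 + z_3 + z_4 + z_5)
  - 2\sum_i \beta_i Lf(y_i) + 2\sum_i \gamma_i Lf(z_i),$$

$$\bar G_{2D} = \varepsilon (z_2 + z_3 + z_4 + z_5)
  - 2\sum_i \beta_i Lf(y_i) - \sum_i \beta_i Lf(w_i)
  + \sum_i Lf(x_i) + 2\sum_i \gamma_i Lf(z_i).$$

Two evaluation choices deserve comment.

**Lagrange terms are residuals, not parameters.** The multiplier terms
used to derive stationarity conditions play no role when *evaluating*
$\bar G$ at already-normalized fractions. `reducedFreeEnergy()` instead
verifies the normalization and consistency constraints of its input and
reports them as residuals, rejecting inconsistent fractions outright.

**The 2-D sign convention was fixed by stationarity.** The 2-D functional
admits several near-identical sign conventions for its $w$, $x$, and $z$
entropy terms, and different plausible sources disagree. We resolved the
ambiguity internally: the analytic 2-D solution $z_3(h)$ (below) must be
a stationary point of the functional. A numerical search over coefficient
conventions showed that exactly one choice satisfies this on
$h \in [0.8, 1.3]$ — the triangle-approximation (Kikuchi) entropy of the
triangular lattice,
$\bar S_{2D} = 2\sum \beta_i Lf(y_i) + \sum \beta_i Lf(w_i) - \sum Lf(x_i)
- 2\sum \gamma_i Lf(z_i)$, the form used above — reproducing the analytic
$z_3(h)$ to below $10^{-8}$, while the nearest alternative (flipping only
the triplet sign) leaves a systematic $\sim 2\%$ error. The choice is
recorded in the `note` field of every 2-D `FreeEnergyBreakdown`. The
single-site term uses coefficient 1 for each state (no degeneracy exists
for single sites); it is constant in the equiprobable case, so nothing
downstream depends on it. The per-unit scale is taken exactly as
$\bar G = G/N$, which makes the 1-D entropy at $h = 1$ equal
$2\ln 2$ per unit; the factor-of-two convention affects no fraction and
no $h$ estimate, and fidelity to the printed normalization was preferred.
Likewise the 2-D enthalpy is kept as $\varepsilon(z_2+z_3+z_4+z_5)$, the
doubling of 2-D window counts being subsumed into $\varepsilon$, so that
$h$ remains directly comparable across geometries.

## Equilibrium solutions

In the equiprobable case ($x_1 = x_2 = 0.5$) the minimum is symmetric
($y_1 = y_3$, $z_1 = z_6$, $z_2 = z_5$, $z_3 = z_4$) and has closed form.
With $h = e^{\varepsilon/4}$ and $s = h^4 = z_1/z_3$:

$$z_3 = \frac{1}{2(s+1) + 4\sqrt s} = \frac{1}{2(\sqrt s + 1)^2},
\qquad z_1 = s\, z_3,$$

with $z_2 = (0.5 - z_1 - z_3)/2$ from normalization. The quadratic
admits a $\pm$ root; the $-$ root gives $1/z_3 = 0$ at $h = 1$,
contradicting the equilibrium value $z_3 = 0.125$, so the $+$ root is
used — a fixed choice, not an option. At $h = 1$ every $z_i = 0.125$ and
$y_2 = 0.25$; as $h \to 0$, $(z_3, z_1, y_2) \to (0.5, 0, 0.5)$
(alternation); as $h \to \infty$, $z_1 \to 0.5$ and $z_3 \to 0$ while
$y_2$ stays positive at any finite $h$ — domains must still meet.

The 2-D analytic alternating-triplet fraction is

$$z_3(h) = \frac{(h^2 - 3)(h^2 + 1)}{8\,[h^4 - 6h^2 + 1]},$$

physically valid on $h \in [3^{-1/2}, 3^{1/2}]$, where it runs from 0.5
down to 0. Outside the branch the value leaves $[0, 0.5]$, and the
denominator vanishes at $h^2 = 3 \pm 2\sqrt 2$; `equilibrium2DZ3()` flags
out-of-branch evaluation and errors within $10^{-6}$ (configurable) of a
singularity, and `equilibrium2DNumeric()` refuses to extrapolate beyond
the branch rather than report unphysical fractions.

**The 2-D numerical minimizer.** No closed forms are available for the
remaining 2-D variables, so they are computed by constrained
minimization. The symmetric solution is parameterized by
$(z_1, z_2, z_3)$ with $z_2$ eliminated by normalization, and positivity
enforced by the log-ratio transform
$(\theta, \phi) = (\ln z_1/z_2, \ln z_3/z_2)$, leaving a smooth
unconstrained two-variable problem. BFGS with analytic gradients runs
from two starts — the uniform $h = 1$ point and the 1-D closed-form
solution — and Newton steps polish the result to a feasible-direction
gradient norm below $10^{-9}$ (typically $10^{-13}$). The returned $z_3$
is always cross-checked against the analytic expression: a discrepancy
beyond the tolerance is flagged and warned about, never silently
accepted. Root-finding the minimizer's $z_1(h)$ (for the 2-D $z_1$
inversion) brackets $10^{-3}$ inside the branch, where the problem is
well conditioned.

## Estimating h from an observed pattern

`estimateH()` counts the triplet windows of a lattice, forms the
per-arrangement $z_1$ and $z_3$, and inverts the equilibrium relations
separately for each:

- 1-D, from $z_3$: $\sqrt s = \sqrt{1/(2 z_3)} - 1$, $h_3 = s^{1/4}$;
- 1-D, from $z_1$: $h_1^2 = \left(2 z_1 + \sqrt{2 z_1}\right)/(1 - 2 z_1)$;
- 2-D, from $z_3$: the analytic expression is a quadratic in $u = h^2$,
  $(1 - 8z_3)u^2 + (48 z_3 - 2)u - (3 + 8z_3) = 0$, solved for the root
  with $u \in [1/3, 3]$;
- 2-D, from $z_1$: root-finding against the numerical minimizer.

The exact inversions replace the look-up-table-with-extrapolation
procedure that the closed forms make unnecessary; a table path is kept
(`method = "table"`) only for parity experiments. $h_{avg}$ is the
arithmetic mean of $h_1$ and $h_3$ — the two differ for small patterns,
which a single flipped unit moves off equilibrium. Inversion presumes the
equiprobable regime, so inputs with $x_1$ more than 0.05 (configurable)
from 0.5 are flagged or, under `strict = TRUE`, rejected. By default
$z_1$ is pooled with $z_6$ and $z_3$ with $z_4$, making the estimate
invariant under global relabeling; pooled/unpooled asymmetry is surfaced
in flags, never averaged silently. Degenerate observations ($z_1 = 0$ in
an alternation-dominated chain) yield the boundary estimate with a flag
rather than an error, so such patterns remain processable.

## Reference pattern generators

`generatePattern()` emulates the canonical 32-unit illustrations:

- **`ferro_defect`** — two like-domains of `size/2` units, each carrying
  one opposite-state defect. The defect sits at the domain midpoint: the
  triplet census ($Z_1 = 11$, $Z_3 = 1$ at size 32) is invariant to any
  interior placement at least two positions from the boundaries, and
  fixing the midpoint makes the output deterministic. Hence
  $h_{avg} = 1.97$ at size 32.
- **`equilibrium_motif`** — repeats of `AAABABBB`, whose circular census
  is exactly the equilibrium distribution, so $h_{avg} = 1$ identically.
- **`antiferro_defect`** — strict alternation except one A-A and one B-B
  adjacency, placed half a circle apart (the run-length profile of B is a
  cyclic shift of that of A, so the pattern is its own state-swap image
  up to rotation). The published antiferromagnetic illustration is shown
  only graphically, so this generator is our stated construction, not a
  certified replica of it; its estimate ($h_{avg} \approx 0.13$ at size
  32) is accordingly checked only qualitatively ($h_{avg} < 1$), and the
  published value for that figure (0.454) is not used as a test oracle.
  The same applies to the published 2-D grid illustration
  ($h_{avg} = 2.42$), whose exact cells — and the unpublished 2-D
  $z_1(h)$ form behind its $h_1$ — are not reconstructible; the package
  checks that a like-dominated 2-D grid yields $h_{avg} > 1$.
- **`random`** — i.i.d. unit draws at $P(A) = 0.5$ from a caller-supplied
  seed, leaving the global RNG stream untouched.

The deterministic generators have exactly equal state counts, matching
the equiprobable premise of the closed-form theory. What passing tests on
these patterns show is that the counting, thermodynamics, and inversion
machinery is exact under the model's assumptions; they do not show that
real neural activation maps are equiprobable, equilibrated, or
nearest-neighbor-coupled — on real data the two estimates $h_1$ and
$h_3$ can diverge substantially, and that divergence is itself a
diagnostic worth inspecting before trusting $h_{avg}$.

## Verification strategy and problem sizes

Counting is verified against an independent window-by-window enumeration
oracle written directly from the neighbor offset convention, on 200
random lattices of up to 64 units (both geometries), alongside exact
integer-level conservation and consistency identities. The 1-D closed
form is verified three ways: analytic stationarity of the free energy,
agreement with direct numerical minimization (Nelder–Mead on the reduced
parameterization, to $10^{-6}$ over $h \in [0.3, 3]$), and the
stationarity relations with a single scalar $q$ at $\lambda = 0$. The
2-D minimizer is verified against the analytic $z_3(h)$ across the
branch, and inversions by round-trips $h \to$ fractions $\to \hat h$
(identity to $10^{-9}$ in 1-D where everything is closed-form, $10^{-7}$
in 2-D through the numerical path). These sizes keep the full suite
around half a minute while exercising every code path; all scale
linearly if larger checks are wanted.

## Known limitations

- The closed-form theory covers the equiprobable case only; the
  non-equiprobable (two-parameter) equilibrium requires a computational
  treatment that is out of scope here, and `estimateH()` deliberately
  warns or refuses when $x_1$ strays from 0.5.
- The 2-D analytic expression covers $z_3$ only; the other 2-D
  equilibrium variables come from the numerical minimizer and have no
  independent published values to compare against.
- Kinetics (how a perturbed pattern relaxes), finite-temperature sweeps
  as a separate axis (temperature is subsumed into $\varepsilon$), open
  boundaries, clusters beyond triplets, and ternary states are out of
  scope.
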