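---
title: "Genotype arithmetic: bounding kinetic orders with monoid Hilbert bases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotype arithmetic: bounding kinetic orders with monoid Hilbert bases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genarith)
```

## The model

An end-product-inhibition cascade is a linear enzymatic chain
$X_1 \to X_2 \to \dots \to X_n$ in which the end product $X_n$
allosterically inhibits the first step.  In the S-system variant of
biochemical systems theory each species has one net production and one net
degradation term, each a power law:

$$
\frac{dX_1}{dt} = \alpha_1 X_n^{-g} - \beta_1 X_1^{h_1}, \qquad
\frac{dX_i}{dt} = \alpha_i X_{i-1} - \beta_i X_i^{h_i} \quad (i \ge 2).
$$

The kinetic orders $h_i$ are ordinary reaction orders; the feedback order
$g$ counts the binding sites of the regulator on its target (the largest
exponent of a rate law equals the number of reactant or regulator binding
sites, by the classical Wyman/Monod argument).  Classical power-law
analysis estimates rate constants but cannot infer $g$; this package bounds
it combinatorially and then refines the bound dynamically.

Sign convention: $g$ is stored as the non-negative structural count of
binding sites and applied with negative sign in the rate law
($X_n^{-g}$), the usual convention for inhibitory feedback.  A negative
`g` argument is read as the raw exponent, i.e. its magnitude is used.

## The combinatorial pipeline

1. **Exponent vectors.**  Each rate law is rewritten as a rational function
   with all exponents in the numerator.  Every monomial contributes an
   integer (or symbolic) exponent vector, homogenized with a trailing 1.
   For the feedback equation the factored form contributes the combined
   vector $(1, 0, \dots, 0, g, 1)$ carrying the unknown.
2. **Lattice cones.**  Per species, the vectors are sorted
   lexicographically and stacked as first original, adjacent pairwise
   differences, last original (the gene interaction matrix).  A further
   normalization cone $D$ — built from the zero monomial and the all-ones
   monomial over the homogenizing block — contributes one extra cone, which
   is what makes the divisor below $n + 1$.
3. **Dual matrices.**  Square integer matrices of size $n+1$ are drawn from
   the dual region $\{v : \langle v, c\rangle \ge 0\}$ of each cone.  The
   default mode is deterministic: shortest feasible vectors, ties broken by
   descending lexicographic order, kept while they increase rank.  A
   stochastic mode samples without replacement with Boltzmann weight
   $\exp(-\lVert v\rVert^2 / T)$ under a fixed seed.
4. **Hilbert bases.**  Each sampled matrix spans a pointed cone whose
   lattice points form a finitely generated monoid (Gordan's lemma); its
   unique minimal generating set is computed natively (see below).
5. **Genotype arithmetic.**  The monomial limit $X^{\langle b(g),
   h\rangle}$ as $X \to 0$ is finite exactly when the exponent is
   non-negative.  Applying this to $b(g) = (1, 0, \dots, 0, g, 1)$ against
   every basis element yields linear inequalities in $g$, solved exactly in
   rational arithmetic.  Both the intersection of all inequalities and the
   single summed inequality are reported; the former is always contained in
   the latter and is the default.

Because step 3 needs numeric exponents, the pipeline sweeps the integer
candidates $g = 0, \dots, g_{\max}$ (default 12), builds the geometry per
candidate, and forms the constraint system over the union of all bases.

## What the constraints can and cannot pin down

For this cascade family every basis element has non-negative inner product
structure against $b(g)$, so the inequalities are lower bounds: the
admissible range is $[0, \infty)$.  That is the honest content of the
combinatorial step — binding-site counts are non-negative integers.  The
finite prediction comes from pairing the range with dynamics: the Jacobian
of the cascade at its steady state has eigenvalues
$\lambda_k = -1 + g^{1/n} e^{i\pi(2k+1)/n}$ at the symmetric defaults, so
stability fails beyond $g^* = \sec(\pi/n)^n$ (8 for $n = 3$, about 2.07
for $n = 7$, about 1.75 for $n = 9$).  The report classifies every integer
candidate and distinguishes the largest stable one, $\hat g$.  This
matches the observation that only bounded feedback orders give stable
physiologies, and that products are not sustained in long pathways.

## The bistochastic aggregate

Each cone's basis contains "sections of the identity" (unit-vector
generators).  Their completion to a full permuted identity matrix — a step
performed manually in the original analyses, with no stated rule — is
mechanized here: sections are placed first in ascending column order, the
missing unit rows follow, also ascending.  Summing the $n + 1$ permutation
matrices (species cones plus constraint cone) and dividing by $n + 1$
yields a matrix whose rows and columns each sum to exactly 1, verified in
integer arithmetic; its entries are the genotype/phenotype ratios
(binding-site occupancy probabilities), and the rows of maximal projection
onto $b(\hat g)$ are reported with ties kept.  No claim is made that the
completed permutations coincide with the manually constructed ones; the
aggregate's bistochasticity is invariant under the choice.

## The native Hilbert-basis engine

The original workflow delegates basis computation to Normaliz.  This
package must build and test without external binaries, so it implements
the computation natively and keeps the Normaliz plain-format file
interface for cross-validation when a binary happens to be present.

A literal expanding-box enumeration — the simplest correct algorithm — is
infeasible for the 4x4 magic-square cone used as a correctness oracle (the
bound on basis coordinates allows entries up to 24 in ambient $Z^{16}$).
The engine instead computes, for the monoid $\{v : Cv \ge 0\} \cap Z^n$:

* extreme rays by double description with the combinatorial adjacency
  test;
* a basis of the saturated lattice of their span by integer Hermite normal
  form, reducing to full-dimensional coordinates;
* a pulling triangulation into simplicial subcones (recursing on faces,
  with memoization);
* the lattice points of each fundamental half-open parallelepiped via the
  Hermite transversal and exact adjugate arithmetic;
* a global irreducibility sweep ordered by the strictly positive
  functional $w = \sum_i C_i$: an element is dropped iff it is the sum of
  two nonzero monoid elements.

Pointedness is required (equivalently, $C$ has full column rank); the
minimal generating set is otherwise not unique and the function refuses
with an explicit error.  Rational generators are scaled row-wise to
primitive integer form, which leaves the cone unchanged (the rational
monoid extension).  All arithmetic uses doubles as exact integer carriers;
magnitudes stay far below $2^{53}$ at this problem scale (dimension
$\le 16$, entries below $\approx 30$).

As correctness oracles the test suite uses Birkhoff-von Neumann: the
magic-square cone of size $k$ must yield exactly the $k!$ permutation
matrices ($k = 3, 4$), every integer matrix with equal line sums $s$ must
split into $s$ permutations, and 50 random pointed cones of dimension
$\le 4$ must agree with an exhaustive enumeration oracle.  The
enumeration oracle checks reducibility with subtrahends from a three-fold
enlarged box and direct inner-product membership for the differences; a
naive single-box oracle is unsound (a reduction witness can lie outside
any fixed box even when the element itself is small).

## The synthetic world

No external data exist for this method: the cascades themselves are the
input.  Defaults are $\alpha_i = \beta_i = 1$, $h_i = 1$, which give the
all-ones steady state and make every verification transparent; the
worked examples span $n = 3, \dots, 9$ and structural $g^\star \in
\{1, \dots, 4\}$.  The property suite perturbs rates log-normally
(sd 0.3–0.4) and kinetic orders in $[0.8, 1.5]$, a realistic spread for
enzymatic chains.  What a green run establishes: internal consistency
(steady states solve the rate law, simulations converge to them, the
stability boundary matches the closed form, the constraint system
re-verifies exactly, the aggregate is exactly bistochastic).  What it does
not establish: that the admissible range is informative on its own — it is
a lower bound, and the finite prediction relies on the stability
refinement; and the pipeline consumes no observed concentrations, so
"recovery" of a known $g^\star$ means containment in the admissible range
plus correct stability classification, not data-driven estimation.

## Numerical choices

* Steady states: the S-system steady state is linear in $\log X$; the
  exact log-linear solve is default, damped Newton (tolerance $10^{-10}$,
  200 iterations) is the fallback and the independent cross-check route.
* Stability: eigenvalue real-part threshold $10^{-9}$; within tolerance is
  classified `marginal`; crossing eigenvalues with nonzero imaginary part
  give `unstable_oscillatory`, otherwise `unstable_divergent`.
* Integration: adaptive Dormand-Prince RK45 in log-concentration space
  (relative tolerance $10^{-8}$), which enforces positivity structurally.
  The cascade spectrum is $O(1)$, so a stiff implicit method is not
  needed; this replaces an external ODE dependency.
* Ordering of symbolic vectors: lexicographic after substituting the
  candidate value of $g$ (the treatment of the symbol in lexicographic
  order is otherwise undefined).
* Dual sampling: the candidate box radius is raised automatically per cone
  to cover its own entries; for large ambient dimension the enumeration is
  staged (feasible signed units first, then a sub-box over the coordinates
  coupled by multi-entry constraint rows), which is exact for the
  shortest-vector semantics because zeroing uncoupled coordinates of a
  feasible vector preserves feasibility and shortens it.

## Known limitations

* Multi-term (GMA) equations are representable in the data model but the
  builders and analysis target the single-term S-system cascade.
* The permuted-identity completion rule is this package's own
  mechanization of an unspecified manual step; divergence from the
  original matrices is expected and documented, and nothing downstream
  depends on the specific permutation beyond determinism.
* The Hilbert-basis engine targets dimension $\lesssim 10$ (ambient 16 for
  the magic-square oracle) with small entries; it is not a general-purpose
  replacement for Normaliz.
* Whether "summing the complete set of inequalities" means intersection or
  literal summation is ambiguous in the source method; both are computed,
  intersection is the default, and the intersection is provably contained
  in the summed range.
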