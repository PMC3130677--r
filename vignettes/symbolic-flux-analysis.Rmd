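---
title: "Symbolic steady-state flux analysis: model, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Symbolic steady-state flux analysis: model, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxkernel)
```

## The steady-state model

Mass conservation around each metabolite gives `dx/dt = N ν`, with **N**
the m × n stoichiometric matrix and **ν** the flux vector. At steady
state `N ν = 0`: the admissible flux space is the kernel of **N**. With
r = rank(N) and f = n − r, any choice of f *independent* fluxes whose
complementary columns still span the row space yields the exact
parameterisation

    ν = R ν_indep,

where **R** (n × f) has the f × f identity at the independent rows and
`N R = 0` holds exactly. Each row of **R** is a *flux relation*: one
dependent flux written as a rational linear combination of the
independent fluxes. Two properties make this representation more useful
to a metabolic researcher than an orthonormal (SVD) nullspace basis:

1. the coordinates are themselves fluxes, so measured exchange or
   biomass rates can be substituted directly, and
2. with a sparsity-aware pivot rule the columns of **R** stay sparse, so
   each independent flux controls an identifiable *sub-network* (the
   dependent fluxes with nonzero entries in its column) instead of the
   whole network.

Closed curated models admit only the trivial steady state; the package
implements both standard rules for opening them: appending a boundary
transport reaction for every species that participates in exactly one
reaction (`open_by_degree`), or deleting the rows of known external
species (`open_by_externals`). The two give equivalent steady-state
behaviour on the shared reactions, which the test suite verifies on
linear chains.

## Exact sparse elimination

All arithmetic is performed on exact rationals: an arbitrary-precision
signed integer type (base 2³², with schoolbook multiplication, binary
long division and Euclidean gcd) carries numerator and denominator, kept
canonical (gcd 1, positive denominator) after every operation. Nothing
is ever rounded; SBML decimal literals are converted as exact decimal
fractions ("0.1" → 1/10), never through binary floating point.

`gauss_jordan_eliminate` reduces the sparse matrix to reduced
row-echelon form (unit pivots, zeros elsewhere in pivot columns) while
recording every elementary row operation. The pivot rule is the point
where a symbolic implementation can beat a numerical one: free of
stability concerns, it can optimise for sparsity. We use the classical
Markowitz criterion — among admissible nonzero entries choose the one
minimising `(row nnz − 1) × (col nnz − 1)` — with deterministic
tie-breaking (smallest column, then row index). The elimination is fully
deterministic: identical input and options give bit-identical output.

Researcher control enters through two arguments:

* `preferred_dependent`: columns tried first, in order, as pivots;
* `forbidden_pivot_cols`: the requested independent fluxes. These are
  pivoted only when the remaining columns cannot span the row space; any
  such forced move is returned in `moved_to_dependent` (and surfaced in
  the pipeline run log), because a silently changed coordinate system
  would corrupt downstream constraint mapping.

The row-operation log can be replayed on any matrix with the same row
count (`replay_row_ops`), e.g. on columns appended later; replaying on
the identity yields the transformation matrix **T** with
`T N = echelon(N)`.

Coefficient growth is the classical risk of exact elimination. On sparse
matrices with small integer entries — the structure of genome-scale
stoichiometric matrices — growth stays negligible; the engine tracks the
largest numerator/denominator bit length (`max_bits`) and the test suite
asserts it below 256 bits on the fixture sweep (observed maxima are
single digits).

### Verification strategy

The elimination is checked against three independent routes: a naive
dense rational eliminator in C++ (no heuristics, first-nonzero pivoting,
shared scalar arithmetic only), a second naive eliminator written in
pure R, and — for the scalar arithmetic and the canonical leftmost-pivot
reduced form — external references (Python's `fractions`,
`sympy.Matrix.rref`). Because the reduced form with a *fixed* pivot set
is unique, oracle comparisons pass the engine's pivot columns to the
naive eliminator; the rank is additionally compared against the
heuristics-free leftmost-pivot run.

## The SVD cross-check

`svd_kernel` computes the dense numerical nullspace basis `V_ker`
(singular vectors whose singular values fall below the standard rank
tolerance `max(m, n) · eps · σ_max`), takes its rows at the independent
indices (`V_indep`, which must be regular — the SVD alone cannot choose
a reliable partition, so the partition always comes from the exact
elimination), and rebuilds the comparable kernel
`R_svd = V_ker V_indep⁻¹`. Two error measures are reported:

* the condition number of `V_indep` (ratio of extreme singular values),
  which governs how many digits the numerical kernel loses; and
* the maximal relative flux error
  `ε_SVD = max |r_svd − r_gje| / max |r_gje|`, with the exact kernel as
  reference. This normalisation (by the largest exact-kernel magnitude)
  is our reading of "maximal relative flux error"; it is scale-invariant
  and zero exactly when the kernels coincide.

Subspace agreement is measured by principal angles, using the
sine-based residual formula where cosines saturate (the pure-cosine
formula cannot resolve angles below ~10⁻⁸).

Sparsity comparisons quote the exact kernel's structural sparsity
against the orthonormal basis thresholded at magnitude 10⁻⁹ (an
orthonormal nullspace basis is generically dense; for f = 1 the two
necessarily share their support, which is why the sparsity-advantage
check applies to f ≥ 2).

## Constraint reduction

Measurements of independent fluxes become equality rows; irreversibility
of a dependent flux d becomes the inequality `R[d, ] ν_indep ≥ 0` (or
≤ 0). The assembled system defines a convex polyhedron over the
independent fluxes, usually with heavy redundancy. `reduce_polytope`
removes all of it exactly:

1. equalities are eliminated by substitution (exact elimination of the
   augmented system; inconsistency yields an explicit empty polytope,
   never an exception);
2. lineality directions — combinations no inequality sees — are split
   off, leaving a pointed polyhedron;
3. vertices are enumerated combinatorially: every d-subset of the
   inequality rows is solved exactly and kept if feasible; extreme rays
   come from (d−1)-subsets of the recession system;
4. facets are recovered from the generators and each is represented by
   one of the *original* inequality rows, identified through its active
   generator set (original rows are orthogonal to the lineality by
   construction, so they remain valid on the whole set); rows active on
   every generator are reported as implicit equalities.

The vertex-then-facet route mirrors standard computational-geometry
practice for redundancy removal, and the intermediate V-representation
is kept in the result because volume-scanning applications consume it
directly. We chose plain combinatorial enumeration over an incremental
double-description implementation deliberately: after the measured
equalities are substituted the dimension that remains is the number of
*unmeasured* independent fluxes (in the intended workflow a dozen or
fewer), where `choose(m, d)` exact solves are fast, trivially
deterministic, and easy to verify; an incremental method's adjacency
bookkeeping adds failure modes without changing the result. The
H/V duality property (feeding the reduced H-representation back through
the pipeline reproduces the same vertices, rays and facet count) is
tested on random systems.

`bounds_per_flux` then reads each coordinate's exact extremes off the
V-representation, widening to ±∞ along rays or lineality directions;
an infeasible polytope raises a typed infeasibility condition.

## Synthetic data

`random_network` builds matrices as a product of two sparse integer
factors, each containing an embedded identity block that extra random
entries never touch, so the rank — and hence the kernel dimension — is
exact by construction rather than asserted probabilistically. Defaults
follow the structure of curated stoichiometric models: coefficients
drawn from {−2, −1, 1, 2} (most entries of real models are ±1),
sparsity target 0.9 at the fixture scale (real genome-scale models reach
0.99; at 60 × 100 a higher target would leave too few entries to couple
the network). All randomness is R's seeded generator over integer draws
only, so fixtures are reproducible across platforms for a given R
version. `double_network` implements the block-diagonal doubling and
seeded column shuffling used to scale networks: nullity scales by the
number of copies and sparsity follows `1 − (1 − s)/copies` exactly —
both are asserted in the acceptance suite.

What the generator does *not* emulate: biological degree distributions,
compartment structure, reaction reversibility patterns, or conserved
moieties beyond those the random factors happen to create. Passing the
exactness sweep therefore certifies the algebra (elimination, kernel,
replay, enumeration) on matrices with realistic sparsity and coefficient
range, not biological plausibility of any particular model. The bundled
SBML example (`yeast_mini_synthetic.xml`) is likewise a hand-built
synthetic miniature — two compartments, central-carbon shape, one
amino-acid branch, one rational coefficient of 1/2 — intended to
exercise the full parse → open → solve → constrain path, not to stand in
for a curated reconstruction.

Three hand-solved toys (`toy_pathways`) pin the kernels of a transport
chain, a branch point, and a two-compartment glutamate/oxoglutarate-style
shuttle loop, the latter checking that a purely internal cycle flux is
recovered as an independent coordinate.

## Numerical and procedural choices

* Preprocessing order: orphan species are removed before the
  polymerization rule is applied; the rule itself is read literally
  (reactant-side entry removed, product side kept, one boundary
  transport reaction appended per species) and is idempotent.
* External species are never inferred from compartment names: they come
  from an explicit list or the SBML `boundaryCondition` flag, with the
  explicit list taking precedence.
* Exchange reactions are named `EX_<species>` and appended in species
  order, keeping column indexing reproducible.
* Relations are ordered by dependent flux in original reaction order,
  terms by independent index; rational values are reported as exact
  `p/q` strings with decimal companions.
* `substitute` from the specification surface is exported as
  `substitute_fluxes()` (the natural name collides with a base R
  primitive).
* SBML writing emits terminating decimals where exact and the `p/q`
  dialect otherwise, so write-then-parse round trips bit-exactly; the
  MatrixMarket writer uses a `rational` field with `p/q` entries.
* Degenerate inputs: rank-deficient matrices are a normal outcome, an
  all-external network yields a zero-row matrix with every reaction
  flagged, f = 0 yields empty relations ("flux = 0") and a refused SVD
  comparison, and empty constraint systems reduce to the whole kernel
  space.

## Problem sizes

The test suite runs 200 seeded fixtures up to 60 × 100 through the full
exactness and SVD-agreement checks (about half a minute), plus the
property, unit and end-to-end tests; `scripts/acceptance.R` re-derives
the headline quantities on 120 fixtures plus 20 doubling cases in a few
seconds. These sizes were chosen so the whole verification cycle stays
interactive on a laptop; the engine itself has no size-specific
constants and the scaling experiments (diagonal doubling) probe the
same code path that genome-scale matrices would take.

## Limitations

* The constraint reducer's combinatorial enumeration is exponential in
  the number of unmeasured independent fluxes; it is intended for the
  post-substitution dimensionalities of targeted flux studies, not for
  enumerating elementary flux modes of genome-scale models (explicitly
  out of scope).
* Elementary flux mode / extreme pathway analysis, FBA objectives,
  isotope-labeling dynamics and thermodynamic constraints beyond flux
  signs are out of scope.
* SBML support covers species, reactions and stoichiometry (levels 2
  and 3); kinetic laws, units, FBC bounds and annotations are ignored.
* The sub-network decomposition is defined for the sparse exact kernel
  only; dense orthonormal bases are refused by design.
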