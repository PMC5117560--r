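---
title: "Identifying conserved moieties from atom transition networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying conserved moieties from atom transition networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moietyr)
```

## The problem

A conserved moiety is a group of atoms that stays intact through every
internal reaction of a metabolic network: think of the adenine nucleotide
core shared by AMP, ADP and ATP, or the nicotinamide scaffold of NAD/NADH.
Each moiety defines a metabolite pool of constant total concentration, and
the vector counting its instances per metabolite is a nonnegative integer
vector in the left null space of the internal stoichiometric matrix
$N \in \mathbb{Z}^{m \times u}$:

$$N^{\mathsf T} l = 0, \qquad l \in \mathbb{N}_0^m .$$

Stoichiometry alone cannot single out moiety vectors among the many
nonnegative integer conservation vectors, and null-space enumeration scales
exponentially. The route implemented here instead uses per-reaction atom
mappings: if every substrate atom is mapped to a product atom of the same
element, the whole network unfolds into an *atom transition network* (ATN), a
directed multigraph with one node per metabolite atom and one edge per atom
transition. Atoms belonging to one conserved moiety follow identical paths,
so moieties fall out of ordinary graph analysis:

1. build the ATN from $N$ and the atom mappings (incidence matrix
   $A \in \{-1,0,1\}^{p\times q}$);
2. find connected components of the underlying simple undirected graph
   (edge directions are ignored: conservation is about staying together, not
   about flux direction);
3. group components into isomorphism classes — two components are isomorphic
   exactly when they contain the same number of atoms of each metabolite
   (equality of their atom conservation vectors $a_h$, the per-metabolite
   atom counts of the component);
4. merge each class into a *moiety graph* whose nodes are moiety instances
   and whose moiety vector $l_k$ is the shared $a_h$;
5. assemble the moiety matrix $L$ with one column per class and verify
   $N^{\mathsf T} L = 0$ exactly.

Every step is polynomial in $p$ and $q$, which is what makes the method
usable beyond toy networks.

## Isomorphism by counting, audited structurally

Deciding isomorphism by $a_h$ equality is a deliberate shortcut: for graphs
arising from real chemistry, components with equal per-metabolite atom
counts are forced to have identical transition structure, because each
reaction maps all atoms of a substrate molecule simultaneously. Hand-crafted
inputs can violate this. The package therefore ships a strict audit
(`verify_isomorphism_strict()`), on by default, that additionally compares
per-reaction multisets of (source metabolite, target metabolite) pairs
between each class member and its representative. A failure downgrades to a
warning naming both components rather than an error, since the shortcut is
the method's defined behaviour and the audit is a safety net.

Merging a class is implemented as "take the representative's incidence
matrix after verifying equality", which avoids the fractional intermediate
of averaging the members' identical matrices.

## Exact arithmetic

Conservation is an integer statement, so no rank or null-space decision in
the package uses a floating tolerance. `exact_rank()` computes the rational
rank by Gaussian elimination modulo several primes just below $2^{26}$ and
takes the maximum. A prime can only under-report the rank if it divides a
fixed nonzero maximal minor, so using enough primes that their product
exceeds the Hadamard bound on any minor makes the maximum provably exact,
while every intermediate product stays below $2^{53}$ and is therefore exact
in double arithmetic. Columns with fractional exchange coefficients are
scaled to integers first (column scaling cannot change rank); a
floating-point SVD rank serves only as a cross-check in the test suite.

Isotopomer totals are kept as arbitrary-precision integers (a small base-$10^7$
counter), because at genome scale the sum of $2^{n_i}$ terms leaves the exact
integer range of doubles.

## Decomposing composite conservation vectors

Atom mappings between a recurring metabolite pair (for instance O$_2$ and
water, whose two symmetric oxygen atoms map with equal chemical
plausibility) can differ between reactions. When they do, two moieties merge
into a single *composite* conservation vector. The package restores a
maximal set by solving, for each candidate $l$,

$$\min \mathbf 1^{\mathsf T} x
 \quad \text{s.t.} \quad N^{\mathsf T}x = 0,\;
 x \in \mathbb{N}_0^m,\; 0 \le x \le l,\;
 1 \le \mathbf 1^{\mathsf T}x \le \mathbf 1^{\mathsf T}l - 1,$$

and replacing $l$ by $x$ and $l - x$ until the program is infeasible for
every remaining column. Infeasibility certifies nondecomposability. The
strict inequalities of the original formulation become the integer bounds
$1$ and $\mathbf 1^{\mathsf T}l - 1$, which is exact under integrality.

Because $x$ is bounded componentwise by $l$, the feasible set is a finite
box, and the bundled solver is an exact depth-first branch-and-bound over
that box with two prunings: the partial reaction residual must remain
reconcilable by bounds on the unassigned entries, and the partial objective
must not exceed the best known. The objective does not pin $x$ down uniquely
(the dopamine network's elemental matrix famously admits an alternate
optimum for its oxygen column), so among minimum-objective solutions the
lexicographically smallest $x$ in metabolite order is returned; that makes
repeated runs byte-identical. All comparisons of decomposition results in
the tests are set-based regardless. An independent certification oracle
(`brute_force_nondecomposable()`) enumerates the entire box for small
vectors and agrees with the branch-and-bound on every tested case;
enumerating unit splits $x + y = l$ suffices because any decomposition into
positive multiples of two conservation vectors yields such a split.

Identical output columns are deduplicated in $D$ but provenance retains
multiplicity, since spanning statements concern distinct vectors. The same
machinery factorises the elemental matrix and the electron vector
($e_i$ = atomic numbers times counts minus charge; no bonding-pair
convention is subtracted, as no electron-mapping formalism exists to support
one).

## Classification

A moiety is *internal* if it is conserved even in the open network
($S^{\mathsf T} l = 0$ with $S = [N, B]$): its pool exchanges nothing with
the environment and acts as a purely regulatory "gearwheel" (the biopterin
pool BH$_4$/BH$_2$ in the dopamine fixture). Metabolites carrying an
internal moiety are secondary; a non-internal moiety confined to primary
metabolites is *transitive*, one spanning both is *integrative*.

## The packaged fixtures

`das_fixture()` reconstructs the dopamine synthesis network (11 metabolites,
4 internal reactions, 7 exchanges) with full element-and-charge-balanced
formulas and a complete atom mapping table: 57 + 58 + 26 + 35 = 176
transitions over 170 atoms. The published sources do not print the
per-molfile atom orderings or the hydrogen transition conventions of the two
hydroxylase reactions, so the fixture fixes canonical choices (the biopterin
core keeps atoms H1–H13; H14/H15 leave to the new water; the displaced ring
hydrogen becomes the new hydroxyl's hydrogen). These are fixture
conventions, not biochemical claims; they reproduce every aggregate the
analysis checks (atom and transition counts, 57 components, the seven moiety
vectors and their compositions, the isotopomer counts). Atom-level
comparisons against figures are therefore only meaningful up to relabelling.
The `oxygen_variant` argument selects which symmetric O$_2$ atom feeds water
in each hydroxylase reaction; variants where the choice differs between the
two reactions ("d", "e") produce the composite oxygen moiety and one fewer
conservation relation.

Massless species (photon-like placeholders with empty formulas) are flagged
in balance reports and excluded from ATNs; the method's definitions simply
do not apply to a species with no atoms.

## The planted-moiety generator

`planted_moiety_generator()` emulates the feature the method exploits —
groups of atoms that travel together — while keeping ground truth exact.
Moieties are tokens with sampled element compositions (default 1–6 atoms
from C/H/N/O/P/S, a realistic size range for single-moiety building blocks).
Each token starts in a private precursor metabolite; internal reactions pool
the tokens of one or two substrates and repartition them into one or two
products, so conservation and elemental balance hold by construction, and
exchange sinks open the network for a random third of the metabolites.
Defaults (4 moieties, ~10 metabolites, 8 reactions) keep each generated case
well under a second to analyse.

Two restrictions guarantee exact recovery of the planted moiety matrix up to
column permutation: at most one instance of a moiety per metabolite type
(keeping each moiety's instance graph connected), and the private precursor
rows (making planted columns pairwise distinct). What the generator does
*not* emulate: multi-instance metabolites, composite moieties from variable
mappings, large stoichiometric coefficients, and unbalanced or incomplete
mapping data. Passing recovery therefore demonstrates correctness of the
component/isomorphism/merge pipeline, not robustness to the noisy mappings
of real reconstructions — the dopamine fixtures cover multiplicity and
composite cases, and real-data robustness is outside what synthetic tests
can show.

## Numerical and design choices

* Internal reactions must have integer coefficients (atom mappings require
  whole molecules); fractional coefficients are accepted in exchange columns
  only. Input column order is preserved, with internal-before-exchange
  enforced through a recorded permutation.
* Node order in the ATN is canonical (network metabolite order, element
  order C/H/O/N then alphabetical, index ascending), so incidence matrices
  and all derived artefacts are reproducible byte for byte; determinism
  comes from ordering, not from the component algorithm.
* Repeated-metabolite instances within a reaction share atom nodes: the
  incidence matrix has one row per atom of the network, and instance
  bookkeeping lives in the mapping table.
* Self-transitions (an atom of a species written on both reaction sides) are
  retained in the transition list as flagged zero columns of $A$ and dropped
  from the simple graph.
* Charge is a metabolite attribute, never a pseudo-element; it enters only
  balance reports and electron counts.
* Moiety naming (`M01`, `M02`, ...) follows class order: descending atoms
  per instance, then lexicographic comparison of moiety vectors. Column
  order of $L$ is a convention; comparisons in the acceptance checks are
  permutation-invariant.

## Problem sizes

The shipped analyses are deliberately desk-scale: the dopamine network (170
atoms, 176 transitions) and generated networks of ~10 metabolites complete
in milliseconds, and the full test suite — including 50 generator seeds and
the exhaustive decomposition oracle up to $\mathbf 1^{\mathsf T} l = 20$ —
runs in well under a minute. Genome-scale analyses from the literature
(thousands of reactions, externally predicted mappings) require inputs that
cannot be bundled; the property suites above stand in for them.

## Known limitations

* One mapping per internal reaction: alternative atom mappings are separate
  `atom_mapping_set`s, and composite moieties arising from mapping
  variability are handled downstream by decomposition rather than by
  enumerating alternatives.
* The RXN/MOL reader covers V2000 with explicit hydrogens; V3000,
  stereochemistry and reaction-centre flags are out of scope.
* The brute-force oracle is exponential by design and capped (default
  $\mathbf 1^{\mathsf T} l \le 64$); it certifies the exact solver on small
  instances only.
* Enumerating *all* nondecomposable nonnegative integer vectors of a
  stoichiometric matrix is a different (and much harder) problem than
  decomposing a given set of columns, and is not attempted.
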