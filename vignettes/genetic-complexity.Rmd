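---
title: "Genetic complexity of genotype-to-phenotype maps: methods and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genetic complexity of genotype-to-phenotype maps: methods and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gpmcomplexity)
```

## The quantity being computed

A genotype-to-phenotype map (GPM) assigns to every genotype in a defined
library the phenotype(s) observed for it.  `gpmcomplexity` quantifies the
*genetic complexity* of such a map as the normalized surplus of genotypic
over phenotypic diversity,

$$ C \;=\; \frac{m^{n} - p}{p - 1}, $$

where

* $n$ is the number of *phenotypically informative* loci — loci carrying at
  least two alleles that are not interchangeable in every genetic
  background present in the library;
* $m$ is the geometric mean number of phenotypically unique alleles per
  informative locus, so $m^n$ is the genotypic diversity of the library
  (for libraries that are not Cartesian products of allele sets, the
  library cardinality $|G|$ takes its place);
* $p$ is the number of measurably distinct phenotypes produced across the
  whole library.  A genotype observed with several phenotypes (biological
  stochasticity, repeated measurement) contributes each of them.

$C = 0$ exactly when the map is injective ($p = m^n$); it is negative when
phenotypes outnumber genotypes.  The $(p-1)$ denominator is a
normalization that stops $C$ from growing linearly with system size; it
makes $C$ undefined at $p = 1$, so a single-phenotype library raises an
error rather than returning an infinity the theory never uses.

All counts are integers and $C$ is a ratio of integers; double-precision
arithmetic is exact for every library this package can enumerate (all
counts are far below $2^{53}$), so no rational-arithmetic layer is needed.

### Allele equivalence

Whether two alleles at a locus are "phenotypically unique" is decided by
an exhaustive swap test: they are equivalent iff in every shared genetic
background present in the table they produce identical phenotype sets.
Equivalence classes are connected components of the pairwise relation
(single linkage).  Two consequences of this choice are worth noting:

* alleles that never co-occur with a shared background cannot be shown
  interchangeable and are kept distinct — a conservative default for
  sparse (non-Mendelian) tables;
* on full Cartesian ("Mendelian") libraries the pairwise relation is
  transitive, so the component construction changes nothing.

For Boolean-network topology-class libraries the swap test is provably
unnecessary — any two distinct update columns are distinguished by some
background (see below) — so `gpm_complexity(assume_unique_alleles = TRUE)`
and the census path both take $m^n = |G|$ there.

### Continuous phenotypes

`discretize_phenotypes()` is a deliberately minimal hook for continuous
measurements: one-dimensional single linkage, merging measurements
connected by gaps strictly smaller than a user-chosen `resolution`, with
the cluster count serving as $p$.  It is a documented stand-in, not a
calibrated measurement model: it has no outlier policy and no noise
model, and any serious application should substitute an estimator of $p$
suited to its assay.  The `resolution` parameter is in the measurement's
own units and has no default for that reason.

## Boolean-network libraries

The model systems in which $C$ can be computed exactly are synchronous
Boolean networks.  A *genotype* of an order-$n$ network assigns each node
an *allele*: an update column of $2^n$ bits, one output per network
state.  All nodes update simultaneously, so a genotype induces a
deterministic map on the $2^n$ states, and every trajectory ends in an
attractor — a fixed point or a periodic cycle.  The attractor reached is
the phenotype.

States are encoded little-endian (node 1 is bit 0); file formats write
binary state strings node-1-first, and the reader/writer pair keeps the
two conventions consistent.

Edges are defined by *essential dependence*: node $j$ feeds node $i$ iff
flipping bit $j$ changes node $i$'s output in at least one state.  A
*topology class* is all genotypes of an order with exactly one edge set,
so each node's allele ranges over the Boolean functions of its input set
that depend essentially on every input.  The number of such functions is
computed by inclusion–exclusion (2, 2, 10, 218 for in-degree 0–3) and is
cross-checked in the tests against direct enumeration.

Two constructive facts shape the library code and are exercised as
property tests:

* **column flips stay in class** — complementing a node's whole column
  reverses its dependencies but removes none, so `flip_column()` is an
  in-class involution;
* **fixed-point completeness** — flipping exactly the columns whose bits
  differ between a state and its image pins that state as a fixed point,
  so every class realizes every state as a fixed-point attractor
  (`realize_fixed_point()`).  This also yields allele uniqueness: two
  differing columns disagree at some state, and a background fixing that
  state separates them.

### Attractor identity

Attractors are pooled across an entire library and de-duplicated by their
**exact canonical cyclic state sequence**: the cycle rotated so its
minimal state code comes first, successor order preserved.  Fixed points
are therefore identified by their single state.

This convention is a genuine design choice.  It reproduces the reference
complexities of the acyclic-dominated 3-node classes (for example
`111 000 000` → 78.1818 and `011 001 000` → 4.57143) and the cell-cycle
results below, but for several loop-containing classes it counts *more*
periodic attractors than the published values imply — e.g. the
three-self-loop class `100 100 100`, where any negation self-allele
yields period-2 cycles that this convention counts individually.  No
attractor-identity rule we tried reconciles all published class values
simultaneously, so the package does not silently force agreement:
`class_census_report()` prints this census *and* the reference value with
an explicit `agrees` flag, and the test suite asserts that the
discrepancy is surfaced, not hidden.

### Census algorithms and problem sizes

Small libraries (topology classes, random libraries, full order ≤ 2) are
censused in vectorized R: transition tables stacked in a matrix, brought
onto their attractors by map-composition doubling ($n$ compositions reach
$2^n$ steps, beyond any transient), and cycles read off with the one-step
table.  The exhaustive censuses — the full order-3 library (16,777,216
genotypes × 8 states, also split by edge count for the size analysis) and
threshold-allele libraries ($3^{11}$ genotypes × 2048 states for the
cell-cycle network) — run in C++: per-genotype transition tables are
assembled incrementally along a depth-first walk over the nodes, and
attractors are found by the standard functional-graph walk that visits
each state once per genotype.  A full cell-cycle library census takes on
the order of a second; the complete 29-edge deletion scan about half a
minute; the order-3 size censuses a few seconds.  Enumeration caps
(default $10^8$ genotype–state pairs, override via
`options(gpmcomplexity.max_pairs = )`) guard against accidentally
intractable requests, and the error reports the computed $|G|$.

Cross-checks pin both engines to independent oracles: a naive
step-by-step walker on random genotypes, and a closed form for the full
order-$n$ library, whose census must realize every fixed state and every
cyclic arrangement of distinct states, $p = \sum_k \binom{2^n}{k}(k-1)!$
— 3, 24 and 16,072 for orders 1–3, which the measured censuses match
exactly.

## Threshold networks and the cell-cycle fixture

The yeast cell-cycle network (CCN) is specified in the threshold
formalism: signed unit arrows $a_{ij} \in \{+1, -1, 0\}$, with node $i$
switching on when $\sum_j a_{ij} S_j > 0$, off when negative, and on a
tie holding its state — unless flagged *self-degrading*, in which case it
switches off.  Self-influence is expressed only through that flag; the
constructor rejects signed diagonal entries.  Conversion to a truth table
evaluates the rule over all $2^n$ states and inverts the self-edge
convention: a self-degrading node has no truth-table self-edge, while a
non-self-degrading node's hold rule makes it depend on itself.

The packaged fixture (`ccn()`, read from two TSVs under `inst/extdata/`)
is a reconstruction of the published 11-node diagram: 15 positive and 14
negative arrows with 5 self-degrading nodes.  The reconstruction is
validated against two independent printed anchors — the 29-arrow total
and the full column of truth-table out-degrees (e.g. Clb1,2 → 8,
Mcm1/SFF → 3) — both asserted in the test suite, and the G1 state
(Sic1 and Cdh1 on) is checked to be a steady state.

Each node admits three alleles — wild-type rule, null (always off),
constitutively active (always on) — giving a library of $3^{11} =
177{,}147$ genotypes.  Null/constitutive assignments matching any state
update every state to it, so all $2^{11}$ fixed attractors are
guaranteed; complexity is then maximal iff no periodic attractor occurs,
which is exactly what the census finds for the wild network
($p = 2048$, $C = 85.54$).

## Perturbation scans

All three scans hold the self-degradation flags fixed and census the full
$3^{11}$ library of each perturbed network; because the fixed attractors
are guaranteed, $\Delta C < 0$ iff the perturbation admits more periodic
attractors.

* **Deletion** removes each signed arrow in turn (29 censuses).
* **Addition** considers every ordered node pair not already carrying an
  arrow of either sign, with both signs — self-arrows are excluded
  because self-influence lives in the self-degradation flag, giving
  $2 \times (110 - 29) = 162$ candidates — and reports the elementary
  cycles each new arrow would close, by length.  Censusing all 162
  candidates is supported but slow relative to the rest of the suite, so
  the scan takes a `census` switch and an optional candidate subset.
* **Input reassignment** for a node redistributes its multiset of signed
  incoming arrows over distinct sources among the other ten nodes,
  excluding the wild-type configuration; arrows of equal sign are
  interchangeable.  A node with one arrow has 9 reassignments, one with
  a (+, −) pair has $10 \times 9 - 1 = 89$.  This definition was pinned
  from several readings of "all possible reassignments of its inputs" as
  the only one that holds the in-degree and sign composition — i.e. all
  other features of the network — fixed.  It is a reconstruction: the
  published per-node mean periodic-attractor counts are not asserted as
  tests, although the pinned definition lands close for the small nodes
  we spot-checked (e.g. mean ≈ 3.1 for the Cln1,2 node against a
  published 3).

Loop analytics use a hand-written anchored depth-first enumeration of
elementary directed cycles (self-loops included), cross-checked against
brute-force permutation search on all 3-node and sampled 4-node digraphs;
no installed package exposes simple-cycle enumeration.

## Synthetic libraries and what the tests do and do not show

`random_library()` draws distinct genotypes uniformly from the full
truth-table space of a given order under a caller-supplied seed.  It
exists to exercise engine invariants (basin partitions, edge-derivation
oracles, census stability under batching and iteration order) on
unstructured inputs.  Uniform random truth tables are *not* a model of
biological regulatory networks — real networks are sparse, canalyzing and
degree-heterogeneous — so passing these property tests says the engine is
correct, not that any biological conclusion transfers.  The biological
content of the package lives in the exhaustive, deterministic censuses,
which involve no sampling at all.

Problem sizes in the shipped test suite were chosen to keep a full run
around two minutes: exhaustive enumeration wherever the object is small
(all 512 order-3 classes for fixed-point completeness, all 84 order-3
size-3 classes for the in-degree-variance comparison, the full order-3
and cell-cycle censuses, the complete 29-deletion scan) and seeded
sampling only for property tests over unstructured random genotypes.

## Known limitations

* The periodic-attractor identity convention does not reproduce every
  published class value (see above); reports always carry the convention
  tag so censuses remain comparable.
* Exhaustive full-order censuses stop at order 3; topology-class
  censuses are bounded by the genotype–state cap rather than order.
* Only synchronous, deterministic updates and unit threshold weights are
  modeled; asynchronous schemes and weighted arrows are out of scope.
* Frequency-weighted (stochastic-rate) phenotypes are not modeled: a
  genotype's observation set is a set, not a distribution.
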