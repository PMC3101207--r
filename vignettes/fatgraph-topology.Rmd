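---
title: "Fatgraph models of protein domains: methods and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fatgraph models of protein domains: methods and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fatsurf)
```

## The model

`fatsurf` describes a protein domain not by its coordinates but by the
topology of a surface built from them. The basic unit is the planar peptide
group between consecutive residues. Each unit becomes a *building block*
(a fatgraph vertex) with two stubs, one for a carbonyl oxygen and one for an
amide hydrogen; consecutive blocks are joined by *alpha-carbon linkages*
and hydrogen-bonded blocks by bond edges. A cyclic ordering of the edge
ends around every block plus a twist bit on every edge turn the graph into
a *fatgraph*; thickening each edge into a strip (half-turn glued when
twisted) yields a compact surface with boundary whose invariants summarize
the fold:

* Euler characteristic $\chi = V - E$; for one unbroken chain $\chi = 1 - H$
  with $H$ the number of hydrogen bonds.
* Boundary components $r \ge 1$, counted by walking the strip margins.
* Orientability: fails iff some cycle carries an odd number of twists.
* Modified genus $\tilde g = (2 - r - \chi)/2$: the classical genus when the
  surface is orientable, half the crosscap number when it is not, so the
  Euler relation holds uniformly.

The model assumes peptide-bond planarity (deviations are only warned about,
threshold 0.5 Å out-of-plane) and uses backbone atoms exclusively; side
chains, sulphur bridges and bifurcated hydrogen bonds are outside the model.

## Geometric conventions

**Frames.** Each unit carries a right-handed orthonormal frame: $e_1$ along
the peptide bond C$\to$N, $e_2$ the in-plane component of C$\to$O orthogonal
to $e_1$, $e_3 = e_1 \times e_2$. Any frame rigidly attached to the planar
unit produces an equivalent model; this rule is fixed once and validated by
the secondary-structure flip patterns below.

**Twists.** An edge joining units $a, b$ is twisted iff
$s = \langle e_2^a, e_2^b\rangle + \langle e_3^a, e_3^b\rangle < 0$:
identical frames give $s = 2$ (untwisted), an upside-down frame $s = -2$
(twisted). The measure-zero tie $s = 0$ counts as untwisted, because small
orientation changes must give untwisted edges and untwisted is the basin
around the identity. With canonical dihedrals the rule reproduces the
expected annotations exactly: helical backbones ($\varphi,\psi$ near
$-57^\circ, -47^\circ$) give all-U flip sequences, extended strands all-T.

**Stub indexing.** Block $k$ (the unit spanning residues $k, k{+}1$) offers
the carbonyl O of residue $k$ on its O-stub and the amide H *of residue
$k$* on its H-stub. Attaching the hydrogen by residue rather than by
physical plane makes helical hydrogen bonds span exactly 4 blocks
($3_{10}$: 3; $\pi$: 5), matching the classical residue bookkeeping
$\mathrm{NH}(i{+}4)\!\to\!\mathrm{O}(i)$; plane-wise attachment would yield
spans 3/2/4 and break the idealized-motif fixtures. The first residue of a
segment has no placeable amide hydrogen, so the first block never donates.

**Rotation order.** The cyclic order of attachment sites around a block is
(backbone-in, O-stub, backbone-out, H-stub): the two stubs leave on
*opposite* sides of the backbone, as the C=O and N–H groups do in a planar
peptide unit. This was a genuinely open design point; enumerating all six
cyclic orders shows this one (up to mirror) is the only convention that
simultaneously reproduces the worked example (sphere, $r = 2$) and the
idealized-motif structure (helix of genus 0 with $r = 1 + H$; every
interior boundary of helices and sheets passing through exactly 4 units).
Conventions with both stubs on the same side give a long helix genus
$\approx n/2$, which is qualitatively wrong. A consequence worth noting:
swapping the donor/acceptor role of a *single* bond moves its ends to the
opposite side and may change the surface, while reversing *all* bonds
mirrors the rotation system and preserves every invariant; the test suite
asserts exactly the invariances that hold.

## Hydrogen bonds

Bond energies follow the Kabsch–Sander electrostatic model,
$E = 0.084 \cdot 332 \,(1/r_{ON} + 1/r_{CH} - 1/r_{OH} - 1/r_{CN})$
kcal/mol, with missing amide hydrogens placed 1.0 Å from N opposite the
preceding carbonyl O$\to$C direction and any inter-atomic distance below
0.5 Å treated as a clash (energy $+\infty$). A bond requires
$E < $ `cutoff`; the default $-0.5$ kcal/mol is the standard DSSP value and
is a first-class parameter everywhere (CLI `--cutoff`), since the derived
variables should be — and empirically are — insensitive to it. Self pairs
and immediate neighbours ($|i-j| \le 1$) are excluded; such contacts
duplicate the backbone edge. The model is bifurcation-free: after
thresholding, every H-stub and O-stub keeps only its lowest-energy bond,
ties broken by smaller $|i-j|$, then lower acceptor index (the selection
rule is a package decision; alternatives differ only on ties). Bonds can
also be read from classic-format DSSP files, with the same cutoff,
de-duplication and uniqueness rules applied after parsing.

Chain breaks (consecutive C$\alpha$ further apart than 4.5 Å, or
non-consecutive residue numbers) split the chain into segments; the
fatgraph is their disjoint union. $\chi$, $H$, $t$ and $r$ add over
components and orientability is the conjunction; $\tilde g$ is recomputed
from the summed $\chi$ and $r$ (with $2c$ replacing 2 for $c$ components).
Since $r$ is not comparable across different segment counts, summaries
carry the segment count explicitly.

## Counting boundary components

The traversal works on states (half-edge, side): crossing an edge moves to
the opposite half-edge, flipping the side exactly when the edge is twisted;
at a block the walk advances to the rotation successor or predecessor of
the arrival half-edge according to the current side. Every state lies on
exactly one cycle, each boundary circle is traced once per direction, and
the two mirror cycles of a circle are identified by their common set of
undirected edge-side arcs, so $r$ = cycles/2. Blocks with no incident
edges are disks and add one component each. Unbonded stubs are dropped: a
dangling strip is contractible and changes no invariant.

The suite cross-checks this traversal against an entirely independent
oracle that builds the surface as an explicit polygonal complex (one
$2d$-gon per degree-$d$ block, one rectangle per edge, twisted rectangles
glued with a flip), identifies vertices by union-find and counts free-side
cycles. The two agree on every random fatgraph tried (hundreds per run,
up to 12 blocks and 8 bonds).

$\tilde g$ is stored internally as the exact integer $2\tilde g$ to avoid
floating-point equality issues with half-integers; negative $2\tilde g$, or
an odd $2\tilde g$ on an orientable surface, is an internal-consistency
error by construction.

## Robustness

The four basic modifications — linkage-twist toggle, bond-twist toggle,
untwisted-bond insertion/removal, and block split/merge (bonds stay with
the N-ward replacement; a merged block must be bond-free with an untwisted
left linkage) — generate all fatgraphs, and the suite verifies by
breadth-first search that every 3–4-block fatgraph with at most one bond is
reached from a 3-chain within six steps. Per single modification the
deviations are bounded: $|\Delta L|, |\Delta t|, |\Delta\chi|, |\Delta r|
\le 1$ and $|\Delta 2\tilde g| \le 2$; `robustness_probe()` measures the
maxima empirically over seeded random modification sequences (1000+ trials
per run) and $k$-step sequences stay within $k$ times the per-step
constants. The coordinate-level analogue, `jitter_structure()`, perturbs
every atom with Gaussian noise: 0.05 Å leaves the ideal-helix fatgraph
bit-identical (twist margins are wide), while 0.5 Å may change the bond
set, with $|\Delta r|$ bounded by the modification count separating the two
fatgraphs.

## Flip-sequence classification

Similarity between flip sequences is the Smith–Waterman local-alignment
score with linear gaps; defaults match $+1$, mismatch $-1$, gap $-1$ — the
simplest scheme for a two-letter alphabet, all configurable. Scores are
normalized as $S(a,b)/\sqrt{S(a,a)S(b,b)}$, which is 1 on self, symmetric,
and lies in $[0,1]$ under match-maximal scoring regardless of lengths. The
similarity of a domain to a level is the maximum normalized score over the
level's members (nearest-member rule); the margin $x = s_1 - s_2$ between
the nearest and second-nearest levels, z-standardized over a training set,
gives the $\Lambda$-score. The decision threshold is the largest value
keeping at least the target fraction (default 95%) of correctly-assigned
training domains above it; the degenerate target 0 is clamped so the
threshold stays finite (no maximal threshold exists for a vacuous
constraint). Methods are combined by majority rule, the highest-$\Lambda$
method deciding three-way disagreements, with ties broken by fixed method
order. Amino-acid mode takes any substitution matrix shipped with
Biostrings by name (BLOSUM45–100, PAM30–250) or a matrix file in the
standard NCBI layout.

The in-package Smith–Waterman implementation is verified two ways: against
an exhaustive enumeration oracle (a local alignment under linear gaps is
determined by its matched index pairs, so all pair sets are enumerable for
short strings — the suite sweeps every flip-string pair up to length 6) and
against `Biostrings::pairwiseAlignment` on random longer sequences.

## What the generators emulate — and what they do not

`make_helix_fatgraph()` and `make_sheet_fatgraph()` are *combinatorial*
idealizations: uniform bond spans, untwisted helix ladders, twisted
antiparallel rungs (neighbouring antiparallel strands run in opposite
directions, flipping the frames) and untwisted parallel rungs, with the
rung donor direction alternating along the ladder (a deterministic greedy
flip resolves stub collisions for odd strand lengths). They capture the
boundary structure of real motifs — interior components through exactly
four units, $r$ growing with motif size, marginal genus — but not
end effects ("interior" deliberately excludes components touching the
first or last block), coordinate noise, or irregular bonding.
`make_ideal_helix_pdb()` is geometric but noiseless and alanine-only;
`random_fatgraph()` samples graphs far outside the protein-realizable set,
which is exactly what makes it useful for property testing. Passing tests
on these fixtures validates the combinatorial and geometric machinery, not
the statistical behaviour of the variables on experimental structures.

## Problem sizes and determinism

Default verification sizes: identity sweeps on 1000 random fatgraphs
($\le 12$ blocks, $\le 8$ bonds), traversal-oracle agreement on 200+,
robustness on 1000+ single-modification trials, the full length-$\le 6$
alignment sweep (8001 pairs), and 20-residue ideal-helix geometry. All
stochastic fixtures take explicit seeds and preserve the caller's RNG
state; every generator is deterministic given its seed and parameters.

## Known limitations

* One twist grade only; graded or continuous twists are not modelled.
* No torsion-angle secondary-structure assignment; the flip sequence is the
  only annotation.
* mmCIF input, sulphur bridges and bifurcating bonds are out of scope.
* $r$ comparisons are only meaningful between domains with equal segment
  counts; summaries flag multi-segment domains rather than hiding them.
* The classification layer is a scoring framework; no claims are made here
  about large-scale database performance, which depends on training data
  the package does not ship.
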