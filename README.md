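# fatsurf

Fatgraph (ribbon-graph) models of protein domain topology in R.

## The idea

A protein domain can be abstracted into a *fatgraph*: a graph whose vertices
are the planar peptide units of the backbone, whose edges are the
alpha-carbon linkages between consecutive units and the backbone hydrogen
bonds, with a cyclic ordering of edge-ends at every vertex and a *twist* bit
on every edge. Thickening every edge into a strip (twisted strips glued with
a half-turn, as in a Möbius band) produces a compact 2-dimensional surface
with boundary. Classical surface topology then summarizes the fold in a few
integers:

- χ = V − E, the Euler characteristic; for a single unbroken chain with H
  hydrogen bonds, χ = 1 − H,
- r, the number of boundary components, counted by traversing the strip
  margins,
- orientability, which fails exactly when some cycle carries an odd number
  of twisted edges (a single twisted hydrogen bond can introduce a Möbius
  band),
- g̃, the modified genus: the classical genus for orientable surfaces, half
  the crosscap number otherwise, so that χ = 2 − 2g̃ − r holds uniformly.

Twists are assigned from geometry: each peptide unit carries a right-handed
orthonormal frame (peptide-bond direction, in-plane oxygen-ward axis, plane
normal), and an edge between units a and b is twisted iff
⟨e2ᵃ, e2ᵇ⟩ + ⟨e3ᵃ, e3ᵇ⟩ < 0. Reading the linkage twists along the backbone
gives the *flip sequence*, a U/T string that acts as a fatgraph-native
secondary-structure annotation: helices read `UUU…`, strands `TTT…`.

Hydrogen bonds are inferred with the Kabsch–Sander electrostatic model
(E = 0.084·332·(1/r_ON + 1/r_CH − 1/r_OH − 1/r_CN) kcal/mol, bond iff
E < −0.5 by default) or read from classic-format DSSP files.

On top of the invariants the package provides the four basic fatgraph
modifications (twist toggles, untwisted-bond insertion/removal, block
split/merge) with an empirical robustness probe — (L, t, r, g̃) change at
most linearly in the number of modifications — and Smith–Waterman
flip-sequence similarity with normalized scores, nearest-level
classification, Λ-score standardization, sensitivity-calibrated thresholds
and majority-rule combination of methods.

## Worked example

```r
library(fatsurf)

# the minimal worked example: 4 peptide units, linkages U,T,T and one
# untwisted hydrogen bond from the H-stub of the first unit to the O-stub
# of the last
g <- make_example_fatgraph()
invariant_summary(g = g)
#> L=5 H=1 t=2 chi=0 r=2 gtilde=0 orientable=yes
```

The two twists cancel: the surface is a sphere with two discs removed
(χ = 0, r = 2, g̃ = 0, orientable), and the backbone reads `UTT`.

From atomic coordinates:

```r
make_ideal_helix_pdb(20, "helix.pdb")      # canonical alpha-helix backbone
chain <- read_pdb_backbone("helix.pdb")
bonds <- infer_hydrogen_bonds(chain)       # all bonds span 4 units
labels <- label_all_edges(chain, bonds)
flip_sequence(chain, labels)
#> [1] "UUUUUUUUUUUUUUUUUU"
g <- build_fatgraph(chain, labels)
invariant_summary(chain, g)
#> L=20 H=15 t=0 chi=-14 r=16 gtilde=0 orientable=yes
```

A long helix is a genus-zero surface whose boundary-component count grows
linearly with length (r = 1 + H), every interior boundary passing through
exactly four peptide units.

The same pipeline is available from a shell:

```sh
fatsurf compute helix.pdb                # TSV: domain_id L H t chi r gtilde orientable flips
fatsurf fixtures sheet --strands 3 --len 6
fatsurf robustness --blocks 10 --bonds 4 --trials 200 --seed 1
fatsurf classify --train flips.fasta --labels labels.tsv --query q.fasta
```

(the script installs under `exec/fatsurf` in the package directory;
`system.file("exec", "fatsurf", package = "fatsurf")` locates it.)

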