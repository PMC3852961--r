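# memorient

Position alpha-helical and beta-barrel membrane proteins in an implicit
lipid bilayer with a knowledge-based statistical potential, estimate the
hydrophobic thickness of the membrane around them, and use the same
potential to score and rank model ensembles for refinement and decoy
discrimination.

## Who this is for

Structural bioinformaticians who need membrane placements for crystal
structures or models at scale — as a preprocessing step for molecular
dynamics, for studying protein–lipid interactions, or inside folding and
refinement pipelines where thousands of orientation evaluations per second
matter. Everything runs offline; a synthetic structure generator stands in
for a curated oriented-structure database so the entire pipeline is testable
from a clean checkout.

## The model

The membrane is an infinite slab 48 Å thick, divided along the membrane
normal (z) into 32 slices of 1.5 Å — roughly the rise per residue of a
transmembrane helix — with z = 0 at the bilayer centre and the cytoplasm at
negative z. From a training set of structures pre-oriented in this frame,
the frequency of each residue type's scoring centre (the Cβ atom; Cα for
glycine) is counted per slice, with a pseudocount of one added to empty
cells. The pseudo-energy of residue type *a* at depth *z* is the log-odds

    E_a(z) = -ln( f_a(z) / f(z) )

where *f_a(z)* is the relative frequency of type *a* at depth *z* and *f(z)*
the relative frequency of all residues there. A structure's energy is the
sum of E over its residues; residues outside the slab contribute zero.

Orientation is a rigid-body minimisation over three parameters — rotation
about x, rotation about y, translation along z — by a genetic algorithm
(population 10 000, five independent runs, best pose reported), a
Hooke–Jeeves direct pattern search seeded from a coarse deterministic probe,
or an exhaustive grid search at 1° / 0.5 Å. Membrane thickness is estimated
by translating the two lipid head-group windows of the potential
(10 ≤ |z| ≤ 20 Å) independently along z and reporting
30 Å + both outward offsets at the energy optimum. For model ranking, the
membrane term can be combined with an external constraint energy as
`E_total = E_contact + w · E_membrane` with `w` = 1.6 by default.

## Worked example

```r
library(memorient)

# a synthetic stand-in for a curated, pre-oriented training database:
# 183 bundles of 8 helices x 51 residues with realistic depth-dependent
# residue composition
ts  <- sample_training_set(seed = 3)
pot <- train_potential(ts$manifest)
pot
#> <mem_potential kind=alpha  20 x 32  (slab 48 A, slice 1.5 A)>

# a held-out 16-helix complex built at tilt 20 deg, z-offset 4 A
set.seed(99)
b <- build_bundle(tilt = 20, z_offset = 4, n_helices = 16, id = "target")

# orient it: the input pose is first scrambled, then the GA minimises
res <- orient(b$structure, pot,
              search_config("ga", pop_size = 2000, generations = 60,
                            n_runs = 5, seed = 7))
res$result
#> <mem_orientation ga: E=-160.6860 at (355.15 deg, 216.71 deg, -30.68 A), 604000 energy calls>

# how well was the construction recovered?
mean_segment_tilt(res$structure, b$topology)   # built at 20 deg
#> [1] 19.90392
z_shift(res$structure, b$topology)             # built at 4 A
#> [1] 3.59841

# hydrophobic thickness of the membrane around the oriented complex
estimate_thickness(pot, res$structure)
#> <mem_thickness 30.00 A (offsets upper +0.00, lower +0.00; E=-266.2560)>
```

The reported energy is the minimised membrane pseudo-energy (dimensionless,
natural-log units; more negative = better embedded). The recovered tilt and
z-shift agree with the construction to 0.1° and 0.4 Å, and the thickness
estimate returns the 30 Å standard hydrophobic thickness the training world
was built with. (The pose parameters are relative to the scrambled starting
structure, so only the recovered geometry is meaningful.)

A command-line interface covers the same pipeline:

```sh
memorient train --manifest manifest.tsv --kind alpha --out alpha.pot
memorient orient target.pdb --potential alpha.pot --search ga --runs 5 \
    --seed 1 --out oriented.pdb --json result.json
memorient thickness oriented.pdb --potential alpha.pot --json thickness.json
memorient evaluate oriented.pdb reference.pdb --topology topo.tsv \
    --tilt-error 3 --z-error 1 --json cmp.json
memorient rank --manifest decoys.tsv --potential alpha.pot \
    --native-id native --w 1.6 --seed 1 --json report.json
memorient simulate --what training --seed 3 --out synthetic/
```

(`exec/memorient` is installed with the package; equivalently call
`memorient_cli(c("orient", ...))` from R.)

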