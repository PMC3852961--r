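---
title: "A knowledge-based membrane potential: model, search, and synthetic validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A knowledge-based membrane potential: model, search, and synthetic validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memorient)
```

## The model and its assumptions

Transmembrane proteins sit in an anisotropic environment: a hydrocarbon
core flanked by polar head groups, with a steep polarity gradient along the
membrane normal. `memorient` models this implicitly. The membrane is an
infinite slab 48 Å thick divided into 32 slices of 1.5 Å along z (about
the translation per residue of an alpha helix), with z = 0 at the bilayer
centre and the cytoplasm at negative z — the slab is asymmetric, which is
what lets the potential distinguish a correctly inserted protein from its
upside-down flip (the "positive-inside" signal of Lys/Arg on the
cytoplasmic flank).

Each residue is reduced to a single scoring centre: its Cβ atom, or Cα for
glycine (Cα is also the fallback when a model lacks side chains). Training
counts centres per (residue type, slice) over a set of structures already
positioned in the membrane frame, adds a pseudocount of one to any empty
cell, and converts frequencies to pseudo-energies

$$E_a(z) = -\ln \frac{f_a(z)}{f(z)}$$

with $f_a(z)$ the per-type relative frequency over depth and $f(z)$ the
depth distribution of all residues. This normalisation makes $E$ an
enrichment log-odds: it is exactly zero wherever a type is represented at
the background rate, and uniformly zero when the training data carry no
depth signal at all. (The text this model derives from admits a second
reading of "relative frequency" — normalising within slices instead — but
only the per-type-over-depth reading reproduces the zero-under-uniformity
property, so it is the one implemented.) A structure's energy under a pose
is the sum of per-residue energies at the transformed depths; residues
outside the slab contribute zero, because the slab is the potential's
entire support.

Assumptions worth stating: residues are independent given depth; one
potential serves all proteins of a class (separate alpha-helical and
beta-barrel flavours are trained, selected by `kind`); and the membrane is
flat, infinite, and laterally featureless.

## Pose space and search

A pose has three parameters — rotations about x and y (degrees) and a
translation along z (Å), applied as $p' = R_y R_x\,p + (0,0,dz)$ with
right-handed rotations. Rotation about z and lateral translations do not
change any depth, so three parameters cover the full quotient space; the
order $R_y R_x$ is a documented convention (the source text states none,
and any full-cover parameterisation has the same minimum). Before any
search the input structure is scrambled by a random pose so that nothing
about the deposited orientation leaks into the result.

Three optimisers are provided:

* **Genetic algorithm** (production default): population 10 000, tournament
  selection (size 2), uniform crossover, Gaussian mutation
  (σ = 10°/10°/2 Å at rate 0.1), 1% elitism, 100 generations, five
  independent runs with the best pose reported. All internals are exposed
  in `search_config()`; the GA internals are package choices — the source
  text specifies only the population size, the five runs, and the reduced
  population of 500 for refinement-mode scoring.
* **Hooke–Jeeves direct search**: classic pattern search (exploratory
  ± steps per coordinate, pattern extrapolation, step halving on failure,
  termination below 0.1°/0.05 Å). The energy landscape has wide
  zero-energy plateaus — any pose that places the protein entirely outside
  the slab — on which a blind pattern search stalls immediately, so the
  default protocol seeds it deterministically from a coarse probe grid
  (15°/2.5 Å) and runs iterated searches (full step schedule restarted at
  the optimum until no improvement) from the best `n_runs` probe poses.
* **Grid search**: exhaustive enumeration at 1°/0.5 Å (configurable), the
  deterministic oracle the stochastic methods are tested against. Ties go
  to the first pose in lexicographic (rot_x, rot_y, dz) order.

A compiled kernel evaluates only the z-row of the rotation, so the
1°/0.5 Å grid over ±50 Å (~26 million poses) takes seconds for a
60-residue chain.

## Membrane thickness

Once a structure is oriented, hydrophobic thickness is estimated with a
split potential: the two head-group windows (10 ≤ |z| ≤ 20 Å) are
translated outward independently; a residue inside a shifted window is
scored by the potential at its back-shifted depth, residues between the
windows receive their type's core average (mean energy over slices with
midpoint |z| < 10 Å) and residues beyond them the extramembranous average
(outermost three slices per side, midpoint |z| > 19.5 Å). Thickness is the
distance between window midpoints at the energy optimum:
30 Å + offset_upper + offset_lower. The scan uses 0.25 Å steps over ±8 Å
per leaflet; ties prefer the smallest total offset, so an uninformative
landscape reports the 30 Å standard rather than an arbitrary extreme. The
averaging windows for "core" and "extra-membranous" are package choices —
the source text names the scores but not their windows — as is the
window-translation (rather than slice-remapping) reading of the split.

## Evaluation geometry

Topology annotations (chain, start, end, in/out sense per transmembrane
segment) drive the evaluation module: segment vectors run between the
scoring centres of boundary residues and are flipped so their sense points
inward-to-outward; the longitudinal axis is the normalised mean of the unit
segment vectors; tilt is `acos(|axis . z|)`, folded into [0, 90°] because
only magnitudes are compared; the z-shift is the mean depth of boundary
residues. `naive_orient()` implements the baseline that aligns the
longitudinal axis with z and centres the span — useful as the control the
potential-based search must beat. When a topology file omits the sense
column, segments alternate starting inward-to-outward, and that convention
is logged.

## The synthetic world: what it emulates and what it does not

Training the real potential requires a curated database of membrane
proteins pre-positioned in the bilayer. To keep every stage testable
offline, the `synthetic` module generates idealized bundles with controlled
depth statistics:

* **Geometry.** Canonical Cα helices (2.3 Å radius, 100°/residue twist,
  1.5 Å rise) with Cβ placed 1.53 Å radially outward; glycine gets no Cβ.
  Helices of 19/37/55 residues have boundary residues at equal azimuth,
  making segment tilts exact; the default 51-residue helices (75 Å span)
  instead prioritise realistic juxtamembrane flanks, at the cost of a
  sub-0.1° azimuthal bias.
* **Composition.** Four concentric bands: aliphatics (A,F,I,L,M,V) across
  the hydrocarbon core (|z| ≤ 10.5 Å), the aromatic belt (W,Y) at the
  inner head-group region (10.5–15 Å), interface polars (N,Q,H,S,T) at the
  outer head-group region (15–19.5 Å), and charged types (D,E) outside,
  with Lys/Arg enriched 1.5× on the whole cytoplasmic head region —
  the positive-inside asymmetry. Enrichment is 8-fold over a uniform
  background with a 10% depth-blind noise floor. Magnitudes are test
  constants chosen once for a clearly detectable but not caricatured
  signal; they are not measured values.
* **Scale.** The default training corpus is 183 bundles (matching the real
  alpha-helical chain count the method was built on) of 8 helices × 51
  residues (~400 residues per chain), each at a random native tilt drawn
  from U(0, 25°). Held-out orientation targets are 16-helix complexes
  (~48 Å across, the scale of a multimeric channel).

Three of these choices are load-bearing in ways worth recording:

1. **Band edges sit on slice boundaries** (10.5/15/19.5 Å). If the
   generating bands straddle slices, a sub-slice rigid shift of a test
   structure gains energy purely by re-registering band edges against slice
   edges, displacing the energy minimum ~1 Å from the constructed pose —
   a discretization artifact, not biology.
2. **Training bundles are tilted.** Perfectly vertical ideal helices place
   every centre at an exact multiple of the 1.5 Å rise, aliasing the
   trained bands one slice upward relative to the continuous bands that
   tilted test structures sample. Random native tilts cover depth
   continuously, as real structures do.
3. **Recovery targets are wide.** Tilt sensitivity comes from lateral
   extent: a rigid tilt by δ changes a residue's depth by roughly its
   lateral distance × sin δ. At a 6-helix bundle's ~11 Å radius, a ±3°
   basin is genuinely flat at 1.5 Å slice granularity, so no implementation
   could localise tilt to 2° there; at a 16-helix complex's ~29 Å radius it
   can.

A green synthetic test therefore establishes that training, search,
thickness, evaluation and ranking are internally consistent and recover a
stated world built on the same depth-statistics the real potential encodes.
It does not establish real-data accuracy: real depth profiles are smoother
and weaker, real proteins have loops, irregular helices and lateral
structure, and real benchmark numbers depend on the curated snapshot used.

## Numerical choices and degenerate inputs

* Slices are half-open `[lo, lo + 1.5)`, lower edge inclusive at −24 Å;
  z = +24 Å is outside. Binning is therefore deterministic at boundaries.
* Pseudocounts are added only to empty cells, as literally stated in the
  source text; `pseudocount = "everywhere"` enables add-one-everywhere for
  sensitivity analysis.
* Grid ties break lexicographically; thickness ties prefer the smallest
  total offset, then lexicographic order.
* Serialized potentials store counts and energies; energies are recomputed
  from counts on load and a mismatch beyond 1e-9 is an error, so hand-edited
  files fail loudly.
* Alt-locs keep the first conformer; MODEL 1 only; MSE→MET and SEC→CYS;
  other non-standard polymer residues are skipped with a warning; malformed
  coordinate records are skipped with a warning. Hetero molecules and
  waters never contribute scoring centres.
* Ensemble scoring uses one derived seed shared by all models in a pass
  (common random numbers): duplicate models receive identical energies and
  rankings between near-identical models are not scrambled by independent
  search noise. Independent per-model seeds were tried and rejected —
  residual search noise of ~1 energy unit inverted the ranking between the
  native and a 2%-scrambled decoy in about a third of ensembles.

## Known limitations

* The direct search, even probe-seeded and iterated, is a local method: on
  rough landscapes (small proteins under a noisily trained table) it can
  terminate 1–3 energy units above the exhaustive-grid minimum. The GA at
  production settings matches or beats the fine grid in all tested worlds;
  the grid itself is available when determinism is required.
* One potential per class: lipid-specific profiles, curvature, and local
  (per-lipid) thickness are out of scope.
* The refinement integration point is `combined_energy()`; the fragment
  recombination machinery that would call it belongs to a separate
  modelling system and is not reimplemented here.
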