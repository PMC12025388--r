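---
title: "Conformer-ensemble analysis of Rh-bisphosphine catalyst complexes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conformer-ensemble analysis of Rh-bisphosphine catalyst complexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhconf)
```

## The problem

Descriptor-based design of homogeneous catalysts usually computes steric
and electronic descriptors on a single optimized geometry. For
Rh-bisphosphine complexes used in asymmetric hydrogenation this is
questionable: the chiral ligand is conformationally flexible, and the
bound substrate selects among several coordination orientations. `rhconf`
implements the analysis layer of a conformer-aware descriptor workflow:
it ingests conformer ensembles (as produced by a metadynamics-based
conformer search such as CREST, then re-optimized by DFT), quantifies
fragment-resolved flexibility, prunes and deduplicates the ensembles, and
summarizes descriptors as Boltzmann-weighted means with weighted standard
deviations, separately per substrate-coordination group.

The quantum-chemistry layer itself (geometry optimization, conformer
search, natural population analysis) is out of scope: its outputs are
ingested from multi-frame XYZ files and a delimited per-conformer
property table with a fixed, documented schema (`member`,
`energy_hartree`, `homo_hartree`, `lumo_hartree`, and per-atom charges
`q_<index>`). Decoupling via this schema keeps the pipeline independent
of any particular quantum-chemistry program's log format.

## Complexes, fragments and coordination modes

A catalyst-substrate complex is modelled as a metal center, a bidentate
bisphosphine ligand binding through two P donors, and either the
prochiral model substrate ("S", methyl 2-acetamidoacrylate, binding
through its alkene and amide oxygen) or the rigid norbornadiene
placeholder ("NBD"). For each ligand, S has four coordination
orientations — two "major" and two "minor" in the Knowles quadrant
picture of a C2-chiral pocket — while NBD has one; `enumerate_complexes()`
is the bookkeeping over these templates (11 ligands give 44
substrate-bound templates, 55 with the precatalysts).

`split_fragments()` separates a conformer into a ligand part (ligand
atoms plus metal) and a substrate part (substrate atoms, metal, and both
P donors; the donors give the substrate fragment an orientation
reference). The two parts deliberately share the metal and donors, so
their sizes sum to the atom count plus three.

### Coordination-mode classification

The quadrant picture is pictorial; to make retention checks computable
we fix an explicit frame. At the metal, let `u1`, `u2` be unit vectors
to the two donors (in the stored donor order). Then

* `x` = the normalized bisector `u1 + u2`,
* `z` = the normalized cross product `u1 x u2`,
* `y` = `z x x` (right-handed).

The substrate's out-of-plane directing-group oxygen is projected on
`(x, y)`; the `y` sign maps to major/minor (convention flag
`major_y_positive`, default `TRUE`) and the `x` sign to mode 1/2.
Because the frame is built from the ligand's own donors, it is covariant
under rigid motions (the label is invariant) and under donor relabeling
conventions; what flips major to minor is the physically meaningful
operation of mirroring the substrate across the ligand's `xz`-plane.
Projections within `1e-3` angstrom of a boundary plane raise an
ambiguity error rather than silently assigning a label. The anchor atoms
(two coordinated alkene carbons plus the reference oxygen) are explicit
configuration, not inferred from connectivity.

Axial-chirality retention is checked as the sign of the dihedral over a
configured 4-atom reference on the chiral axis (`check_chirality()`); a
reflection flips the sign, so inverted conformers are caught.

## Minimal RMSD

Structural variability is measured as the minimal heavy-atom RMSD under
optimal superposition, computed in closed form by the Kabsch/SVD
construction. Two conventions matter:

* **No reflections.** If the optimal orthogonal transform is improper,
  the smallest singular direction is flipped to force a proper rotation.
  Allowing reflections would silently superpose enantiomers.
* **Positional correspondence.** All conformers of one complex descend
  from a single input structure, so atom `i` corresponds to atom `i`;
  no graph matching or permutation correction is attempted.

`rmsd_profile()` reports, per member, the whole-complex, ligand-part and
substrate-part RMSD relative to the lowest-energy conformer (energy ties
broken by lowest member index), each part superposed independently, with
hydrogens excluded by default.

## Ensemble statistics and filters

* `relative_energies()`: member energy minus the conformer-search input
  ("baseline") energy, in kJ/mol; negative values mean the search found
  structures more stable than its input.
* `energy_window_filter()`: retains members within a window of the
  ensemble minimum; default 6 kcal/mol, the conventional selection
  window of the conformer-search stage (the window stays in kcal/mol
  while relative energies are reported in kJ/mol, matching field usage).
* `deduplicate()`: re-optimization often collapses several sampled
  conformers into one minimum. Members are visited in ascending energy
  order and join an existing representative when heavy-atom RMSD
  <= `rmsd_tol` *and* energy difference <= `energy_tol`. Defaults
  `rmsd_tol = 0.25` angstrom, `energy_tol = 1.0` kJ/mol: tight enough
  not to merge distinct wells, loose enough to merge numerically
  identical minima. Greedy ascending-energy clustering is deterministic,
  idempotent, and guarantees representatives are their cluster's energy
  minima; it is not complete-linkage clustering, a deliberate trade of
  statistical elegance for reproducibility and O(n k) cost.
* `apply_retention_filters()`: removes members with flipped chirality or
  a changed coordination mode, logging each removal; ambiguous
  classifications are flagged, never silently dropped.

## Descriptors

The five-descriptor subset computed per conformer
(`descriptor_table()`):

| descriptor | source | unit |
|---|---|---|
| `V_bur_metal` | grid integration | % |
| `V_bur_donor` | grid integration, mean of the two P | % |
| `q_metal` | ingested NPA charge | au |
| `q_donor` | ingested, mean of the two P | au |
| `homo_lumo_gap` | ingested orbital energies | eV |

Percent buried volume is the fraction of a probe sphere centered on an
atom occupied by the scaled van der Waals spheres of the surrounding
atoms. Defaults follow the de-facto standard of the buried-volume
literature — sphere radius 3.5 angstrom, Bondi radii scaled by 1.17,
hydrogens excluded, center atom excluded — because the source workflows
for this descriptor rarely state them; all four are arguments. The
integral is evaluated on a deterministic cubic grid (spacing 0.05
angstrom, compiled kernel), stable to about 0.05 percentage points under
grid halving; the test suite checks it against a closed-form single-
sphere ratio and a Monte-Carlo rejection oracle. Bondi's table lacks the
platinum-group metals; a 2.00 angstrom supplement is used there (the
center atom is excluded by default, so this rarely enters).

## Boltzmann weighting

Within each group, conformer `i` gets raw weight
`w_i = exp(-(E_i - E_min) / (k_B T))` with `E_min` the group minimum, so
the most stable conformer has weight 1; weights are then normalized per
group. Energies are converted to kJ/mol and `k_B T` uses the molar gas
constant — numerically identical to the per-molecule form. The default
temperature is 289 K, kept exactly as the source descriptor workflow
states it even though it may well be a transcription of 298 K; it is a
single argument to override (`k_B T` = 2.403 kJ/mol at 289 K vs 2.479
at 298.15 K, a small but not negligible difference in weights).

Summaries report the weighted mean and the *population-form* weighted
standard deviation `sqrt(sum w_i (v_i - mean)^2)` (the source workflow
does not specify a form; the population form is the natural dispersion
of a normalized-weight distribution and is zero for constant values),
plus the Kish effective sample size. `group_summary()` pools the two
major modes into one group and the two minor modes into another,
mirroring the three-group layout (S-major, S-minor, NBD) in which such
descriptor averages are reported; per-set summaries can be obtained by
passing finer group labels.

## The synthetic-data generator

Real ensembles require days of DFT; the generator provides ensembles
with known ground truth so every stage is testable at desk scale.

`make_complex_template()` builds a geometrically valid base complex
(metal at origin, donors symmetric about the bisector axis, two ligand
arms with a definite axial dihedral, substrate trans to the donors with
its reference oxygen placed in the requested quadrant; minimum
interatomic distance 0.8 angstrom). `make_ensemble()` then draws, per
conformer, independent Gaussian displacements — `sigma_ligand` (default
0.8 angstrom) on ligand-arm atoms, `sigma_substrate` (default 0.05) on
the substrate, metal and the metal-anchored donors — followed by a random
proper rigid motion of the whole frame, so superposition code cannot
pass by coordinate coincidence. These defaults reproduce the qualitative
structure of real ensembles: substrate-part RMSDs around 0.1 angstrom
(rarely approaching 1) against ligand-part RMSDs of one to several
angstrom. Energies above the minimum are exponential with mean 10 kJ/mol
— a right-skewed, minimum-anchored spread over tens of kJ/mol, emulating
(not asserting) the shape seen in re-optimized ensembles. Electronic
descriptors follow a linear model in the realized ligand-part RMSD plus
Gaussian noise, with all draws stored in a truth record.

`make_dedup_fixture()` plants `n_wells` well centers (rejection-sampled
until pairwise heavy-atom RMSD >= `well_separation`) and replicates each
with jitter far below the dedup tolerance, spreading a requested total
as evenly as possible (151 members over 35 wells gives wells of 4-5).

A single integer seed governs each generator call; the displacement,
energy and descriptor streams are drawn in a fixed documented order, so
identical configurations reproduce byte-identical output.

What the generator does *not* emulate: bonded structure and force-field
realism, anharmonic well shapes, correlated collective motions,
rotamer/topology duplicates, and any real relation between geometry and
electronic structure. Passing tests therefore demonstrate correctness of
the analysis pipeline under controlled ground truth, not accuracy of any
chemistry conclusion about real catalysts.

## Numerical choices and degenerate inputs

* Kabsch uses base `svd()`; the reflection fix flips the smallest
  singular direction. Fewer than three atoms after masking/hydrogen
  filtering is an error, as is superposing differing element sequences.
* Energy ties for the RMSD reference and dedup visiting order break by
  lowest member index.
* Collinear dihedral triples, antiparallel donor geometries and
  near-boundary quadrant projections raise errors instead of returning
  arbitrary labels.
* The energy-window filter includes the boundary (`<= window + 1e-12`
  kJ/mol) so exact-boundary members are kept.
* Unit conversions use CODATA factors (1 hartree = 2625.499639 kJ/mol =
  627.509474 kcal/mol = 27.211386245988 eV) and round-trip to 1e-10
  relative.

## Problem sizes used in the shipped checks

The test suite and the reproduction script run entirely on synthetic
data: ensembles of 4-200 conformers of a ~35-atom complex, a 151-member
35-well dedup fixture, and Monte-Carlo oracles up to 1e7 samples. These
sizes give stable statistics for every check while keeping a full run in
the minutes range on one CPU; all of them are arguments, and nothing in
the package logic depends on them.

## Worked example

```{r example}
cfg <- generator_config(seed = 11, n_conformers = 12)
tb <- make_complex_template(cfg, "major1")
gen <- make_ensemble(cfg, tb)

prof <- rmsd_profile(gen$ensemble, tb$spec)
summary(prof[c("rmsd_ligand", "rmsd_substrate")])

dd <- deduplicate(gen$ensemble)
length(dd)

dt <- descriptor_table(dd, tb$spec,
                       gen$property_table[attr(dd, "representatives"), ] |>
                         transform(member = seq_len(length(dd))) |>
                         ingest_property_table(dd),
                       grid_spacing = 0.08)
gs <- group_summary(dt, ensemble_energies(dd), rep("S-major", length(dd)))
gs[gs$descriptor == "q_metal", ]
```

## Known limitations

* Atom correspondence is positional only; ensembles whose atom order was
  permuted upstream must be reordered before analysis.
* The coordination classifier operationalizes the quadrant picture with
  one specific frame; systems with strongly pyramidalized donor
  geometries may need a different out-of-plane reference.
* Boltzmann weighting uses electronic energies only; free-energy
  (entropy-corrected) populations are out of scope.
* Buried volume ignores elements without a tabulated radius (raising an
  error) rather than guessing one.
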