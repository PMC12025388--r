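# rhconf

Conformer-ensemble analysis for Rh–bisphosphine catalyst complexes.

Single-geometry descriptors can misrepresent flexible asymmetric-
hydrogenation catalysts: the chiral bisphosphine ligand samples many
conformations while the bound substrate (the prochiral model substrate
"S" or the norbornadiene placeholder "NBD") stays comparatively rigid in
one of several coordination orientations. `rhconf` is the analysis layer
for conformer-aware descriptor workflows. Given conformer ensembles
(CREST-style multi-frame XYZ with per-frame energies) and a per-conformer
property table from upstream quantum chemistry, it provides:

* **Fragment-resolved flexibility profiling** — minimal heavy-atom RMSD
  by Kabsch superposition (proper rotations only, positional atom
  correspondence), computed for the whole complex, the ligand part
  (ligand + metal) and the substrate part (substrate + metal + both P
  donors), relative to the lowest-energy conformer.
* **Ensemble curation** — chirality and coordination-mode retention
  filters (a computable quadrant classifier built on the donor-bisector
  frame at the metal), a 6 kcal/mol energy-window filter, and greedy
  ascending-energy deduplication of conformers that re-optimization
  collapsed onto one minimum (defaults 0.25 Å / 1.0 kJ/mol).
* **Descriptor statistics** — percent buried volume at Rh and at the P
  donors (deterministic grid integration, 3.5 Å sphere, Bondi radii
  × 1.17, H excluded), ingested NPA charges and HOMO–LUMO gaps, averaged
  per group with Boltzmann weights
  `w_i = exp(-(E_i - E_min) / (k_B T))` at T = 289 K and reported as
  weighted mean ± weighted (population) standard deviation for the
  S-major, S-minor and NBD groups.
* **A synthetic-ensemble generator** with exact ground truth (known
  displacement scales, energies, well structure and descriptor models)
  so the full pipeline is testable without any quantum-chemistry run.

## Worked example

```r
library(rhconf)

cfg <- generator_config(seed = 11, n_conformers = 12)   # study-like defaults
tb  <- make_complex_template(cfg, "major1")
gen <- make_ensemble(cfg, tb)

prof <- rmsd_profile(gen$ensemble, tb$spec)
summary(prof[c("rmsd_ligand", "rmsd_substrate")])
#>   rmsd_ligand    rmsd_substrate
#>  Min.   :0.000   Min.   :0.00000
#>  Median :1.654   Median :0.09224
#>  Max.   :2.001   Max.   :0.11833
```

The flexible ligand arms move by 1.5–2 Å between conformers while the
substrate part stays near 0.1 Å — the fragment-resolved signature of a
flexible pocket around a rigidly coordinated substrate.

```r
length(deduplicate(gen$ensemble))   # all 12 members are distinct minima here
#> [1] 12
gs <- group_summary(
  descriptor_table(gen$ensemble, tb$spec, gen$property_table),
  ensemble_energies(gen$ensemble), rep("S-major", 12))
gs[gs$descriptor == "q_metal", ]
#>     group descriptor       mean         sd  n      ess
#> 3 S-major    q_metal -0.1774591 0.02063994 12 4.381292
```

The Boltzmann mean of the Rh charge is dominated by the lowest-energy
conformers (effective sample size 4.4 of 12); the weighted standard
deviation (0.02 au) is the ensemble-induced spread a single-geometry
workflow would miss.

A command-line front end over the same functions lives at
`inst/cli/rhconf.R` (subcommands `generate`, `filter`, `dedup`, `rmsd`,
`descriptors`, `boltzmann`, `report`), composing through plain XYZ/TSV/
YAML intermediates.

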