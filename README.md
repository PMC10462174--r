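# discbelt

Construction and trajectory analysis of double-belt lipid nanodiscs in R.

Nanodiscs are discoidal particles in which a patch of phospholipid bilayer
is encircled by belt-like amphipathic scaffold proteins. For
apoE3-NT/DMPC particles the working model is a *double belt*: four
scaffold chains arranged as two stacked rings (chains A/B above, C/D
below), whose N-to-C angular sense can be *parallel* or *antiparallel*
between the rings. `discbelt` provides the two halves of a simulation
study of such particles, everything except the molecular dynamics itself:

* **Model construction** — linearise a four-helix bundle into an extended
  chain (helices kept internally rigid), wrap two tandem copies per ring
  with a 0.5 nm terminal Cα gap, stack the second ring 3 nm below in
  parallel or antiparallel sense, and pack a DMPC bilayer disc inside
  (`linearize_bundle()`, `assemble_double_belt()`, `pack_lipid_disc()`,
  `build_system()`).
* **Trajectory analysis** — for structures/trajectories in PDB, GRO or
  DCD: reorientation of the bilayer normal onto *z*; 100-bin mass density
  profiles with the phosphate peak-to-peak **thickness** and two
  **diameter** estimators (outermost protein density maxima; lipid
  density decay to 1 kg/m³); **radius of gyration**; Shrake–Rupley
  **SASA** with 48 sphere points and 0.14 nm (all-atom) or 0.265 nm
  (coarse-grained) water probes; Kabsch-superposed backbone **RMSD**;
  inter-chain residue **contacts** (1 nm extraction, 0.4 nm cutoff)
  classified polar / nonpolar / nonspecific with an ionic (salt-bridge)
  flag for Arg/Lys/His × Asp/Glu pairs; and the acyl-chain order
  parameter

  > S<sub>i</sub><sup>CD</sup> = ½ ⟨3 cos²θ<sub>i</sub> − 1⟩,

  with θ<sub>i</sub> the angle between a C–H bond of tail carbon *i* and
  the bilayer normal, averaged over both chains (sn1/sn2), lipids and
  frames, reported as |S<sub>CD</sub>| for the full disc and for core
  (≤ 3 nm from the lipid centre) and rim (≤ 1.4 nm from the belt)
  subsets.
* **Synthetic ground truth** — a generator (`generate_nanodisc()`,
  `generate_bilayer_patch()`) that emits idealised nanodisc trajectories
  with known radius, thickness, belt geometry and per-carbon
  |S<sub>CD</sub>|, so every analysis stage is testable without running
  MD.

Published per-system contact counts and backbone RMSD values for the
apoE3-NT/DMPC series (240–420 DMPC, both belt senses) ship as
`apoe_contact_counts()` / `apoe_backbone_rmsd()` so the
parallel-vs-antiparallel comparison statistics can be reproduced
directly.

## Worked example

Generate a synthetic 240-lipid antiparallel disc and run the full
analysis pipeline:

```r
library(discbelt)

d   <- generate_nanodisc(disc_spec(n_lipids_per_leaflet = 120,
                                   n_frames = 10, seed = 7))
rep <- run_analysis(d$traj, label = d$truth$label,
                    config = analysis_config(n_snapshots = 10))
print(rep)
#> analysis report for 240-A
#>   thickness_nm                 3.407
#>   diameter_protein_x_nm        10.844
#>   diameter_lipid_x_nm          9.679
#>   diameter_protein_y_nm        10.829
#>   diameter_lipid_y_nm          9.436
#>   diameter_protein_mean_nm     10.837
#>   diameter_lipid_mean_nm       9.558
#>   radius_of_gyration_nm        4.018
#>   sasa_nm2                     1046.380
```

The disc was built with phosphate planes 3.4 nm apart and a lipid radius
of 4.79 nm: the pipeline recovers the thickness (3.407 nm), the lipid
threshold diameter (9.56 vs 9.57 nm true), and the protein-maxima
diameter correctly exceeds the lipid one (the belt lies outside the
lipids). With vertical tails and C–H bonds perpendicular to the normal,
the order parameter is |S_CD| = 0.5 up to noise:

```r
head(subset(rep$metrics$order_parameters, region == "core"), 3)
#>    carbon_index carbon_number   abs_scd region n_lipids
#> 14            1             2 0.4999689   core      109
#> 15            2             3 0.4999689   core      109
#> 16            3             4 0.4999689   core      109
```

Comparing belt senses on the published contact table:

```r
tab <- apoe_contact_counts()
configuration_comparison(tab[tab$mode == "parallel", ],
                         tab[tab$mode == "antiparallel", ])$ratios
#> polar_total       ionic nonspecific    nonpolar       total
#>         1.8         3.2         1.5         2.3         1.8
```

Antiparallel discs have on average 2.3× the nonpolar and 3.2× the ionic
inter-chain contacts of their parallel counterparts — the quantitative
backbone of the conclusion that the antiparallel arrangement is the more
stable one.

A thin command-line front-end is installed with the package
(`inst/scripts/discbelt`) with `synth`, `build`, `analyze`, `sasa`,
`scd` and `compare` subcommands.

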