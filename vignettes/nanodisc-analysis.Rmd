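---
title: "Building and analysing double-belt lipid nanodiscs"
author: "discbelt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and analysing double-belt lipid nanodiscs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(discbelt)
```

# The system and the model

Apolipoprotein E3's N-terminal domain (apoE3-NT) is a four-helix bundle
when lipid-free; bound to a DMPC bilayer patch it opens into an extended
helical belt that wraps the patch edge. The working structural model for
apoE3-NT/DMPC nanodiscs is a *double belt*: four chains, two per ring,
arranged in tandem around the disc, with the lower ring either parallel
or antiparallel to the upper one in its N-to-C angular sense. Systems
are labelled by total DMPC count and belt sense, e.g. `240-A` for 240
lipids, antiparallel.

`discbelt` implements (i) the geometric construction of such starting
structures from a helix bundle, (ii) the complete post-hoc analysis
suite applied to trajectories of such systems, and (iii) a synthetic
trajectory generator with exact ground truth that makes every stage of
(ii) testable without molecular dynamics. Running the dynamics itself is
out of scope: the package consumes coordinates, it never propagates
them.

# Units and containers

All internal lengths are nanometres; PDB files (Å) are converted on
read and write. A `trajectory` couples an atom table (name, element,
residue, chain, mass) to an `natoms × 3 × nframes` coordinate array;
atom order is the identity key across frames. Masses come from the
conventional IUPAC standard atomic weights (C 12.0107, H 1.00794, …),
under which one DMPC (C36H72NO8P) weighs 677.93 amu; coarse-grained
beads whose names are not element symbols take per-bead masses from a
user-supplied table. `system_mass()` reports whole-system masses as
integer daltons with the fractional remainder discarded and a default
chain mass of 34,000 Da (the ≈34 kDa apoE figure), which reproduces the
published 298,703–420,730 Da range for four chains plus 240–420 DMPC
exactly. XTC input is not supported (no available reader decodes its
compressed coordinates); DCD fills the binary-trajectory role, with a
small built-in writer so round trips need no external tooling.

# The synthetic generator

`generate_nanodisc()` emits an idealised disc with every relevant
quantity known by construction:

* **Lipids.** A minimal explicit-hydrogen DMPC surrogate: one phosphate
  P atom, two 14-carbon tails (carbons 2–14, CHARMM36-style names
  `C2k`/`C3k` with hydrogens `HkR/HkS` and `HkX/HkY`) with both
  hydrogens perpendicular to the tail axis. Atom-name-based selection
  and the order-parameter code therefore run unchanged on real
  force-field output.
* **Packing.** `n` sites per leaflet are laid out on a Vogel
  (golden-angle sunflower) spiral of radius
  `sqrt(n · APL / π)`, which gives exactly one `area_per_lipid` (APL)
  per site with an isotropic, circular edge. A hexagonal cut-out was
  rejected: its boundary circumradius and apothem differ by ~13%
  (≈0.4 nm at these sizes), and because reorientation aligns the widest
  direction with x, that anisotropy biases per-axis diameter estimates
  by several bin widths. The outermost ring sits one molecular
  footprint (0.25 nm) inside the nominal radius so the *atomic* edge —
  which is what a density-threshold diameter measures — lies at the
  ground-truth radius. The bilayer patch generator
  (`generate_bilayer_patch()`, default 150 lipids, 75 per leaflet)
  keeps a plain hexagonal lattice under periodic boundaries.
* **Defaults.** APL 0.60 nm² (fluid-phase DMPC) and phosphate plane
  separation 3.4 nm, the measured all-atom disc thickness, so synthetic
  fixtures resemble the studied systems out of the box.
* **Tails and ground-truth order.** Tail directors follow a configurable
  tilt law (fixed angle, Gaussian, or isotropic); an extra tilt spread
  can be applied to lipids within `rim_width` of the edge to emulate
  rim-localised disorder. The per-carbon |S~CD~| implied by the
  constructed C–H bond directions is recorded as ground truth; with
  vertical tails it is exactly 0.5 for every carbon.
* **Noise.** Thermal motion is emulated as a per-frame *rigid
  per-residue* Gaussian displacement (default sd 0.05 nm, a realistic
  heavy-atom fluctuation amplitude). Independent per-atom jitter was
  rejected: 0.05 nm of it on a 0.109 nm C–H bond randomises bond
  directions, which no real trajectory does, and would destroy the
  order-parameter ground truth while leaving densities unchanged.
  (`perturb_frames()` applies the same scheme; each atom's positional
  sd still equals the requested sigma.)
* **Belts.** Four ideal α-helical poly-alanine ribbons (1.5 Å
  rise/residue wound along the ring) at `disc_radius + radius_offset`,
  chains A/B in the upper and C/D in the lower ring; antiparallel mode
  reverses the lower ring's angular sense. These test geometry code,
  not protein chemistry.
* **Determinism.** One private RNG stream per call, seeded explicitly
  and recorded in the ground truth; the caller's RNG state is restored.

What the generator does *not* emulate: thermodynamic realism, water and
ions, lipid conformational disorder (gauche defects), membrane
undulations, or coarse-grained bead models. Passing tests on synthetic
discs therefore demonstrate the correctness of the estimators, not the
behaviour of real bilayers.

# Reorientation

Snapshots are reoriented so the bilayer normal is +z and the lipid
centre of mass is the origin. The normal comes from the eigenbasis of
the phosphate positional covariance. For a wide flat disc it is the
smallest-eigenvalue eigenvector; for small discs, however, the two
phosphate planes (±1.7 nm) can contribute as much variance along the
normal as the disc radius does in plane, so the axis is instead chosen
as the eigenvector with the smallest *within-side* spread — phosphates
collapse onto one or two tight planes along the normal but spread over
a sizeable fraction of the radius along any in-plane axis. The two
rules coincide whenever the radius safely exceeds half the plane
separation. In-plane, the major principal axis is rotated onto x, which
fixes the otherwise arbitrary x/y assignment when elliptical discs are
reported per axis.

# Density profiles and size metrics

Profiles are 100-bin, frame-averaged mass histograms along one axis,
converted to kg/m³ with a per-bin slab volume of bin width × the
orthogonal bounding-box cross-section of the full system (fixed per
trajectory and recorded in the result; the conversion is a convention —
thresholds and peak positions, not absolute density values, carry the
science). The default extent is the bounding box plus a 1 nm margin.
Mass is conserved to 1e-9 relative before symmetrisation.

Symmetrisation replaces density(c+δ) and density(c−δ) by their mean; the
centre is snapped to the nearest half-bin so the reflection maps bins
onto bins exactly, which makes the operation idempotent.

* **Thickness** is the peak-to-peak distance of the symmetrised
  phosphate profile along z, with each peak refined by 3-point parabolic
  interpolation to beat 100-bin quantisation. A candidate pair of peaks
  must be separated by a density valley below half the smaller peak;
  a noisy monolayer histogram therefore errors out as "not a bilayer"
  rather than returning a spurious sub-bin thickness.
* **Protein diameter** is the distance between the outermost local
  maxima of the belt density along x or y (parabolic-refined).
* **Lipid diameter** is the distance between the outermost crossings of
  the 1 kg/m³ level, linearly interpolated between bins. This threshold
  sits deep in the sampled tail of the distribution: on atomistic
  histograms the crossing is set by single-atom excursions, so it is an
  intrinsically noisy estimator at the ±(bin width) level — one reason
  the protein-maxima diameter is reported alongside.
* `average_diameter()` treats the disc as elliptical and reports the
  x/y mean with the major and minor values retained;
  `linear_trend()` fits size metrics against lipid count by OLS.

On synthetic sweeps of 240–420 lipids (8 frames, default noise), the
recovered thickness stays within half a z-bin of the construction value
and the lipid-threshold diameter within one bin width + 3σ of twice the
ground-truth radius, with the protein diameter always larger — the
double-belt signature.

# SASA

`shrake_rupley_sasa()` samples each atom's expanded sphere
(r~vdW~ + probe) with a deterministic golden-spiral point set — 48
points by default, mirroring common practice — and counts points not
buried in any neighbour's expanded sphere; neighbour search uses a
uniform cell grid (C++) whose parameters do not affect the result. Bondi
element radii serve the all-atom profile; the coarse-grained profile
assigns one 0.264 nm bead radius. Probe radii are 0.14 nm (AA water)
and 0.265 nm (CG water bead). At 48 points the two-sphere closed form is
matched to well under 5% and rotations reproduce the area to a couple of
percent (the point lattice is fixed in space; translations are exact).

# RMSD and escaped lipids

`kabsch_superpose()` implements the SVD form of least-squares rigid
superposition with a proper rotation enforced;
`backbone_rmsd_series()` refits every frame onto the reference (first
frame by default, configurable — which frame the published per-system
values used is not stated) over N/CA/C/O and reports mean ± sd in the
"0.48 ± 0.10" convention. `detect_escaped_lipids()` single-links lipid
residue centroids; everything outside the largest cluster is escaped.
The default linkage distance is 2.0 nm: it must exceed both the
in-plane neighbour spacing (~0.9 nm at 0.60 nm²/lipid) and the
inter-leaflet centroid separation (~1.7 nm for a 3.4 nm bilayer), or an
intact bilayer falls apart into its two leaflets.

# Contacts

Residue–residue distances are side-chain heavy-atom minima (Gly falls
back to CA; backbone-mediated contacts are excluded by construction).
Pairs across the stacked chain pairs (A,C) and (B,D) by default are
extracted within 1 nm and evaluated per frame at the 0.4 nm cutoff; a
pair is reported when present in ≥ 50% of frames (configurable;
`occupancy_min = 0` on one frame reduces to a plain distance scan).
Classification uses a polarity table the source material never spells
out, so it is an explicit, overridable package decision: polar =
{D,E,K,R,H,N,Q,S,T,Y,C,W}, nonpolar = {A,V,L,I,P,F,M,G}, one of each =
"nonspecific"; the ionic flag marks {R,K,H} × {D,E} pairs (salt
bridges). `configuration_comparison()` forms, per category, the ratio of
mean antiparallel to mean parallel counts over the lipid counts present
in both series, rounded to one decimal; applied to the published
apoE3-NT/DMPC table (`apoe_contact_counts()`) this yields 2.3 for
nonpolar and 3.2 for ionic contacts.

# Order parameters

For tail carbon *i*, S^CD^~i~ = ½⟨3cos²θ~i~ − 1⟩ over every C–H bond of
that carbon, both tails, all selected lipids and frames; |S| is
reported per carbon (chain positions 2–14 map to plot indices 1–13;
the terminal methyl is included). Hydrogens are located by the
CHARMM-style naming convention; inputs without explicit hydrogens are
rejected rather than silently reconstructed. Region profiles evaluate
membership per frame: *core* = lipid centroids within 3.0 nm (in-plane)
of the lipid centre of mass; *rim* = centroids within 1.4 nm of any
belt atom. The rim cut-off in the source material reads "14 nm", which
would include every lipid of every disc studied; it is treated as a
typo for 1.4 nm and exposed as a parameter. Analytic fixtures pin the
implementation: perpendicular bonds give exactly 0.5, magic-angle bonds
0, and 10⁵ isotropic bonds 0 ± 0.01.

# The belt builder

`linearize_bundle()` re-places each helical segment as a rigid body
(zero internal RMSD, verified to machine precision) end-to-end along x,
rebuilding loop and terminal residues as extended connectors on the
axis. "Unwinding" is under-specified in the source material; rigid-helix
re-placement with extended loops is this package's reading, and the
model is a starting structure for minimisation and dynamics, not a
refined fold — no backbone dihedral modelling is attempted.

`assemble_double_belt()` bends two tandem copies around a circle:
helix segments are placed rigidly and tangentially at their central arc
angle, loop residues per residue, so secondary structure again survives
intact. The ring radius is not user-set: it is solved (1-D root find on
the realised terminal Cα positions) so the 0.5 nm tandem Cα gap is
honoured exactly; when a chain's termini are helical and wind off-axis
the exact gap can be geometrically unreachable, in which case the
closest achievable radius is used with a warning. The lower ring sits
`layer_separation` (3 nm) below, with equal (parallel) or reversed
(antiparallel) angular sense — the two builds differ in nothing else.
`pack_lipid_disc()` reuses the synthetic lipid surrogate and verifies a
0.2 nm protein–lipid clearance; `build_system()` warns for lipid counts
outside 240–420 (sizes outside that window tended not to form stable
discs) but still builds.

`generate_helix_bundle()` provides a synthetic up-down four-helix
bundle — ideal helices on a 2×2 square with short loops and two-residue
flexible termini, in the spirit of the apoE3-NT fold — as a
self-contained input for the builder; real PDB input goes through
`build_system(path, segments = ...)`.

# Pipeline

`run_analysis()` chains the stages (window → reorient → densities →
sizes → R~g~ → SASA → RMSD → contacts → S~CD~ → escaped lipids) with
per-stage failure isolation: a stage that errors is recorded in
`stage_errors` and flagged `partial` without aborting the rest, since
real trajectories routinely break single metrics (a CG naming dialect
without "P" atoms, a belt-less patch). The analysis window takes the
terminal fraction of frames and subsamples a fixed number of snapshots
at equal stride (200 by default, matching the snapshot-averaging
convention of the study design). Reports serialise to JSON with units
embedded in the metric names; identical input, configuration and seed
give byte-identical reports. `compare_configurations()` produces the
contact-ratio table, per-carbon ΔS~CD~ = |S~CD~(parallel)| −
|S~CD~(antiparallel)|, a side-by-side RMSD table and linear size trends;
pre-computed summary tables can be supplied in place of reports.

# Problem sizes and limitations

The test-suite and acceptance computations use synthetic discs of
240–420 lipids (the studied size range) with 1–80 frames and the
generator's default noise — sizes chosen so the whole suite runs in a
few minutes on one CPU while keeping every estimator in its intended
regime. Known limitations: trajectory-dependent published quantities
(absolute diameters of the simulated systems, the RMSD table, the
ΔS~CD~ curves) require the original trajectories, which are not
deposited, and are represented here by the property-based ground-truth
checks instead; XTC is unsupported; the SASA rotation dependence at 48
points is inherent to fixed point sets; and the 1 kg/m³ diameter
threshold is extreme-value sensitive on sparsely sampled data.
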