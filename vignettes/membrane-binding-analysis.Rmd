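---
title: "Analysing peptide-membrane binding with bilayerbind"
author: "bilayerbind maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing peptide-membrane binding with bilayerbind}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bilayerbind)
```

## The problem this package addresses

Amphipathic peptides such as the 37-residue islet amyloid polypeptide
(amylin) bind to the surface of lipid bilayers before they aggregate, and
how they bind — which terminus touches down first, which helical face points
into the membrane, how the lipids respond — is studied with molecular
dynamics trajectories of a peptide over a hydrated bilayer. `bilayerbind`
re-implements the standard trajectory analyses for this problem as a tested,
reusable package: residue depth profiles, closest-residue adsorption
timelines, geometric hydrogen-bond counting, a cutoff Coulomb plus
Lennard-Jones interaction-energy decomposition, electron density profiles,
the acyl-chain order parameter S~CD~, phosphorus-to-phosphorus membrane
thickness (global and local), area per lipid, and a four-class rotational
classifier for the binding orientation of the helix.

Because deposited trajectories rarely exist for published peptide-membrane
studies, the package also ships a synthetic-data module that builds
idealized bilayers and helical peptides with *known* ground truth, plus
scripted (kinematic) trajectories. Every analysis can therefore be verified
against analytic construction values without running molecular dynamics.

## Conventions

* Internal units are nm, ns, kJ/mol, degrees and elementary charges.
  Angstroms appear only at I/O boundaries (PDB files are converted on
  load).
* The depth reference is the mean z-position of the lipid phosphorus atoms
  of the leaflet the peptide faces (the *proximal* leaflet); depth is
  positive on the water side. Density profiles instead use the bilayer
  midplane as z = 0.
* A residue's position is the unweighted geometric centroid of its selected
  atoms; the mainchain is N, C&alpha;, C, O. Centroids are unweighted
  because none of the analyses here require mass weighting and the simpler
  convention is reproducible without a mass table.
* Boxes are orthorhombic; minimum-image displacements fold each component
  into (-L/2, L/2] (the boundary goes to +L/2, so behaviour at exactly half
  a box length is deterministic). Triclinic input is rejected.
* Molecules that straddle a periodic boundary are unwrapped sequentially
  along the atom order (each atom placed by minimum image relative to its
  predecessor), which stays correct even when a molecule is longer than
  half the box — an anchor-based unwrap would fold it.

## The analyses and their tunable parameters

### Adsorption and contacts

A residue counts as *adsorbed* when its centroid depth stays below a
threshold for a minimum dwell time. Neither number has a community-standard
value, so both are explicit parameters: threshold 0.3 nm above the proximal
phosphorus plane and dwell 1 ns by default. The initiating region reported
by `adsorption_report()` is N-terminal (residues 1-19 by default) or
C-terminal (20-37), whichever contains the earliest-adsorbing residue.
Contacts (`contact_count()`) are heavy-atom pairs within 0.45 nm by
default — a common literature convention, configurable.

### Hydrogen bonds

`detect_hbonds()` implements the widely used geometric criterion: a
donor-hydrogen-acceptor triple is a hydrogen bond when the donor-acceptor
distance is below 0.35 nm, the hydrogen-acceptor distance below 0.25 nm and
the D-H...A angle above 150 degrees. Two deliberate choices:

* The angle vertex is at the **hydrogen**. Some MD tools measure at the
  donor instead; exact parity with those tools is not claimed.
* Donor/acceptor capability is a per-atom flag in the parameter sidecar
  rather than hard-coded to N and O, so lipid hydroxyl donors (e.g.
  glycerol headgroups) and peptide acceptors are all countable.
  `hbonds_by_lipid_group()` counts both directions (peptide as donor and as
  acceptor) by default.

Hydrogens are paired with their donor heavy atom through the topology; at
file load the pairing is inferred from geometry (nearest heavy atom of the
residue within 0.12 nm). Polar hydrogens must be present in the input —
there is no hydrogen reconstruction for hydrogen bonding, since united-atom
force fields retain polar hydrogens.

### Interaction energies

`group_interaction()` sums plain-cutoff Coulomb (1.2 nm) and C6/C12
Lennard-Jones (1.4 nm) terms over cross-group atom pairs under minimum-image
distances, with geometric-mean combination of the per-atom C6/C12
parameters. For pairwise-additive potentials this cross sum *is* the group
interaction energy U(A+B) - U(A) - U(B); the test suite asserts that
identity numerically. Three caveats are intentional:

* No Ewald/reciprocal-space electrostatics, reaction field or dispersion
  correction: reanalysis energies here are for signs and rankings (e.g. the
  early repulsion between a cationic residue and a choline-topped
  zwitterionic bilayer), not for reproducing an MD engine's absolute
  numbers.
* No intramolecular terms or 1-4 exclusions ever arise, because only
  cross-group pairs between disjoint groups are summed.
* Energies are instantaneous per frame; window means and error bars are the
  caller's job. Note that scripted (kinematic) trajectories ignore sterics,
  so deeply inserted scripted poses can produce arbitrarily large repulsive
  Lennard-Jones values — physically meaningful energies require physically
  relaxed coordinates.

### Membrane observables

*Electron density* bins atoms by z relative to the per-frame bilayer
midplane; each atom contributes its atomic number plus one electron per
implicit hydrogen (united-atom CH2 counts 8, CH3 counts 9). The bin width is
a fixed 0.05 nm by default — fixed rather than box-adaptive so results are
deterministic under box fluctuations — and the profile integrates exactly to
the group's electron count.

*S~CD~* is 0.5 &lt;3 cos&sup2;&theta; - 1&gt; with &theta; the angle between
a C-H bond vector and the bilayer normal, averaged over the carbon's C-H
vectors, lipids and frames. For united-atom chains the two methylene
hydrogens are reconstructed assuming ideal tetrahedral geometry from the two
chain neighbours; terminal carbons lack a neighbour and are reported absent,
not zero. An explicit-hydrogen mode bypasses reconstruction. An optional
filter restricts the average to lipids within a 3D minimum heavy-atom
distance (1 nm typically) of the peptide.

*Thickness* is the mean phosphorus z of the upper leaflet minus that of the
lower, averaged over frames. The *local* variant includes only lipids whose
minimum **lateral** (xy, minimum-image) heavy-atom distance to the peptide
is below a cutoff. Laterally, because the quantity of interest is the
membrane column under the peptide: a 3D distance criterion would empty the
distal leaflet for every cutoff smaller than roughly the membrane thickness
and make small-cutoff local thickness undefined. Leaflet membership always
comes from the full bilayer, and an empty leaflet under the cutoff is an
error suggesting a larger cutoff.

*Area per lipid* is the time-averaged lateral box area divided by the
lipids per leaflet.

### Binding orientation

The orientation analysis answers "which face of the helix points into the
membrane", discretized into four 90-degree classes Fd, Fa, Fb, Fc.

1. `fit_helix_axis()` estimates the helix axis of the core helical region
   (residues 8-19 by default) from cross products of successive
   C&alpha;-bond-vector differences — on a regular helix those differences
   point radially, so their cross products all point along the axis. This
   estimator is exact for ideal helices of *any* fractional turn count,
   where a principal-component line is biased by the phase distribution of
   the C&alpha;s. A cylinder refinement (minimising the variance of
   point-to-axis distances) then polishes axis and axis point; the axis
   point is the least-squares circle centre of the projected C&alpha;s.
2. `rotational_phase()` defines the phase &psi; as the azimuth — about the
   axis, measured from the downward (membrane-ward) direction with the
   right-hand rule — of the *anchor face*: the mean radial direction of the
   anchor residues' side-chain centroids (residues 11, 15, 19 by default,
   so the pose with those side chains membrane-facing has &psi; = 0 and is
   class Fd). The depth-weighted radial resultant
   &Sigma; max(0, z&#772; - z~i~) u~i~ over the core residues is computed
   alongside: if it vanishes the side-chain depth profile is flat, there is
   no membrane-facing asymmetry, and the phase is reported as an error. We
   do not use the depth-weighted direction itself as the phase, because for
   any bound helix it simply points membrane-ward — it is (nearly) invariant
   under rotating the peptide about its own axis and therefore cannot
   separate the four classes; the anchor-face azimuth rotates one-to-one
   with the molecule. Both ingredients appear in the per-window confidence.
3. `classify_orientation()` evaluates &psi; per frame over an analysis
   window (the final 20 ns by default), combines frames by circular mean,
   and maps the mean to the quadrant classes with fixed boundaries at 45,
   135, 225 and 315 degrees; successive +90-degree rotations advance the
   class cyclically Fd &rarr; Fa &rarr; Fb &rarr; Fc. The quadrant width is
   not configurable: four classes partition the circle, and changing the
   width would change the class system. A peptide with no residue inside
   the adsorption threshold anywhere in the window is reported "unbound".
   The cyclic labels Fa/Fb/Fc beyond the anchored Fd are a package
   convention (anchored by the rotation sense of `build_initial_states()`),
   since only the Fd face is pinned to named residues.

`build_initial_states()` constructs the four standard starting
configurations: helix axis parallel to the membrane, a chosen reference
residue's side chain pointing at the bilayer, minimum peptide-lipid
heavy-atom separation of at least 1.4 nm, rotated copies at 90-degree steps
about the helix axis. The construction is deterministic.

## The synthetic-data module

`generate_bilayer()` builds a planar two-leaflet bilayer of pseudo-atom
lipids (about 12 sites each: a head site, phosphorus, two ester sites, one
all-trans zigzag acyl chain) on a lateral grid whose box area realizes the
target area per lipid exactly. Defaults describe a fluid
phosphatidylcholine-like membrane: 2 x 64 lipids, area per lipid
0.616 nm&sup2;, phosphorus-to-phosphorus thickness 3.67 nm, choline above
phosphate above ester layering, headgroup z-jitter 0.1 nm, chain tilt 30
degrees. A phosphatidylglycerol-like style swaps the choline site for a
glycerol site that can donate and accept hydrogen bonds and removes the head
charge. Three construction details matter for testing:

* Chain-tilt and zigzag azimuths are deterministically stratified over the
  lipids of each leaflet (not drawn i.i.d.), so orientational averages are
  exact rather than sampled: with all chains tilted at the magic angle,
  S~CD~ is zero to machine precision, and for an ideal zigzag the closed
  form S~CD~(&tau;) = 0.5 (3 sin&sup2;&tau; / 2 - 1) (`scd_ideal_chain()`)
  holds exactly at every interior carbon.
* The lower leaflet is the bit-exact z-mirror of the upper-leaflet
  construction, so electron-density symmetry about the midplane is exact by
  construction at zero jitter.
* An optional Gaussian dimple thins both leaflets under the box centre,
  emulating peptide-induced local thinning for the local-thickness
  analysis.

`generate_peptide()` builds an ideal &alpha;-helix (rise 0.15 nm, twist 100
degrees per residue) with a reduced per-residue geometry — backbone N,
C&alpha;, C, O near the helix radius, an amide hydrogen, and the side chain
as a single radial stub site plus a polar hydrogen where the residue type
donates. The default sequence is the 37-residue human amylin sequence with
charged Lys1/Arg11 side chains, a charged N-terminus and an amidated
(neutral) C-terminus, giving net charge +3. The rotational phase of the
anchor face is a placement parameter, recovered exactly by the orientation
analysis.

`generate_scripted_trajectory()` moves the rigid peptide over the bilayer
along piecewise-linear schedules for the depth of its two helix ends and its
rotational phase, and can plant hydrogen bonds by relocating lipid acceptor
atoms onto ideal geometry (D-A 0.30 nm, H-A 0.20 nm, angle 180 degrees —
strictly inside the default criterion). The default script emulates
C-terminal-first adsorption: the C-terminal end reaches the surface at 12 ns
and the N-terminal end at 50 ns. The ground-truth record carries the true
phase per frame, per-residue centroid depths computed by construction
arithmetic, planted bond counts, and the per-residue first-adsorption times
implied by the threshold/dwell rule.

**What the generator does not emulate.** There are no forces: scripted
trajectories are kinematics, so nothing relaxes, lipids do not respond to
the peptide, and steric overlap is possible in deeply inserted poses. There
is no solvent, no ions (beyond an option for selection tests), no thermal
disorder beyond the headgroup jitter and tilt distribution, no protrusions,
no sn-2 chain and no chemically complete lipids. Passing tests therefore
demonstrate that the *analysis* code measures what it claims on coordinates
whose answer is known — they do not demonstrate anything about force-field
accuracy or sampling of real membranes.

## Numerical choices and degenerate inputs

* Ties in the closest-residue arg-min go to the lower residue index.
* A phosphorus set that cannot be split into two leaflets is an error, as
  is a donor-capable heavy atom without an attached hydrogen (named in the
  message), overlapping groups where disjointness is assumed, and a frame
  count mismatch between trajectory and topology.
* The helix-axis fit requires at least four C&alpha;s and falls back to a
  least-squares line for degenerate (near-collinear) geometry; phase
  analysis refuses axes tilted more than 60 degrees out of the membrane
  plane, and azimuths are undefined (NA) for a near-vertical axis.
* The GRO writer emits nm with three decimals (the format's precision);
  round-trip tests assert agreement to half the last digit.

## Problem sizes in the test-suite

The tests run idealized systems of 8-64 lipids per leaflet and trajectories
of 2-60 frames, with 100-trial seeded recovery loops for the orientation
classifier and 50-100 random frames for the brute-force oracle comparisons
(hydrogen bonds, contacts, pair energies). These sizes were chosen as the
smallest that exercise every code path — periodic wrapping, both leaflets,
multi-frame averaging — while keeping the whole suite fast; all analyses
scale to full-size systems (2 x 64 lipids and beyond) unchanged, and the
default generator parameters are the full-size study conditions.

## Known limitations

* Electrostatics is cutoff-based; absolute interaction energies differ from
  Ewald-based engines by construction.
* The hydrogen-angle convention (vertex at H) differs from donor-vertex
  tools; counts can differ near the 150-degree boundary.
* S~CD~ hydrogen reconstruction assumes ideal tetrahedral methylenes; a
  double-bond-specific convention for unsaturated carbons is not
  implemented.
* Only orthorhombic boxes are supported.
* XTC/TRR binary trajectories are not read; use multi-frame GRO or
  multi-model PDB.
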