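---
title: "Geometric reactivity and chain-length selectivity of DHHC acyltransferases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometric reactivity and chain-length selectivity of DHHC acyltransferases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acylselect)
```

## The model

DHHC acyltransferases autoacylate on a catalytic cysteine using acyl-CoA
as the fatty-acid donor. In hDHHC20 the four transmembrane helices form a
teepee-shaped cavity whose extracellular closure ("ceiling", the
Ser29/Val185/Ser217 triad) stops the acyl tail; the DHHC motif with Cys156
sits at the membrane–cytosol interface at the cavity bottom. Since the tail
tip always rides against the ceiling, chain length translates directly
into the geometry available for nucleophilic attack on the thioester
carbonyl. `acylselect` reduces that mechanism to three per-frame scalars:

* `D1 = Z(terminal acyl C) − Z(ceiling COM)` — cavity fitness. The ceiling
  COM is mass-weighted over all heavy atoms of the triad. `D1 < 0` means
  the tail has not overcome the ceiling.
* `D2 = |Nu − C(carbonyl)|` — the attack distance, with the nucleophile
  being Cys156's SG, or the Ser156 hydroxyl O in the catalytically dead
  mutant used for crystallography.
* `α_BD` — the Buergi–Dunitz angle, defined as the Nu–C(carbonyl)–O(carbonyl)
  angle with the vertex at the carbonyl carbon. This is the standard atom
  triplet for carbonyl attack; the ideal value for small organic systems
  is ≈107° and can relax toward 90° in enzymes while staying obtuse. The
  complementary Flippin–Lodge angle is out of scope.

A frame is *reactive* when `D2 < 6 Å` (a van-der-Waals contact distance)
and `α_BD > 90°`; *improper* when `D2 < 6 Å` but `α_BD < 90°`. Both
inequalities are strict: a frame exactly at a threshold is neither. This
choice is inconsequential in measure (floating-point frames essentially
never sit exactly on a boundary) but makes the contract unambiguous and
testable.

Reactive fractions across chain lengths (C12–C20) are normalized by their
sum to 100 % to form the in-silico selectivity profile; the same
normalization applied to the improper fractions gives the complementary
acute-angle profile. This is the only normalization that makes the bars
comparable across chain lengths.

## Assumptions about the input

* Frames are pre-centered on the protein: no periodic-image handling is
  performed inside the complex, and distances are plain Euclidean norms.
* The membrane normal is the laboratory Z axis. The bilayer center is
  located as the mean Z of the lipid phosphorus atoms
  (`membrane_frame()`); there is no per-frame bilayer-plane fitting, no
  curved-membrane support. This matches the convention of
  protein-centered, semi-isotropically coupled bilayer simulations and of
  the standard density tools.
* For a crystal structure, which carries no bilayer, the membrane normal
  is stood in by the first principal axis of the transmembrane Cα cloud
  (`orient_by_principal_axis()`), with the sign fixed by requiring the
  ceiling triad above the catalytic residue (the teepee has its bottleneck
  on the extracellular side). D1 values computed this way inherit an
  uncertainty of a few tenths of an Angstrom from this convention, which
  is why the crystal-reference D1 is quoted with a ±0.5 Å tolerance while
  D2 and α_BD (rotation-invariant) carry much tighter ones.
* Residue numbering is author numbering: `resid 156` addresses the
  catalytic position on any topology derived from the deposited
  structures.

## Summary statistics and the conditional average

Per-run tables report the mean ± s.d. of D1 over all frames, but of D2 and
α_BD only over frames with `D2 < 6 Å`. An attack angle measured while the
nucleophile is 15 Å away is meaningless, so the spread of α_BD is only
informative conditionally on proximity. `summarize_reactivity()` implements
this `D2 < 6 Å` reading and exposes `condition = "reactive"` as a switch
for averaging over reactive frames instead — the two readings coincide
whenever close-approach frames are predominantly obtuse. Standard
deviations are sample (n−1); the choice is recorded in the `sd_type`
output field so downstream comparisons are unambiguous. If no frame
satisfies the condition the conditional fields are `NA` with
`conditional_defined = FALSE`, never silently zero.

## Interaction fingerprints

* Contacts: a (protein residue, ligand heavy atom) pair is in contact in a
  frame when any heavy-atom pair is within 4 Å. Hydrogens are excluded —
  an acyl chain's hydrogens would only double-count its carbons.
* Hydrogen bonds: donor–acceptor ≤ 3.5 Å and H–D–A angle ≤ 30°, the
  defaults of the standard GROMACS H-bond tool; hydrogens are assigned to
  donor heavy atoms by covalent distance (≤ 1.25 Å) in the first frame.
  "Lifetime" is occupancy — the fraction of frames satisfying the
  criterion — not a continuous-segment survival time; reported maps keep
  bonds with lifetime > 10 % in at least one trajectory (strict
  inequality).
* π-cation: counted when the cation centroid is within 6 Å of the ring
  centroid and within 45° of the ring normal. These two thresholds are not
  standardized in the literature; they follow common interaction-
  fingerprint practice, are configurable, and are echoed into the output
  manifest.

All thresholds are monotone by construction: loosening any cutoff can only
increase a lifetime, which the property tests assert.

## Density profiles

`density_profile()` assigns each atom's mass to its membrane-frame Z bin
(default 1 Å) and divides by the slab volume using the per-frame box XY
area — the area fluctuates under semi-isotropic pressure coupling, so a
constant-area shortcut would break mass conservation. Profiles are
averaged per frame and then over frames; the integral of the profile times
the box area returns the group mass to numerical precision, which the
tests require at 1e−6 relative. Densities are reported in amu/Å³ with an
optional kg/m³ conversion.

## The synthetic-data generator

`generate_synthetic_trajectory()` emulates the *study conditions*, not the
physics: a four-helix Cα teepee with a full heavy-atom ceiling triad, a
catalytic residue 156 (CYS or the dead SER mutant), a Ser143 hydroxyl
donor, an Arg246 head group, an acyl-CoA-like ligand (carbonyl C1/O1,
chain carbons with 1.53 Å C–C zigzag geometry, pyrophosphate-like
acceptors, a planar adenine-like six-ring), and two leaflets of
pseudo-lipid phosphorus atoms at Z = ±18 Å in a 60 × 60 × 90 Å box.

Per frame, (D1, D2, α_BD) are drawn from truncated normals and *realized
exactly* by placing the nucleophile, carbonyl group and terminal carbon —
placement, not toy dynamics, because exact ground truth beats physical
realism for validation. When a reactive probability is prescribed, each
frame's region (reactive / improper / far) is drawn first and the
truncated normals are conditioned on it, so the ledger's reactive fraction
is an exact Bernoulli realization. Default distribution parameters
(`d2_mean = 5.1 Å`, `abd_mean = 112°`, `d1_mean = −2.1 Å` with spreads of
0.6 Å, 34° and 0.3 Å) describe a representative palmitoyl run securely
bound in the cavity; the benchmark suite prescribes reactive probabilities
(0.05, 0.10, 0.60, 0.30, 0.08) for C12–C20 so the normalized profile must
peak at C16, and improper probabilities (0.70, 0.55, 0.05, 0.30, 0.60) so
the acute-angle profile gives C16 the least weight.

Frames are independent draws by default; an AR(1) coefficient on the
latent Gaussian copula is available to mimic the autocorrelation of real
MD frames, but the recovery statistics are stated for the independent
case. Hydrogen-bond and π-cation geometries are toggled deterministically
(on for the exact leading fraction of frames) so occupancies are recovered
exactly; Bernoulli toggling is available and is then recovered within
binomial error.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: force-field energetics, water and ions, chain
flexibility (only the reporter atoms move), membrane undulations, cavity
exit/entry events of short chains, and autocorrelated sampling noise.
Absolute agreement with published per-run tables requires the deposited
trajectories themselves.

The pseudo-lipid residue name is `POP` (three characters) so multi-model
PDB round-trips stay within strict PDB columns; selections for real
systems simply use the actual lipid residue name (e.g. `resname POPC`).

## Numerical choices

* 2D (D2, α_BD) histograms default to 0.25 Å × 5° bins; the mode is the
  center of the maximal-count bin, ties broken toward the lowest D2 and
  then the lowest angle. Replicate runs may be concatenated before
  binning; summary statistics stay per-replicate.
* Truncated-normal sampling uses the inverse-CDF transform, which is exact
  and keeps seeded runs bit-identical; `sd = 0` collapses onto the mean.
* Kabsch RMSD uses the SVD construction with the determinant correction
  (proper rotations only) and is validated against a hierarchical
  rotation-grid search refined to sub-0.5° resolution.
* GRO files are written at 4-decimal (nm) precision and the reader detects
  the coordinate field width from the decimal-point spacing, so both
  standard 3-decimal and high-precision files round-trip; PDB coordinates
  round-trip at their native 1e−3 Å.
* Degenerate inputs fail loudly: empty selections, multi-atom selections
  where one atom is required, zero-length angle vectors, collinear Cα
  clouds, missing boxes for density, atom-count mismatches between frames
  (reported with the frame index).

## Scale of the validation runs

The acceptance checks run the benchmark suite at 5000 frames per chain
length — large enough that three binomial standard errors separate all
prescribed fractions — with geometry oracles on 1000 random fixtures,
density checks on 400–500-frame slices, and byte-identity checks of two
full pipeline reruns at 200 frames. These sizes were chosen so the entire
validation remains a desk-scale computation.

## Interface

The package is driven from R: `run_analysis()` consumes a `run_config()`
(or a YAML file with the same fields) and writes per-system CSV tables, a
selectivity profile and a JSON manifest echoing every threshold, version
and seed, so no number in a report depends on an unlogged default.
`run_crystal_reference()` measures a single structure. The exported
functions plus `scripts/acceptance.R` are the intended entry points; the
package deliberately ships no shell wrapper, since analyses of this kind
are driven from R sessions and R scripts.

## Known limitations

* Only orthorhombic boxes; no periodic-image reconstruction.
* XTC is not read (convert to multi-model PDB, GRO or DCD); DCD requires a
  separate topology.
* The selection grammar covers name/resname/resid/chain/element/serial
  with boolean composition — no distance-based or within-style selections.
* The crystal-reference D1 depends on the principal-axis membrane-normal
  convention (see above).
* H-bond lifetimes are occupancies; kinetic (continuous-segment) lifetimes
  are not computed.
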