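---
title: "porescope: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{porescope: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(porescope)
```

porescope implements the quantitative structural analyses by which
neurosteroid modulation of the α1β2γ2 GABA-A receptor is characterised:
pore geometry at the M2 gates, ligand pose stability and clustering,
residue–ligand contact fingerprints, pore hydration, upper-ECD spread, and
1-d permeation free energies. This vignette records the models behind each
analysis, the parameters that matter, the numerical choices, and what the
synthetic-data tests do and do not establish about real data.

## Conventions

Structures are atom tables in Å with author-assigned residue numbering
(1-based); atom indices are plain row indices. Trajectories couple one
topology to an ordered frame stack with a sampling interval that defaults
to 0.4 ns, the cadence at which the underlying simulations are typically
sub-sampled for analysis. Alternate locations are collapsed to the
highest-occupancy conformer (ties broken alphabetically) so all geometry is
single-conformer and deterministic. M2 prime numbering maps prime index
*k* ∈ [−2, 20] to residue `anchor + (k − 9)`, where the anchor is the 9′
activation-gate leucine of each subunit class — α1 L264 (so 2′ is V257),
β2 L259 (2′ A252), γ2 L274 in the shipped configuration. Prime arithmetic
refuses ranges crossing insertion codes, since the offset rule assumes
contiguous numbering; a non-leucine anchor only warns, so engineered
constructs (e.g. 2′-serine mutants) remain usable.

The pseudo-C5 pore axis is the principal eigenvector of the inertia tensor
of the five per-subunit M2 Cα centroids; for points on a ring that
eigenvector is the ring normal, which makes the definition robust to
missing side chains. The sign is fixed so the extracellular side is +z,
using an ECD selection when given and otherwise the direction from the
−2′ ring to the 20′ ring. Alignment is idempotent to numerical precision.

## Pore profiling

The profile is the classic maximal inscribed-sphere construction: at each
axial position the largest sphere centred in that plane that touches no
atom, with atom radii from the simple vdW table (C 1.85, O 1.65, N 1.75,
S 2.00, H 1.00, P 2.10 Å; hydrogens excluded by default since deposited
models are heavy-atom). We replace the common simulated-annealing search
with a deterministic coarse grid (0.5 Å) plus Nelder–Mead refinement so
repeated runs are bit-identical; defaults are a 0.25 Å axial step and an
8 Å lateral search disc.

One genuine design decision: near the open channel mouths the
unconstrained per-slice maximum lies *outside* the wall, so by default the
search tracks the lumen — slices are processed outward from a seed slice
and each search is confined to within 2.5 Å of the previous slice's sphere
centre. For fully enclosed sections tracking and the pure disc maximum
coincide (the tests compare both against an exhaustive dense-grid oracle);
tracking only matters where the pore communicates with open space. Gate
diameters are twice the minimal profile radius within ±1.5 Å of a ring's
mean z — wide enough to capture the ring constriction, narrow enough to
exclude neighbouring helix turns. Because the exact parameterisation of
the original pore-profiling runs behind published diameters is not
recorded with the structures, matching printed values is expected at the
±0.5 Å level rather than exactly.

A subtlety the synthetic stand-ins exposed: an inscribed sphere at a
flaring section is clipped by nearby constriction walls, so a wall built
naively at `target + r_C` measures systematically narrow where the profile
is steep. `synthetic_state_channel()` therefore calibrates its spline
control radii by fixed-point iteration until its own analytic
inscribed-sphere profile, evaluated with the same slab rule, reproduces
the programmed diameters; auxiliary controls (a shelf above the −2′ climb,
shoulders around 9′) carry the shape but are not targets. The stand-ins
are labelled synthetic throughout: they exercise the measurement pipeline
at the published geometry, they are not deposited coordinates.

## Ligand dynamics

RMSD traces superpose each frame onto the reference (frame 1, the
experimentally derived pose, by default) over protein Cα atoms — the
agreed convention for "ligand movement relative to the protein" — then
measure RMSD over ligand heavy atoms without refitting. No symmetry
correction is applied; the steroids analysed here have no symmetric heavy
atoms. The crop rule used for agonist-unbinding comparisons (raw values
above 60 Å stored as 10 Å, flagged) ships as a named preset and is off by
default. The z-trace is the mass-weighted ligand COM displacement along
+z relative to frame 1; positive values point to the outer leaflet.

Pose clustering is greedy quality-threshold clustering on the pairwise
ligand-RMSD matrix: repeatedly extract the unassigned frame with the
largest cutoff-neighbourhood as a cluster (ties to the lowest frame index,
making the partition deterministic and permutation-stable), until 10
clusters exist or all frames are assigned; leftovers are noise. The
pairwise matrix is computed after aligning every frame to the common
reference rather than by mutual pairwise fitting — this matches the trace
definition and keeps O(n) superpositions. The cited clustering plugin's
exact objective is not documented, so the greedy neighbour-count rule here
is declared, not inferred; population ordering and memberships on separated
pose groups are what the tests pin down.

## Contacts, hydration, ECD spread

A residue contacts the ligand in a frame iff any residue heavy atom is
within 4.5 Å of any ligand heavy atom. This deliberately aggregates all
interaction chemistry into one reproducible geometric criterion — typed
fingerprints (H-bond, hydrophobic, …) would add parameterised chemistry
without changing the frequency summaries these analyses rest on; the
cutoff is configurable and recorded. Replicate aggregation unions residue
universes with zero-fill and reports sample mean and n−1 sd; the ≥ 50 %
rule is inclusive at the boundary.

Hydration counts distinct water molecules (by residue, so a straddling
molecule counts once) whose oxygen is within 3 Å of any atom of the five
9′ leucines. Distances are plain Euclidean: inputs are expected to be
whole-molecule frames; a minimum-image option is out of scope here.

Upper-ECD spread uses the per-class residue intervals α1 10–45, 66–102,
107–133, 157–180, 200–213; β2 7–43, 62–99, 104–130, 154–176, 194–208; γ2
25–57, 77–113, 119–145, 169–189, 210–223. After Cα alignment to frame 1,
`radial_spread` is the mean distance of the five upper-ECD COMs to their
centroid and is the default reported mode, matching the
spread/contraction language; `com_displacement` (mean |COM_i(t) −
COM_i(0)|) ships alongside because the phrase admits either reading, and
the mode is always recorded. Neither is claimed to reproduce published
spread magnitudes — that would need the underlying ensembles.

## Free-energy post-processing

The module consumes 1-d ion-coordinate samples (optionally with a recorded
bias potential) or an already-estimated profile; running the adaptive-bias
machinery that produces such samples at scale is explicitly out of scope.
Boltzmann inversion is `F(z) = −k_B T ln ρ̂(z)` on a fixed-width histogram
(k_B T = 2.494 kJ/mol at the default 300 K), with weights `exp(+V_b/kT)`
removing a recorded bias, bins under 5 raw counts masked as gaps, and the
offset chosen so the reference window's minimum is zero (the sampled flank
by default, recorded in the result). Barrier height is the in-window
maximum above the minimum of the flanking sampled regions. Profiles follow
the convention of the pore axis in nm with the −2′ gate at 0 and the
extracellular side to the left; the 9′ gate then sits near 1.5 nm.

The Metropolis sampler (uniform proposals, reflecting bounds standing in
for a flat-bottom restraint) is the recovery oracle: the tests require a
programmed 18 kJ/mol double-well barrier back within 1 kJ/mol at 10⁶
samples and harmonic curvature within 10 % at 10⁵. For the 32 kJ/mol
barrier, direct sampling would cross wells only a handful of times per
10⁶ steps, so the analysis workflow samples a flattened potential (¼ U)
and records the applied bias — exercising the same reweighting path that
real adaptive-bias output requires. Bin width 0.08 nm and a ±0.24 nm gate
window keep the top-bin noise (≈ kT/√count) and the max-over-bins bias
both near 0.2 kJ/mol at these sample sizes.

## Synthetic data: what it does and does not show

Generators are pure functions of spec + seed (identical seeds give
byte-identical files). Channels are five chains of carbon pseudo-atom
rings realising a requested radius profile analytically, numbered so the
shipped prime map applies; rings every 0.5 Å with 24 atoms keep the
discretisation bulge of the inscribed sphere below 0.01 Å. Trajectories
add a 12-heavy-atom pseudo-steroid with rigid-body jitter and drift,
probe atoms realising exact per-residue contact schedules, waters realising
exact per-frame gate counts, and five C5-symmetric upper-ECD groups whose
radial breathing scales the spread exactly (the symmetry guarantees the
Cα alignment stays the identity, which is what makes the ×1.1 test exact).

These fixtures establish correctness of the measurements — counting,
geometry, clustering, inversion — under known ground truth. They do not
emulate force-field physics, solvent structure, lipids, or conformational
coupling, so passing them says nothing about whether a given real system
will show, e.g., pore dilation; it says the pipeline will measure such
effects faithfully if present. Analyses of deposited receptor coordinates
run through exactly the same functions once the files are placed under
`inst/extdata/deposited/` (they are not redistributed).

## Problem sizes and numerical notes

The shipped analyses use 1 608-atom channels, 40–200-frame trajectories,
and 10⁵–10⁶-sample chains; each analysis script runs in seconds to a few
tens of seconds on one core. Nelder–Mead refinement uses reltol 1e-10 and
falls back to the best coarse-grid point if refinement does not improve
it, so the profiler can only gain over the grid. Degenerate inputs error
early and specifically: fewer than 3 superposition pairs or collinear
selections, empty gate selections, contradictory contact schedules,
sub-atomic pore radii, all-empty histograms. CSV outputs are written at
fixed 6-decimal formatting so reruns diff cleanly; manifests record
package version, seed and a configuration digest.

## Known limitations

Curved or strongly tilted pores are profiled along a straight axis only;
there is no conductance prediction; cluster error bars and block averaging
for the free-energy profiles are future work; buried-surface-area
reporting for interfaces is not implemented. The CLI surface is the set of
numbered scripts under `analysis/` plus `run_pipeline()`; a standalone
shell tool would add nothing the scripts do not already provide.
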