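---
title: "Methods: models, parameters and design choices in kindyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in kindyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kindyn)
```

`kindyn` analyzes coordinate trajectories of the kinesin motor head bound
to the microtubule. This vignette documents the models each stage
implements, the tunable parameters and their defaults, what the
synthetic-data generators do and do not emulate, and the numerical and
design decisions taken where the methodology left genuine choices.

## Trajectory model and units

A trajectory is an ordered set of frames over a fixed annotated atom
table with uniform time spacing. Coordinates are in Ångström, time in
nanoseconds; the default frame interval is 0.24 ns, the typical save
interval of long production runs of this system. Multi-model PDB is the
interchange format (CHARMM/X-PLOR DCD is accepted for coordinates with a
single-model PDB topology, via bio3d). Because PDB carries no charges,
per-atom annotations — partial charge (e), van der Waals radius,
donor/acceptor flags with attached hydrogens, water-oxygen flags — live
in a sidecar CSV keyed by atom index. This deliberately decouples the
analysis from any force-field toolchain: any code that can emit a CSV can
annotate a topology. Atom indices are 1-based throughout, following R
convention. Stages that need annotations (contacts, hydration) refuse to
run without them rather than guessing.

Rigid superposition is the Kabsch algorithm via singular value
decomposition, restricted to proper rotations (a reflection would be
unphysical for rigid-body motion); selections that are collinear to
within a relative singular-value tolerance of 1e-8 are rejected. The
independent check in the test suite compares the post-fit RMSD with
bio3d's least-squares fitter.

## β-sheet curvature and free-energy landscapes

Sheet Cα atoms are superposed per frame onto a canonical reference and
fit with the quadric $z(x,y) = a_0 + a_1 x + a_2 x^2 + a_3 y + a_4 xy +
a_5 y^2$ by linear least squares (QR; rank-deficient designs error out).
Curvatures are computed from the coefficients as $M = 2(a_2+a_5)$ and
$G = a_4^2 - 4 a_2 a_5$, exactly as printed in the source methodology.
Note the sign convention: for a graph surface at a critical point the
differential-geometry Gaussian curvature is $(4a_2a_5 - a_4^2)$ to
leading order, so this $G$ is its negative — positive for saddles,
negative for bowls. The formula is implemented literally as a
"saddle-point curvature" and the discrepancy documented here rather than
"fixed", so numbers are comparable with the original convention.

`canonicalize_reference()` is exposed as an explicit operation (plane to
*xy* by SVD, center of mass to origin, proper rotation enforced) so a
curvature series is reproducible from any starting pose of the reference.
For strongly curved synthetic surfaces the least-square plane of the
surface itself differs from the generator's *xy*-plane; ground-truth
recovery tests therefore pass the flat anchor grid as the reference. Real
β-sheets are in the gently curved regime ($M \lesssim 0.3$ Å⁻¹) where
this distinction is negligible.

The landscape over $(M^2, G)$ uses a histogram normalized by its maximum
count, $E = -k_BT\ln\rho$, so the modal bin is exactly 0 and empty bins
carry $+\infty$ (excluded from all sums; their merge weights vanish
anyway). Bin edges are user-set, defaulting to 30×30 equal-width bins
spanning the sample range — the methodology states no bin widths, so they
are an explicit parameter rather than a constant. $k_BT$ defaults to 1
(energies in units of $k_BT$). Merging solves the weighted least-squares
problem for the constant shift $\Delta$ in closed form (the count-weighted
mean of the energy differences over jointly occupied bins) and avoids any
iterative optimizer; a brute-force scan over $\Delta$ is used as the test
oracle instead. Frames from replicate simulations are pooled with equal
weight, the simplest defensible choice where the methodology is silent.

## Domain kinematics

The microtubule frame is the orthonormal triad built from the two tubulin
H12 centers of mass ($u_L$), the reference α4 axis ($u_N \propto
u_{\alpha4}\times u_L$), and $u_T = u_L\times u_N$; orthonormality and
right-handedness are enforced to 1e-9. Helix axes are the first principal
component of the Cα set, sign-oriented N→C; this is robust for the short
helices involved, unlike rise-vector averaging, at the cost of a small
finite-length tilt that decays quadratically with helix length (the test
fixture quantifies it). Plane axes (major axis and normal of the
least-square plane of the sheet section) are sign-matched frame-to-frame
so orientation series track continuously through rotations past 90°.
Angles are signed in-plane projections (atan2), reported in (−180°, 180°]
as differences from the reference pose; ω_β is typically negative for
this system's geometry — negating it for display is left to plotting.

Mobility profiles require exactly one Cα per residue. Displacement is the
time-mean distance to the reference-frame position (deformation); RMSD is
by default the fluctuation about the window-mean position (RMSF-like) —
the two are deliberately different statistics, and RMS about the
reference is available behind `rmsd_about = "reference"`. The rolling
mean of mobile-residue displacement applies its threshold (default 1 Å)
per frame; applying it once per residue from whole-window means is a
meaningfully different filter and can be emulated by pre-selecting
residues from `mobility_profile()`. Rolling windows everywhere are
centered and truncated at the edges, specified in ns and converted via
the frame interval.

## Contacts

Defaults follow the printed criteria: hydrogen bonds at a 2.4 Å distance
cutoff, nonpolar contacts where both atoms have |q| < 0.3 e at < 3.0 Å,
occupancy as the fraction of frames formed, a 400-frame (96 ns) rolling
window, 200-frame (48 ns) edge windows with 0.05/0.5 thresholds for
irreversible formation/breakage, and transition times where the rolling
occupancy crosses 0.5 (first crossing scanning forward for formation,
last for breakage). Two ambiguities are resolved as flags rather than
assertions:

* 2.4 Å is geometrically short for heavy-atom donor–acceptor pairs, so
  the default measures donor-hydrogen → acceptor distance against it;
  `mode = "heavy"` applies the number to the donor heavy atom literally.
* Nonpolar detection considers all atoms including hydrogens by default
  (`heavy_only = TRUE` restricts).

Salt bridges are not a separate class — they satisfy the H-bond
criterion. No angular criterion is applied (none is stated). A residue
pair may appear under both kinds independently. Transition-time error on
deterministic step fixtures is bounded by half the rolling window, which
the tests assert exactly.

## Hydration, surfaces, bridges

The water-density grid uses 0.7 Å cubic cells in a box spanning the
reference domains padded by 15 Å — the box is defined by the reference
only, so maps from different trajectories are directly comparable. The
per-cell statistic is binary presence of a water oxygen per frame divided
by the cell volume (a count-based mode exists behind `count_mode`). The
bulk water density threshold is 0.0333 Å⁻³ (the printed unit "Å⁻¹" is
treated as a typo for number density). Blobs are 26-connected components
above k× bulk. MRC export writes standard MRC2014 mode-2 (float32,
little-endian) volumes with the grid origin in the ORIGIN words; the
writer/reader pair is hand-rolled because no installed R package handles
MRC, and round-trips are lossless at float32.

SASA is Shrake–Rupley with a 1.4 Å probe and 960 deterministic Fibonacci
sphere points per atom (errors against analytic sphere/cap references are
within 1% at that density; the lattice makes results exactly
reproducible). Neighbor candidates are found by direct vectorized
distance screening — at the selection sizes this package targets, cell
lists would add complexity without measurable benefit. Default van der
Waals radii are an element-based (Bondi-style) table, overridable per
atom via the sidecar. Buried area is SASA(A)+SASA(B)−SASA(A∪B), symmetric
by construction. Two-water bridges use a single configurable cutoff
(default 3.5 Å, a generous hydrogen-bonding O···O distance; the
methodology states none) for all three legs, counting each unordered
water pair once and imposing no exclusivity between simultaneous bridges.

## Nucleotide geometry

Torsions follow the IUPAC convention (cis = 0, trans = 180°, reported in
(−180°, 180°]); as with any standard torsion they are invariant under
complete chain reversal and negate under mirror reflection. The
eclipsed/staggered angle φ_γ is defined operationally — the methodology
defines it only pictorially — as the minimum absolute torsion over the
nine (β-oxygen, γ-oxygen) pairs about the Pβ–Pγ axis, which for
threefold-symmetric oxygen triples lies in [0°, 60°] (0 = eclipsed, 60 =
staggered) and is invariant to permutations within each triple. Mg²⁺
coordination uses a 2.5 Å cutoff (typical Mg–O first shell; none is
stated), with (1 β, 1 γ) labeled bidentate and (1 β, 2 γ) tridentate,
matching how those terms are used for this system. Named bond angles are
a configurable list of index triples, not hard-coded atom names.

## Synthetic generators: what they do and do not emulate

Each generator produces trajectories whose ground truth is known exactly:
sheets place pseudo-Cα atoms on a prescribed quadric with Gaussian noise
on the normal coordinate only (so least-squares recovery is unbiased);
contact pairs follow prescribed distance schedules or a two-state
telegraph (discrete-time Markov) process with exponential-like waiting
times, whose stationary fraction and integrated autocorrelation time give
closed-form tolerance bands; hydration boxes place hotspot waters with
prescribed per-frame presence probabilities (binomial bands); rigid
bodies follow exact translation/rotation schedules; phosphate fragments
have exact torsions, with Mg placed by sphere intersection at exactly
2.0 Å from the intended coordinating oxygens. All generators are
deterministic under a seed.

They make no attempt at physical realism: no force field, no excluded
volume, no solvent structure, no coupling between the observables that
real trajectories correlate (e.g. sheet curvature and contact states
evolve jointly in a real motor). Passing tests therefore demonstrate the
correctness of the measurement machinery — fits, histograms, detectors,
surface areas — not anything about kinesin biophysics; conclusions about
the real system require real trajectories. Problem sizes in the test
suite and acceptance script (49-anchor sheets over 500 frames,
1000–4000-frame contact traces, 2000-frame hydration runs, ≤100-atom
contact fixtures) were chosen as the smallest sizes at which the
closed-form statistical bands are meaningfully tight.

## Known limitations

No PSF/force-field parsing, protonation inference, or hydrogen placement;
no periodic-boundary unwrapping (input frames must be whole); no PMF
smoothing or error bars; no automated secondary-structure assignment; no
binding-energy pipeline. The per-frame contact detectors are O(donors ×
acceptors) per frame, adequate for selection-scale analyses rather than
whole-system contact maps over very long trajectories.
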