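---
title: "Distance-transform surfaces, hydrogen bonds and headless rendering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distance-transform surfaces, hydrogen bonds and headless rendering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(molscene)
```

molscene turns a protein–ligand complex into analysis products a
docking practitioner needs — triangulated molecular surfaces, putative
hydrogen bonds, a cubic search box, and reproducible PNG figures —
entirely in software. This vignette explains the models behind each
step, the tunable parameters and their defaults, the numerical choices,
and what the synthetic test surface does and does not demonstrate.

## Structure model

PDB and PDBQT text parse into a tidy atom table (one row per
ATOM/HETATM record) carrying coordinates in Å, occupancy, B factor,
element, van der Waals radius, AutoDock type and partial charge where
present, and a per-residue secondary-structure flag in
{helix, sheet, coil} taken from HELIX/SHEET records. Multi-model PDB
(NMR) files keep model 1 only; PDBQT MODEL blocks are all kept, because
there each model is a docking pose — the object of interest — and an
ensemble must have identical atom ordering across models or parsing
fails loudly. Alternate locations are restricted to `' '`/`'A'`, the
simplest deterministic rule. Waters and ions are parsed and retained;
consumers that must ignore them (docking-box detection) filter
explicitly.

Element inference prefers the PDB element columns, then the AutoDock
type map, then an atom-name heuristic in which residue context
disambiguates, e.g., an ALA `" CA "` alpha carbon from a calcium ion.
One Bondi-style radius table is used everywhere (C 1.70, N 1.55, O
1.52, S 1.80, H 1.20, P 1.80 Å, halogens included, default 1.70 Å for
unknowns). Any published set would serve; what matters is that a single
documented table feeds the surface engine, so areas and solids are
internally consistent.

## Surfaces by Euclidean distance transform

The four standard surfaces are defined on a voxel grid:

* **van der Waals (VdW)** — boundary of the union of atom spheres;
* **solvent accessible (SAS)** — the same with every radius inflated by
  the probe radius $r_p$;
* **solvent excluded (SES) / molecular (MS)** — boundary of the region a
  spherical probe cannot reach; morphologically the erosion of the SAS
  solid by $r_p$, which equals the closing of the VdW solid by $r_p$.

The two names denote one surface; what differs is the discrete
derivation, and the package implements both: the *erosion route*
thresholds the exact Euclidean distance transform (EDT) measured inward
from the accessible exterior at $r_p$, and the *closing route* unions
the VdW solid with the accessible-interior voxels no probe center can
reach before surfacing. On every fixture tested the two solids differ on
at most a one-voxel shell, and a `swap_ses_ms` flag exchanges which
label maps to which route, since the naming convention is a choice, not
a property of the algorithm.

**Grid policy.** Spacing starts at `1/target_resolution` (default 4
voxels/Å) and the box encloses all inflated atom spheres plus a
two-voxel margin. No dimension may exceed the cap (default 180): an
oversized molecule coarsens the spacing uniformly rather than cropping
the box, because cropping would truncate the molecule while coarsening
merely lowers resolution. The cap bounds CPU and memory: the worst case
is $180^3 \approx 5.8$M voxels.

**Exact EDT.** Distances are computed with the separable
lower-envelope algorithm on squared distances — three 1-D passes, exact
Euclidean, $O(n)$ per voxel line — with the nearest feature voxel
propagated alongside so every voxel also knows its nearest atom. A
brute-force all-pairs scan is kept in the test suite as the oracle; the
two agree to machine precision on every random mask tried.

**Sub-voxel boundary refinement.** A binary EDT measures distances to
exterior voxel *centers*, which overestimates the distance to the
exterior *region* by a lattice-dependent fraction of a voxel; a naive
half-voxel correction overcorrects, because the nearest exterior center
is usually off the surface normal. Instead the package subtracts, from
each center-to-center distance, the nearest exterior voxel's own signed
SAS distance — exact for points outside a union of spheres — which
tightens the field into a distance-to-surface estimate. With this
refinement a single atom's SES area lands within ~1–3% of $4\pi r^2$ at
4 voxels/Å; solid *masks* (used for the voxelwise nesting guarantee
VdW ⊆ SES/MS ⊆ SAS) deliberately use the uncorrected threshold, which
is what makes the nesting provable.

**Marching tetrahedra.** Isosurfaces are extracted by marching
tetrahedra over the Kuhn 6-tetrahedra decomposition of each cell rather
than the classic 256-case cube table. The decomposition shares face
diagonals between neighboring cells, so the triangulation is crack-free
by construction and has no ambiguous saddle configurations to resolve —
the property that costs the cube table an asymptotic decider. The cost
is roughly twice the triangle count; the benefit is a watertightness
guarantee the test suite checks literally (every undirected edge shared
by exactly two triangles, every directed edge unique). Crossings are
linearly interpolated; vertex normals come from interpolated
central-difference gradients; each vertex inherits the nearest-atom
label of the edge endpoint with the smaller |field value|, which drives
per-atom surface coloring. Values exactly at the isovalue are nudged by
$10^{-9}$, and near-coincident vertices are welded at $10^{-5}$ of the
spacing before degenerate triangles (area < $10^{-12}$ Å²) are dropped
— the weld is what keeps exact grid-vertex hits from opening pinholes.

**Smoothing.** EDT-derived fields carry voxel staircase; a Laplacian
pass (fixed weight 0.5, default 2 iterations for SES/MS, none for the
already-smooth analytic VdW/SAS fields) reduces it without changing
topology. Per-iteration vertex drift is bounded by one voxel spacing,
and interior vertices of a flat patch are fixed points.

## Hydrogen bonds

Detection is purely geometric: every intermolecular donor–acceptor
heavy-atom pair within the cutoff (default 3.5 Å) is reported, sorted
by length, each unordered atom pair once. 3.5 Å is the conventional
donor–acceptor distance criterion; no angular term is applied, both
because hydrogen positions are usually absent from crystallographic
input and because a distance-only rule is what the surrounding workflow
expects. Chemistry comes from two documented, overridable routes: with
AutoDock types, acceptors are `OA`/`NA`/`SA` and donors are N/O heavy
atoms with a covalently attached `HD` polar hydrogen (attachment =
distance < 1.3 Å); without types (PDB, no hydrogens), donors are
backbone N, side-chain N of Lys/Arg/His/Trp/Asn/Gln and hydroxyl O of
Ser/Thr/Tyr, acceptors are every O plus His side-chain N, and hetero
N/O atoms take both roles. Intramolecular pairs are excluded — the
quantity of interest is the receptor–ligand interface. Each bonded atom
yields one label, `chain:resname resseq:atomname`, anchored at the atom.

## Docking box

The binding-site box is the smallest cube covering the largest
co-crystallized ligand — HETATM groups, excluding waters
(HOH/WAT/DOD) and a documented monoatomic-ion/additive list, largest by
atom count with ties to first occurrence — expanded by
`expand_fraction` (default 0.5, i.e. 50%) to reserve conformational
sampling space. Whether to expand the cube or each axis independently
is ambiguous in principle; the cube-then-expand rule is the default
(for a uniform expansion the cube edge is the same either way) and a
`per_axis` flag keeps the rectangular variant. The edge floor (10 Å)
and the no-ligand default edge (20 Å, centered on the protein's
unweighted geometric center) are typical docking search-space
magnitudes, exposed as arguments. Containment uses closed intervals per
coordinate, so an atom exactly on a face counts as inside.

## Rendering

The rasterizer is deliberately minimal and deterministic: painter-free
z-buffer triangle fill with Gouraud shading from a single headlight at
the eye (Lambert, ambient 0.2, two-sided), one-pixel lines and points,
no antialiasing — determinism enables byte-identical PNG regression
tests, which antialiasing heuristics would complicate. Translucent
surface batches (opacity 0.5–1.0) composite back-to-front against the
opaque depth buffer. Perspective and orthographic cameras share a
linear-in-eye-depth buffer; the slab manipulation concept maps to
tightening near/far. The default camera sits on +z at twice the
bounding-sphere radius. Anaglyph stereo renders two views with eyes
displaced ±half the separation along the camera right vector, both
converging on the target, and encodes left-eye luminance in red and
right-eye luminance in green+blue — gray anaglyph avoids the retinal
rivalry of color anaglyph. Labels are drawn with a built-in 5×7 bitmap
font at the projected anchor plus a fixed offset, in serial order.

Representation geometry follows standard conventions: bicolor bonds
split at the midpoint; cylinders default to 0.25 Å radius, 8 sides;
icospheres (subdivision 2, $20\cdot4^s$ faces) rather than UV spheres
for even tessellation; a uniform Catmull–Rom spline with endpoint
duplication and 8 subdivisions per residue threads the Cα trace — it
interpolates its control points, so the curve passes through every Cα
exactly. Ribbons orient by carbonyl-oxygen peptide-plane normals when O
atoms exist and fall back to parallel transport for Cα-only chains; the
B-factor tube scales its radius by $B/\bar B$ per residue. The spectrum
scheme spans hue 240°→0° and the ribbon width defaults to 1.6 Å, both
flags, since any such constants are stylistic.

## Synthetic data: what it shows and what it cannot

All tests run on generators that are closed-form and seeded
(`synth_pdb`, `synth_pdbqt`, `synth_assembly`): a diatomic probe pair,
an ideal α-helix (rise 1.5 Å/residue, 100°/residue, radius 2.3 Å — so
consecutive Cα sit the canonical ~3.8 Å apart), a HETATM blob with
exact per-axis extents, sphere clusters at stated centers, a rigid
multi-pose PDBQT ligand with stated REMARK energies, and a two-complex
assembly emulating a crystal asymmetric unit with two receptor–ligand
copies plus waters. The only pseudo-randomness (blob jitter) comes from
a package-local LCG, so the same spec and seed give byte-identical
files.

These fixtures exercise exact geometric contracts: parser round-trips
to PDB precision, analytic sphere/box areas and volumes, threshold
behavior at exactly 3.5 Å, 50% box expansion, the 180-voxel cap. They
do not contain disorder, insertion codes beyond the default, chain
breaks, assemblies at crystallographic scale, or realistic ligand
chemistry; passing them demonstrates the algorithms' correctness on
their stated models, not robustness to every archival PDB quirk. The
two-complex assembly in particular is a synthetic stand-in: it shows
the chain-counting and largest-ligand machinery behaves as it would on
a real two-copy asymmetric unit, without requiring a download.

Problem sizes in the suite are chosen small — grids of a few dozen
voxels per side for property checks, one deliberately 200 Å-wide
cluster to exercise the cap, 20 random ≤12³ masks against the
brute-force EDT oracle — so the whole suite runs in seconds while still
covering each contract.

## Known limitations

* Distance-only hydrogen bonds over-report relative to angle-aware
  detectors; the chemistry tables are heuristics, not a force field.
* Marching tetrahedra may place tunnels at saddle-like configurations
  one voxel differently than cube-table implementations.
* The signed-distance field is computed by a full atom × voxel scan,
  $O(VN)$; for very large complexes at the 180³ cap this is seconds,
  not milliseconds.
* Affine (not perspective-correct) attribute interpolation in the
  rasterizer; visually irrelevant at molecular fields of view.
* No mmCIF input, no bond-order perception, no hydrogen addition, no
  cavity analysis beyond what erosion/closing produce.
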