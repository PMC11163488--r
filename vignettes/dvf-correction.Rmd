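---
title: "Mechanical correction of displacement fields: models, parameters and design choices"
author: "dvfmend"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechanical correction of displacement fields}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dvfmend)
```

## Scope and conventions

`dvfmend` works with displacement vector fields (DVFs) in the *pull-back*
convention: a point $x$ on the reference grid corresponds to $x + u(x)$
in the moving image, with $u$ in millimetres on an axis-aligned voxel
lattice (identity direction cosines; oblique inputs are rejected at the
I/O layer). All sampling is voxel-centre based. The Jacobian determinant
$J(x) = \det(I + \nabla u(x))$ is computed with central differences in
physical units, one-sided at the grid faces; central differences are
exact for affine fields, so every affine test case has a closed-form
Jacobian. Backward warping samples the source at $x + u(x)$ (trilinear
for images and dose, nearest-neighbour for label masks), which means a
region where $J > 1$ shows *compressed* cells when a rectilinear grid
image is pulled back — the sampling points spread out in the source.

One numerical convention deserves a note: wherever physical points are
binned to voxels (contour rasters, element centroids), rounding is
half-up (`floor(t + 0.5)`), not R's `round()`. Banker's rounding sends
exact half-voxel offsets to the even sublattice, which collapses the
occupancy raster of a half-voxel-translated contour to a fraction of its
voxels and breaks the translation invariance of the matcher.

## The elastic model

Tissue is modelled as isotropic linear-elastic material on a regular
tetrahedral mesh. Each cube of the lattice is split into six tetrahedra
around a fixed main diagonal (Freudenthal/Kuhn subdivision), giving a
conforming mesh whose simplices are the coordinate orderings
$f_{\sigma(1)} \ge f_{\sigma(2)} \ge f_{\sigma(3)}$ of the local cube
coordinates. That identity makes point location and barycentric
interpolation O(1) lattice arithmetic, and it means the lattice has only
six element shapes up to translation — element stiffness matrices are
memoized by (shape class, E, ν), so assembly is a lookup plus a triplet
fill.

Elements are 4-node constant-strain tetrahedra,
$K_e = V\, B^\top D(E, \nu)\, B$. The global system $K d = f$ is driven
purely by prescribed displacements at *driving nodes*; constraints are
applied by exact partitioned elimination (the known $d_1 \dots d_k$ move
to the right-hand side, and the reduced symmetric-positive-definite
system is solved for the free nodes — sparse Cholesky by default, a
conjugate-gradient fallback at relative tolerance $10^{-10}$ for very
large meshes). External forces on driving nodes are carried in the data
model for completeness, but since every forced node is also
displacement-constrained they affect only reactions, never the solution.
Constant-strain elements reproduce affine fields exactly, which gives
the patch tests their $10^{-8}$ mm tolerances.

Material constants follow the values commonly used in biomechanical DIR
modelling: Young's modulus 1 kPa (lung), 10 kPa (soft tissue), 1 MPa
(bone), with Poisson ratios 0.38, 0.45 and 0.49. In a purely
displacement-driven problem only the *ratios* of E matter (verified by a
scale-invariance test); ν controls compressibility and is the parameter
with physical leverage. Each element takes the material of the label at
its centroid's voxel; centroids outside labelled tissue fall back to
soft tissue with a reported count.

## Hybrid correction

`correct_field` keeps a DVF's own organ-surface displacements and
replaces the interior with the elastic solution. Boundary voxels are
label-map surface voxels under 6-connectivity (grid-edge voxels count as
boundary). Each boundary voxel is assigned to its nearest mesh node
(regular-lattice rounding, ties to the lowest index) and a node's
prescribed displacement is the *mean* of its assigned voxels'
displacements. That averaging rule is the one deliberate source of
discretization error: for an affine field it evaluates the field at the
voxel-cluster mean rather than the node, so affine DVFs are reproduced
to the quadrature-offset scale (~0.2 mm at a 5 mm mesh pitch), not to
machine precision.

Two design choices were genuinely open:

* **Mesh-surface anchoring.** Driving only the organ-boundary nodes
  leaves the outer mesh boundary with natural (traction-free)
  conditions, so the solution relaxes away from the preliminary field
  between the organs and the mesh box — and the merged field (elastic
  inside, preliminary outside) jumps at the mesh boundary. By default
  the mesh-surface nodes are therefore also driven, with displacements
  sampled trilinearly from the preliminary field (`anchor_surface =
  TRUE`), which restores continuity and near-affine reproduction.
* **One mesh vs per-organ meshes.** The default scales one mesh over all
  selected structures; `per_organ = TRUE` corrects each structure with
  its own mesh sequentially, for workflows where different preliminary
  registrations are trusted for different organs.

Voxels outside the mesh are returned bit-identical to the input; the
correction is idempotent at the driving nodes to $10^{-6}$ mm.

## Contour matching (CM-FEM)

When no preliminary DVF exists, boundary constraints come from surface
matching. The moving structure is first rigidly translated so its point
centroid coincides with the reference centroid. Each reference point
$r_i$ then considers the translated moving points within
`search_radius_mm` (default 15 mm) and minimizes

$$G(r_i, m_j) + \lambda\, N(r_i, m_j),$$

with $G$ the Euclidean distance in mm ("geometric distance" made
concrete), $\lambda = 1$ by default, and $N$ a Gaussian-weighted
mismatch of binary contour-occupancy rasters over a cubic window
(half-width `neighborhood_radius_vox` = 3 voxels, Gaussian scale
`gaussian_sigma_mm` = 3 mm). Only λ's default has an external reference;
the window defaults were chosen once at the scale of the abdominal
phantoms (2 mm voxels, organs of 15–20 mm semi-axes) and are plain
configuration. Ties resolve to the smaller $G$, then the lower candidate
index. The recorded displacement restores the centroid shift —
`matched original moving point − reference point` — because the FEM
constraints must map reference anatomy onto moving anatomy; the
alternative reading (displacement relative to the translated copy) would
silently discard the rigid component and contradicts the bound
$|u| \le$ radius + |shift| that the correspondence set satisfies.

Two window pairings are implemented because the mismatch sum is genuinely
ambiguous: `"offset"` (default) compares occupancy at corresponding
offsets about $r$ and $m$; `"absolute"` evaluates both rasters in the
window of $r$ only, in which case the similarity term no longer
discriminates between candidates and matching degenerates toward
nearest-neighbour — it is retained behind the flag purely for
comparison. For speed, the binary mismatch decomposes as
$N(r, m) = G_R(v_r) + G_M(v_m) - 2\,C(v_r, v_m)$ where $G_R, G_M$ are
separable Gaussian window sums (precomputed over the grid) and the cross
term only visits window offsets that actually hit the reference raster;
a direct double-loop `local_similarity` remains as the reference
implementation and the two are tested against each other.

Matched displacements are pooled over structures, averaged per nearest
node, and fed to the same elastic solve; the field is zero outside the
mesh. Points with no candidate in range are excluded from the
constraints (with a reported count); an entirely unmatched structure is
an error suggesting a larger radius.

## Evaluation metrics

DSC is computed on voxelized masks; MDA is the *symmetric* mean surface
distance (the directed variants sit behind a flag, since the metric's
name is used in the field for both conventions). Jacobian statistics are
population moments over an ROI plus the fraction inside the
physiological range $[0.8, 1.2]$; structures are flagged at the
conventional QA thresholds MDA > 3 mm or DSC < 0.8. Flags and the range
fraction are descriptive — they rank registrations and are not
acceptance criteria for dose accumulation.

The cohort comparison uses the one-tailed Wilcoxon–Mann–Whitney test on
the U statistic with midranks: exact by enumeration when the pooled
sample has at most 12 tie-free observations, otherwise a normal
approximation with tie-corrected variance and continuity correction. A
degenerate all-equal pooled sample returns p = 0.5 with a warning. The
unpaired test is what the name WMW denotes; a paired Wilcoxon
signed-rank companion is offered separately for per-organ paired designs
without being attributed to anyone. The continuity correction biases
tiny identical samples slightly above 0.5 — visible in the tests, where
the symmetric-null check uses n = 20.

## The phantom generator

`make_phantom` voxelizes ellipsoid "organs" (default three, semi-axes
15–21 mm, all soft tissue) inside a soft-tissue body box, 64³ voxels at
2 mm — abdominal organ scale at MR-like resolution. Ground-truth
deformations are analytic (translation, affine, radial, divergence-free
swirl) with closed-form Jacobians where they exist, and
`deform_phantom` voxelizes the *moving* anatomy through the closed-form
inverse map, so warping the moving masks back through the ground truth
reproduces the reference anatomy up to voxelization.

`corrupt_field` models interior registration error as compactly
supported radial bumps, $u \mathrel{+}= a\,(x - c)\,(1 - (r/R)^2)^2$ for
$r < R$ — $C^1$, zero value and slope at $R$ — placed so the whole
support stays at least `min_depth_vox` voxels inside an organ. The clean
field is therefore bit-exact at and outside every organ boundary, which
is the precondition for the correction study: boundary metrics must not
move. Amplitudes are capped at 1 because a single stronger bump folds
the deformation; bump centres are kept at least one radius apart so the
fold-free guarantee survives superposition of cores (overlapping tails
can still push J slightly negative, which real erroneous DVFs also do).
The defaults (8 bumps of 6 mm radius, amplitude 1) were calibrated once
so the per-organ STD-JD of a corrupted smooth field lands around
0.25–0.45 — the scale reported for intensity-driven DIR in abdominal
organs — and the generator reports the achieved STD-JD per organ so any
configuration can be checked against the scale it is meant to emulate.

What the phantoms deliberately do *not* emulate: image intensities (no
MR simulation — registration inputs here are surfaces and fields, never
voxel intensities), realistic organ shapes, sliding interfaces, or the
error structure of any particular commercial algorithm. Passing the
study therefore shows that the mechanical correction removes interior
error *of the modelled kind* while preserving boundaries; it does not
certify behaviour on patient data.

## The correction study

`run_study` generates n phantoms (default 7, i.e. 21 organs), alternates
translation and mild-affine ground truths (displacements ≤ ~8 mm,
|A − I| ≤ 0.06), corrupts, corrects, and evaluates per organ. One-tailed
WMW tests compare corrected vs preliminary in the improvement direction:
smaller STD-JD, smaller MDA, larger DSC. The expected pattern — and what
the acceptance suite asserts under the fixed study seed — is a highly
significant STD-JD reduction (p < 0.05, mean reduction well above 50 %)
with DSC/MDA p-values above 0.5, i.e. no boundary improvement and no
boundary damage. Problem sizes (64³ grids, 12³-division meshes, 7 × 3
organs) were chosen as the smallest sizes at which organs comfortably
contain the corruption bumps and the mesh resolves organ surfaces;
`mesh_divisions` trades accuracy against cost, and the node count is
configuration rather than a constant because no single lattice size is
canonical.

## Degenerate inputs and edge behaviour

Rejected with named errors: non-finite fields, degenerate mesh boxes
(including coplanar voxel sets with zero margin), near-zero-volume
tetrahedra, insufficient or collinear constraint sets (a collinear set
leaves a rotation free; the solver also reports near-singular reduced
systems), empty masks and empty pooled candidate sets, vector files
without exactly 3 components. Occupancy windows extending past the grid
treat outside voxels as empty. Out-of-extent warp samples take a `fill`
value (dose transfer uses 0 and reports the count). NIfTI headers store
voxel spacing as 32-bit floats, so grid metadata round-trips bit-exactly
only for float32-representable spacings; MetaImage headers are text and
round-trip at full precision, and fields are stored as float32 in both
formats (~10⁻⁶ mm round-trip error at these magnitudes).

## Known limitations

Linear (small-strain) elasticity only: corrections of multi-centimetre
displacements with strong rotation are outside the model's validity even
though the solver will happily produce them. The mesh is a box, not
organ-conforming; material boundaries are staircased at element
resolution. Contour matching assumes the centroid translation captures
the rigid component — no rotation/scale pre-alignment. Dose transfer is
voxel-count trilinear warping without mass/energy conservation and the
DVH has no partial-volume weighting; both are comparison tools, not
accumulation-grade dosimetry.
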