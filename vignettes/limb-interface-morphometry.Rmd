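---
title: "Quantifying interface-induced residual-limb deformation from surface models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying interface-induced residual-limb deformation from surface models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(limbmorph)
```

## The measurement model

`limbmorph` treats interface fit as a geometry problem. Two surfaces per
interface condition, both segmented from the same image volume and
therefore expressed in one scanner frame in millimetres, carry all the
information used:

* the **hard-tissue surface** — the separately segmented bones and the
  meniscus/patellar-tendon assembly compiled into one triangulated model
  (`merge_meshes()`: concatenation, no boolean union, no vertex welding —
  exactly what compiling segmentation exports into a single STL does);
* the **skin surface** — the outer boundary of the soft-tissue
  segmentation.

Changes in the bone-to-skin distance between interface conditions indicate
soft-tissue deformation. Two complementary readings are computed.

**Nearest-vertex distance field.** For each hard-tissue vertex the nearest
skin vertex is found (`nearest_vertex_distances()`), giving a directed,
asymmetric field: `d(A→B) ≠ d(B→A)` in general, and the package never
assumes otherwise. Distances are summarised as a 100-interval histogram
normalised to percent of source vertices, so two scans with different
triangle densities can be overlaid. Vertex-to-vertex is the primary mode
because the protocol this implements is defined at vertices;
`nearest_triangle_distances()` provides the point-to-facet alternative so
users can quantify the (always one-sided: facet ≤ vertex) discrepancy
between the conventions.

**Signed skin-to-skin offsets.** After registration, for each reference
skin vertex `v` with outward area-weighted normal `n(v)` and nearest
other-condition vertex `w`, the offset `(w − v)·n(v)` is negative where
the other skin lies inward — the other interface more compressive — and
positive where the fit is more relaxed. An unsigned distance cannot carry
this direction at a vertex, which is why the signed projection is computed;
the unsigned value is retained alongside. `bidirectional_comparison()`
repeats the computation with the roles swapped and flips the second map's
sign so one colour convention holds on both surfaces.

## Registration

Conditions are aligned on a common bone (the tibia in a transtibial limb,
though any mesh is accepted so sensitivity to that choice can be tested):

1. `landmark_rigid_fit()` — orthogonal-Procrustes/Kabsch least-squares
   rotation + translation from paired landmarks (default protocol: 10
   pairs at recognisable features and the bone extremities). Reflections
   are excluded by a determinant correction: anatomy must never be
   mirrored, even when mirrored input would fit better. Collinear
   landmarks are rejected as degenerate.
2. `icp_refine()` — point-to-point ICP on vertices from the landmark
   initialisation. The trace records the post-update RMS under each
   iteration's own correspondences; that quantity has the classical
   monotone non-increase guarantee, which the test suite asserts. A
   subsample (default cap 5000 points) is drawn once per call from a
   seeded local RNG stream, so results are reproducible and the guarantee
   survives subsampling. A correspondence-rejection cutoff
   (`max_pair_distance`) is available but off by default, because a
   changing correspondence set voids the monotonicity guarantee.
3. `hausdorff_report()` — registration quality. The absolute bidirectional
   Hausdorff distance is the larger of the two directed maxima of nearest
   distances; the *average* variant is not standardised in the mesh
   literature, so the package adopts the common symmetric convention — the
   mean of all nearest distances pooled over both directions — and its
   invariants (swap symmetry, average ≤ absolute) are tested.

## Trimming

Analysis should cover only tissue encapsulated by the interface.
`anatomical_trim_plane()` builds one plane a fixed offset (default 50 mm)
proximal to the most distal vertex of a reference surface, and
`trim_by_plane()` applies that same plane to every surface of the scan, so
skin and hard tissue are cut at exactly the same level. Triangles crossing
the plane are split at their exact edge–plane intersections (shared cut
vertices cached per edge), rather than dropped whole, keeping the cut
boundary bit-consistent between surfaces; the cut is left open, because a
cap would add fictitious skin area to the histogram. The proximal–distal
axis is not derivable from an STL, so the distal direction is an explicit
input; the default `(0, 0, −1)` reflects the convention of axial image
stacks ordered along z. For the phantom, which is generated entirely
within its "socket", the pipeline accepts `trim_offset_mm = NULL` to skip
trimming.

## The phantom and its deformation presets

`generate_phantom_limb()` builds an axisymmetric stand-in for a
transtibial residual limb: a tapered skin envelope (proximal radius 50 mm,
distal 40 mm over a 160 mm shaft, hemispherical distal cap, flat proximal
face) around a capsule bone (radius 15 mm; distal cap centre at
z = 25 mm so the bone tip clears the skin cap; proximal tip 10 mm below
the proximal face, leaving a soft-tissue pad as at a scan cut-off). The
payoff of this simplicity is closed-form truth: over the shaft the radial
clearance is `r_skin(z) − r_bone`, and every distance computation in the
package is checked against it to within one mesh edge length, with a
two-resolution convergence test confirming the error shrinks as the mesh
refines. Default resolutions (64 vertices per ring, 48 axial stations,
about 3000–4300 vertices per surface) keep that edge length near 4 mm and
the full test suite under a few seconds.

`apply_socket_deformation()` moves each skin vertex radially inward by a
uniform compression plus Gaussian indentation patches placed in surface
coordinates (axial position, angular position, isotropic sd in mm along
the surface). The displacement tapers linearly to zero within 8 mm of the
limb axis so vertices near the distal pole cannot cross it, and the
deformed surface is checked against the bone profile — a violating spec is
refused naming the culprit patch. The *exact* applied field is returned,
which is what makes the signed-comparison recovery test quantitative
(Pearson r > 0.95 and mean absolute error below one edge length,
mid-surface, boundary-flagged vertices excluded).

The two presets encode the casting philosophies as displacement fields:

* **hands_off** — pressure-cast: 2 mm uniform radial compression, no
  patches. Hydrostatic capture compresses mildly and near-uniformly.
* **hands_on** — patellar-tendon-bearing rectification: a 3 mm global
  volume reduction (clinician-rectified casts remove more volume overall)
  plus the classic localized features — patellar-tendon bar and popliteal
  depression (z = 115 mm), medial and lateral supracondylar depressions
  (z = 125 mm), all 6 mm deep with 25–30 mm sd, and a narrow 2 mm
  *relief* (negative amplitude) over the distal tibial end. Patch depths
  were placed where the phantom's soft tissue is deepest, so rectification
  compresses deeper where there is more tissue to displace and depths are
  evened toward the distal minimum — which is precisely the mechanism that
  makes a rectified interface's depth histogram peak both taller and
  further left than the pressure-cast one. That qualitative signature
  (taller, left-shifted modal bin; more volume at shallow depth) is
  asserted by the acceptance tests on the default phantom.

What the phantom does **not** emulate: real anatomy is not axisymmetric —
in a genuine transtibial limb the anterior tibial crest runs millimetres
below the skin, producing the very shallow (~1–2 mm) depths where strain
risk concentrates, while the phantom's centred bone keeps clearances above
~10 mm; there is no liner, no muscle/fat heterogeneity, and its
deformation fields are kinematic prescriptions, not mechanics. Passing
tests therefore demonstrate the *measurement pipeline* is correct to
analytic truth, not that any clinical claim generalises.

## Numerical choices

* **STL welding** (1e-6 mm, grid snap): STL stores a facet soup; snapping
  to a tolerance grid before grouping makes the recovered shared-vertex
  mesh independent of facet order. The tolerance is orders of magnitude
  below voxel size, so anatomy is untouched. Stored facet normals are
  ignored; orientation is carried by winding.
* **Histogram binning** is right-closed: a value exactly on an interior
  edge belongs to the bin closing at that edge, the range minimum joins
  the first bin, so `{1,2,3,4}` over `[0,4]` in 4 bins gives 25% each.
  Distances outside an explicitly supplied range are counted in the
  nearest end bin, keeping percent mass at exactly 100. An all-constant
  field with no explicit range is refused rather than guessed.
* **Tie-breaking** is deterministic everywhere: equidistant nearest
  neighbours resolve to the lowest target index (the KD-tree prunes
  strictly so it agrees bit-for-bit with the exhaustive oracle — both
  paths accumulate the squared distance in the same operation order, and
  the compiled code forbids fused-multiply-add contraction), ties in
  `extreme_point()` and in the modal bin go to the lowest index.
* **Boundary flagging**: skin vertices within one median edge length of an
  open (trim) boundary are flagged; their nearest-neighbour matches can
  cross the open rim, so they are excluded from summary statistics while
  remaining visible in heat maps.
* **Binary STL** quantises coordinates to IEEE float32 (~7 significant
  digits, sub-micrometre at limb scale); tests compare round trips at
  1e-4 mm.

## Problem sizes and runtime

The default phantom (about 2900 hard-tissue and 4300 skin vertices) is
used for the analytic-clearance, signature and recovery checks; oracle
equivalence runs on eleven fixture pairs of at most 500 vertices each;
the Monte-Carlo landmark-noise study uses 100 seeded trials of 10
landmarks; end-to-end determinism uses a 32 × 24-resolution phantom. The
entire suite and the acceptance script each complete in well under a
minute on one CPU.

## Known limitations

* Vertex-count normalisation does not correct for vertex *density*
  differences across a surface; area-weighted histograms would, and are a
  natural extension.
* Point-to-point ICP with landmark initialisation has no global search; a
  grossly wrong landmark set can converge to a wrong basin (the Hausdorff
  report is the guard).
* The signed offset uses the nearest vertex, not the nearest surface
  point, so on coarse meshes the sign can flip for offsets much smaller
  than an edge length.
* Heat maps are exported as per-vertex scalars in ASCII PLY for standard
  viewers; no in-package 3-D rendering is attempted.
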