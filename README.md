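# limbmorph

Surface morphometry of the residual limb for prosthetic interface
comparison.

After a lower-limb amputation, the fit of the prosthetic interface (socket
plus liner) decides how load is transferred into the residual limb's soft
tissues; a poor fit causes discomfort and tissue injury. `limbmorph`
implements a geometry-based way of quantifying how an interface deforms
those tissues, working entirely from segmented surface models (STL) of the
limb imaged while the interface is worn:

1. **Bone-to-skin nearest-distance analysis.** For every vertex `v` of the
   compiled internal hard-tissue surface, the nearest skin-surface vertex
   `w` is found and the directed distance `d(v) = min_w ||w − v||` computed.
   The distances are split into 100 equal intervals and normalised to
   percent of source vertices, so distributions from scans with different
   vertex counts overlay on a single graph. A deeper-compressing interface
   shifts this distribution left; a more localized rectification makes it
   peakier.
2. **Registered, signed skin-to-skin comparison.** The two conditions are
   aligned on a common bone: a landmark-based orthogonal-Procrustes
   (Kabsch) rigid fit from 10 paired points, refined by point-to-point
   iterative closest point (ICP), scored by the absolute and average
   bidirectional Hausdorff distances. For each skin vertex `v` with outward
   normal `n(v)` and nearest vertex `w` on the other condition's skin, the
   signed offset `(w − v)·n(v)` is negative where the other interface is
   more compressive and positive where it is more relaxed, and is exported
   as a per-vertex heat map (PLY).

Because clinical MRI-derived surfaces are rarely shareable, the package
ships a parametric transtibial **limb phantom** — a tapered soft-tissue
envelope around a capsule bone with closed-form bone-to-skin clearance —
plus deformation presets emulating a hands-on (patellar-tendon-bearing
rectification: localized indentations) and a hands-off (pressure-cast:
near-uniform compression) interface, with the exact per-vertex displacement
field returned as ground truth. Every analysis step is validated against
this analytic truth.

Intended users: prosthetics and rehabilitation-engineering researchers
processing segmented limb surfaces, and methodologists who need a
reproducible, self-validating reference pipeline for surface-to-surface
distance mapping.

## Worked example

```r
library(limbmorph)

# synthetic study: one limb, two interface conditions
phantom   <- generate_phantom_limb(phantom_spec())
hands_on  <- apply_socket_deformation(phantom$skin, deformation_spec("hands_on"))
hands_off <- apply_socket_deformation(phantom$skin, deformation_spec("hands_off"))

# method 1: nearest-distance histograms on a shared range
d_on  <- nearest_vertex_distances(phantom$hard, hands_on$deformed)
d_off <- nearest_vertex_distances(phantom$hard, hands_off$deformed)
shared <- c(0, max(d_on$distance, d_off$distance))
glance(distance_histogram(d_on,  range = shared))
#>   n_bins n_source_vertices modal_bin_lower_mm modal_bin_upper_mm modal_percent
#> 1    100              2946               24.3               24.7          17.7
glance(distance_histogram(d_off, range = shared))
#> 1    100              2946               24.7               25.1          6.52
```

The hands-on condition concentrates 17.7% of the bone surface in one
0.39 mm depth interval starting at 24.3 mm, while hands-off peaks lower
(6.5%) and further right (24.7 mm): the rectified interface compresses a
larger tissue volume to a smaller common depth — the classic contrast
between the two casting philosophies.

```r
# method 2: register the bone across conditions, then compare the skins
perturbed <- apply_rigid_perturbation(phantom$hard, max_angle_deg = 5,
                                      max_translation_mm = 3, seed = 1)
marks <- phantom_landmarks(phantom$hard, n = 10,
                           transform = perturbed$transform,
                           sigma_mm = 0.5, seed = 2)
init <- invert_transform(landmark_rigid_fit(marks))
reg  <- icp_refine(perturbed$mesh, phantom$hard, init = init)
glance(reg)
#>   rotation_angle_deg translation_norm_mm   rms_mm converged
#> 1               1.33                1.15 2.10e-14 TRUE
hausdorff_report(apply_transform(perturbed$mesh, reg), phantom$hard)
#> <hausdorff_report: absolute 0.0000 mm, average 0.0000 mm (n = 2946 / 2946)>

cmp <- bidirectional_comparison(hands_on$deformed, hands_off$deformed)
glance(cmp$on_a)
#>   mean_signed_mm min_signed_mm max_signed_mm percent_compressive n_used
#> 1           2.46        -0.963          7.48               0.723   4290
```

ICP recovers the 5°/3 mm misalignment to machine precision, and the signed
comparison shows the hands-on skin lying on average 2.46 mm inside the
hands-off skin (positive offsets on the hands-on reference mean the *other*
condition sits outward, i.e. hands-on is the more compressive interface
almost everywhere). `write_scalar_mesh()` exports any of these fields as an
ASCII PLY heat map; `autoplot()` and `plot_histogram_overlay()` give
ggplot2 summaries.

A file-based pipeline (`cmd_phantom()`, `cmd_distance()`, `cmd_register()`,
`cmd_compare()`) wires the same steps together with provenance JSON, STL in
and CSV/JSON/PLY out, and a thin CLI lives at `inst/cli/limbmorph.R`.

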