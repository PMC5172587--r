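---
title: "Reconstructing bone-marrow microvessel networks from serial sections: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing bone-marrow microvessel networks from serial sections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesselrecon)
```

## The problem

Human bone marrow is vascularized by two largely distinct classes of
microvessels: narrow capillaries (outer diameters down to ~2 um after
immersion fixation) prevailing in pure adipose tissue, and wide,
thin-walled, often flattened sinuses (>= 30 um) draining haematopoietic
areas. Whether and how these classes interconnect is a three-dimensional
question that single sections cannot answer. The input to this package is
a stack of *registered* serial sections (typically 21 sections of 7 um
thickness scanned at 0.28 um/pixel) in which all microvessel endothelia
are stained brown by immunoperoxidase (DAB) against CD34 plus CD141.
`vesselrecon` turns such a stack into quantitative, colored 3D models and
quality-controls them. Registration itself is out of scope: the package
consumes stacks that are already aligned.

## Pipeline overview

1. **Color conversion** (`extract_saturation`): the brown reaction
   product is colorful, the counterstained background nearly achromatic,
   so the HSV saturation channel `S = (max - min) / max` of RGB, scaled
   to 0..255, isolates stain in a single 8-bit channel (also cutting the
   working set from three channels to one: 4.79 GB to 1.60 GB for a full
   3500 x 3500 x 140 block).
2. **Anisotropy compensation** (`interpolate_slices`): in-plane
   resolution is ~25x finer than the section spacing. For each of the
   `n - 1` section gaps, dense optical flow is estimated in both
   directions and flow-warped intermediates are synthesized every
   `target_z` um (default 1 um).
3. **Segmentation** (`apply_chain`): six grayscale volume filters in
   fixed order — *Threshold 70, Close 10, Fill hole, Dilate 3, Close 5,
   Blur 0.33* — turn the noisy stain volume into solid vessel bodies.
4. **Meshing** (`extract_isosurface`, `heal_and_solidify`,
   `taubin_smooth`): an isosurface at the 8-bit midpoint (127.5) is
   extracted with anisotropic spacing applied, healed into closed
   outward-oriented solids, and smoothed with 10 Taubin iterations.
5. **Models**: branch A (`remove_interior`, `filter_components`,
   `shape_diameter`, `colorize_sdf`) colors local vessel caliber — red
   below 12 um, green above 30 um, gradient centred at 16.5 um — after
   removing interior wall remnants and all components smaller than 70 um.
   Branch B (`classify_connectivity`) discards structures under 7 um,
   colors 7-28 um "small structures" red, the largest network light
   blue, further large networks dark blue, the rest green.
6. **QC** (`surface_distance`, `repair_missing`,
   `stage_difference_report`, `overlay_mesh_on_slice`,
   `blind_end_census`): nearest-surface distance maps in both
   directions between the healed reconstruction and the processed model,
   colored blue (identity) to red (>= 10 um); components of the
   reference farther than 10 um from the model are appended back;
   stage-difference panels and model-on-scan overlays support visual
   review.

`run_pipeline()` orchestrates all of this and writes a manifest of
per-stage checksums, so a configuration hash fully determines every
output.

## Optical-flow interpolation

Flow is estimated by polynomial expansion: each image is locally fitted
with a quadratic form under a Gaussian applicability window
(`poly_sigma` 1.5 px), displacement is solved from the change in the
linear coefficients, aggregated over a 21 px box window, and iterated 3
times per level over a 4-level image pyramid. Both forward and backward
fields are computed and intermediates are blended symmetrically,
`I_t(x) = (1 - t) I_1(x - t F(x)) + t I_2(x - (1 - t) B(x))`,
which avoids one-sided ghosting at gap midpoints. Warping plus convex
blending cannot create intensities outside the input range, and
identical neighbouring sections interpolate to themselves exactly.

**Plane-count convention.** Each gap contributes
`z_spacing / target_z` planes: the leading original section plus its
warped intermediates; the trailing original is not emitted (it leads the
next gap; the final section of the stack is dropped). A 21-section stack
at 7 um therefore yields exactly `20 * 7 = 140` planes at 1 um. The
inclusive alternative would give 141; the convention here is chosen for
consistency with the production volume of 140 planes and is asserted by
tests.

## The six-filter chain

* **Threshold 70**: intensities strictly below 70 (of 255) become black;
  values >= 70 are kept unchanged — deliberately a *grayscale* threshold,
  not a binarization, so later stages still see intensity structure.
* **Close 10 / Close 5**: grayscale closing with digital spheres of 10
  and 5 *voxels* radius mends missing wall patches (a radius-`r` closing
  bridges gaps up to about `2r` voxels). Structuring elements are defined
  in voxel units even though voxels are anisotropic; on a
  0.28 x 0.28 x 1 um grid the physical reach is correspondingly larger
  along z. This follows the production definition and is documented
  rather than "corrected".
* **Fill hole**: background voxels (0) not connected to the volume
  border are enclosed lumina; each cavity is set to the minimum positive
  intensity of its enclosing shell. Whether the production operation was
  2D per-slice or 3D is not recorded; both are implemented
  (`fill_holes(per_slice = )`), and the *pipeline default is per-slice
  2D*. The reason is a failure mode of the 3D fill discovered on
  phantoms: when a vessel's end cap falls between two 7 um sections, the
  interpolated wall fades below threshold there, the lumen connects to
  the exterior through the open end, and a 3D fill leaves the entire
  vessel hollow — after which the shape diameter reads wall thickness
  (~6 um) instead of caliber. The per-slice fill closes each intact wall
  ring in-plane and is immune to end leaks; the thin unfilled lens at
  the fading planes is then sealed by the second closing. Solid vessel
  bodies are a precondition for reading vessel *diameter* (not wall
  thickness) from the mesh later.
* **Dilate 3**: grayscale dilation, radius 3 voxels. Together with the
  closings this slightly inflates all vessels; the effect is negligible
  for sinuses and for capillaries counteracts collapse from immersion
  fixation.
* **Blur 0.33**: a final Gaussian blur (sigma in voxels, reflect
  boundary, 4-sigma truncation) smooths the staircase of the binary-ish
  field so the subsequent isosurface is accurate; it is the last stage
  before meshing.

Border handling pads dilation with `-Inf` and erosion with `+Inf`
(out-of-bounds neighbours ignored), the convention under which closing
remains idempotent and extensive — both properties are tested.

## Meshing

Isosurfaces are extracted by marching tetrahedra on the Freudenthal
six-tetrahedron cube decomposition. This variant was chosen over
table-driven marching cubes because it is exactly implementable without
the 256-case tables, tiles the grid consistently (no ambiguous faces),
and with edge-keyed vertex sharing yields watertight surfaces away from
the volume boundary. On smooth fields (which the blur stage guarantees)
the surface area of a radius-25 sphere is reproduced to well under 1%;
on hard binary data any voxel-based extractor overestimates area, which
is why the fixture suite uses anti-aliased analytic volumes.

The production iso-value is not recorded anywhere, so it is exposed in
`pipeline_config(iso_value = )` with default 35 — the midpoint between
background (0) and the smallest intensity the threshold stage retains
(70). The naive 8-bit midpoint 127.5 is *wrong for this chain*: hole
filling writes the shell **minimum** (>= 70 but often well below 127)
into vessel lumina, so an iso-value above the threshold re-excavates
the freshly filled lumina and the final models are hollow shells whose
shape diameter reads wall thickness. With iso 35, everything the
threshold kept — walls and filled lumina alike — is "inside", and the
surface lands mid-way down the blurred wall edge.

Healing interprets "solidify" as a contract: the output is a set of
closed, consistently outward-oriented 2-manifold components. Duplicate
vertices are welded (1e-6 um grid), degenerate faces dropped, windings
made consistent by adjacency propagation (faces at non-orientable
contacts are dropped with a warning), every boundary loop — small
topological defects and the open rims where vessels meet the block
boundary alike — is closed with a centroid fan, and components with
negative signed volume are flipped. Taubin smoothing uses the classical
defaults lambda = 0.5, mu = -0.53 with uniform umbrella weights; 10
iterations change enclosed volume by well under 3% on closed meshes,
whereas the same budget of pure Laplacian steps shrinks an icosphere by
over 5% — the test suite demonstrates the anti-shrink property
comparatively.

## Shape diameter and interior removal

Vessel interiors still contain the inner faces of the original wall
shells. Each vertex gets a volumetric obscurance value: the fraction of
48 low-discrepancy sphere directions whose rays escape the scene.
Enclosed inner-shell vertices score exactly 0, exposed surface points
about 0.5. Vertices under the threshold (default 0.05) are deleted with
their faces; if cut-surface flags are present, deleting a flagged vertex
is treated as a validation failure, which operationalizes the rule that
the visible surface must never be touched.

The shape diameter function casts `n_rays = 30` rays per vertex into the
mesh within a cone around the inward normal and records the **shortest**
hit distance. With that aggregation the cone must be narrow for the
value to read the diameter: on a sphere the shortest ray over a cone of
half-angle `a` is `D cos a` by geometry, so a wide cone *systematically*
under-reads (60 degrees would halve every diameter). The default is
therefore 15 degrees (`cos 15 = 0.966`), which reproduces analytic
sphere and cylinder diameters within 5% in the tests; a robust variant
(median of rays within one standard deviation) is available for noisy
surfaces, and the cone is configurable for users who prefer the wide
cone + median convention of other SDF implementations. The known caveat
is inherited deliberately: broad flat sinuses read their thin dimension
from the broad side and appear capillary-red; the models locate
networks, they do not classify individual vessels.

The SDF colormap is a two-ramp gradient — red up to 12 um, green from
30 um, with the 50/50 blend pinned at 16.5 um (the production gradient
centre, which is intentionally *not* the arithmetic midpoint of 12 and
30; the exact production colormap file is not available, so the two-ramp
construction is this package's concrete reading).

## Component filtering and connectivity

`largest_diameter` is the exact maximum pairwise vertex distance,
computed directly for components up to 20,000 vertices. Larger
components are first reduced to their extreme vertices along 2562
well-spread directions — extreme points are convex-hull vertices and the
hull attains the diameter — giving a bounded (<0.3%) underestimate; no
size threshold in the pipeline sits anywhere near that error. The 70 um
production cutoff is 5% of the space diagonal of a 980 x 980 x 140 um
block (`diagonal_fraction_threshold`), the 7 um connectivity-model
cutoff is 0.5%. The 7-28 um "small structure" band is applied to the
largest diameter of every remaining component, and "largest network" is
ranked by total surface area (vertex count differs negligibly on
uniform meshes; the metric is exposed).

## QC distances and repair

Surface distance is computed exactly (point-to-triangle with a uniform
grid and ring search), not by stochastic ray casting — the ray
description is the intuition, the nearest-point distance is its limit,
and exactness makes the repair contract testable. Repair appends every
connected component of the healed reconstruction whose *minimum* vertex
distance to the processed model exceeds 10 um — the conservative reading
that only fully missing structures are restored — and flags appended
vertices with a `repaired` attribute rather than re-processing them, so
provenance stays visible. After repair, every reference component lies
within the threshold of the output, and repair is idempotent; both are
asserted as exact postconditions.

`blind_end_census` is a reviewing aid only: it lists directional
extreme points whose surrounding surface slab is laterally compact (a
tube cap, not a tube side), excluding caps at the block faces. It feeds
manual review and takes no part in any quantitative result.

## The phantom generator

Real accessioned stacks do not exist for this pipeline, so the package
ships a generator whose output is the test bed for everything above. It
emulates: two vessel classes with disjoint caliber ranges (capillaries
2-12 um, sinuses 30-60 um by default) growing in segregated subdomains
(capillaries in an "adipose" region, sinuses in a "haematopoietic"
region, mirroring the observed spatial segregation and parallel
arrangement); biased random-walk trees (step 10 um, branching
probability 0.15); optional end-to-side capillary-to-sinus anastomoses;
elliptical sinus cross-sections with per-network flatness up to 3:1
extended along z; stained walls of 1.5 um; and the sectioning artefact
taxonomy — unstained wall arcs, capillaries collapsed to ~2 um, and
isolated stained cells that appear in single sections and fuse into
z-elongated red fragments in the connectivity models. Defect-rate
defaults (0.5 wall gaps per 100 um of centerline, 10% collapsed
capillary edges, 5000 cells/mm^3) are plausibility choices: no
quantitative density is recorded for the real specimen, and they are
fixed once here rather than tuned.

Distinct networks are grown in per-network boxes whose margins guarantee
a surface clearance (>= 10 um plus radii) so that the 10-voxel closing
cannot fuse separate networks — fusing them would make the component
count meaningless as a recovery metric, not because fusion could not
happen in reality.

What the phantom does **not** emulate: registration error (registration
is out of scope), bone trabeculae, realistic cell textures,
megakaryocyte background staining, or scanner shading. Passing the
end-to-end tests therefore shows that the *reconstruction machinery*
recovers known geometry and topology under realistic stain contrast,
anisotropy and artefact rates — it does not validate stain chemistry or
registration.

`evaluate_recovery` matches mesh components to truth networks by
majority vote over nearest centerline edges and scores SDF
classification per vertex (capillary below 16.5 um). Vertices whose
nearest edge is a flat sinus (minor axis below 30 um) are exempt from
the headline accuracy, mirroring the method's own documented caveat;
the raw accuracy over all vertices is reported alongside so the
exemption is never silent.

## Problem sizes and determinism

The test and acceptance workloads are desk-scale by design: oracle
equivalences run on 40^3 random volumes (20 seeds), mesh oracles on
meshes up to a few thousand triangles, and the end-to-end phantom on a
256 x 256 px x 21 section block (178.5 x 178.5 x 140 um at 0.7 um/px),
which runs in minutes on one CPU while preserving every production
constant (7 um sections, 1 um interpolation, the full filter chain and
both model branches). All randomness flows through explicit seeds —
generator operations restore the caller's RNG state — and
`run_pipeline` manifests are byte-identical across runs of the same
configuration.

## Known limitations

* The interpolation convention (drop the trailing section) is one
  consistent reading of the production plane count; stacks meant to be
  concatenated should account for the missing final plane.
* Grayscale closing in voxel units smooths more strongly along z after
  interpolation to isotropic spacing than it did on the anisotropic
  production grid; all thresholds stated in um are unaffected.
* Marching tetrahedra produces ~2x more triangles than marching cubes
  for the same grid; meshes are correspondingly heavier but exact.
* The shortest-ray SDF is noise-sensitive near sharp corners; the
  robust variant is available but is not the default because the
  shortest-ray definition is the production behaviour being reproduced.
* `blind_end_census` is heuristic and intentionally excluded from all
  quantitative acceptance checks.
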