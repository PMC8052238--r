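---
title: "Reconstructing multi-tissue aneurysm wall models from serial histology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing multi-tissue aneurysm wall models from serial histology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(histowall3d)
```

## The problem

Rupture risk assessment of intracranial aneurysms leans on simulations of
the vessel wall, but clinical images resolve neither the wall thickness nor
its composition. Postmortem specimens sectioned serially (2 µm sections
mounted every 100 µm), H&E-stained and segmented into tissue texture
classes, do carry that information — as a stack of 2D label images.
`histowall3d` turns such stacks into watertight, per-tissue 3D surface
models and demonstrates, with a small plane-strain finite-element solver,
why the heterogeneity matters mechanically.

Nine tissue texture classes are used (`tissue_classes()`): mixed textures
(1), inflammatory cells (2), myointimal hyperplasia (3), degenerated wall
(4), decellularized organizing-thrombus/MH (5), red thrombus (6),
organizing thrombus (7), white thrombus (8) and intact wall (9). Label
images additionally mark the lumen (10) and optionally the exterior (11).

## Pipeline and assumptions

The stages of `run_pipeline()` are pure functions of their inputs and
configuration:

1. **Ingest** (`read_label_stack()`, `downsample_labels()`). Segmented
   images are piecewise constant, so resolution is reduced by 85% by
   default (`downsample_keep_fraction = 0.15`), with nearest-neighbor
   sampling — any interpolation would invent label values. Isotropic
   pixels are assumed.
2. **Virtual inflation** (`inflate_slice()`). Excised specimens deflate;
   each slice is warped so the lumen contour moves toward its least-squares
   (Kåsa) circle at weight `t = 0.4` of the full projection. The inner
   contour moves radially by `t (R - r(θ))`; inside the wall the
   displacement decays linearly in the normalized radial coordinate to
   zero at the outer contour, which therefore never moves. Labels are
   transported by the exact inverse warp (pull-back, no holes). Rays with
   several lumen crossings use the nearest one and are counted in a
   warning.
3. **Contours** (`extract_contours()`). Per class: 8-connected components,
   Moore-neighbor boundary tracing with Jacob's stopping criterion,
   orientation normalized to positive signed area. Components below 16
   pixels are segmentation noise and are dropped; holes inside a component
   are ignored (a single outer contour cannot represent them) and logged.
   The default-class component that spans the whole annulus is treated as
   background fill, not as a tissue segment: it is exactly the wall volume
   between the inner and outer wall meshes that the FE model fills with
   `default_class`.
4. **Assembly** (`register_slices_cpd()`, `match_contours()`,
   `build_tracks()`, `build_point_clouds()`). Consecutive slices are
   registered with affine coherent point drift on the union of their
   contour points; same-class contours are then matched by center distance
   (≤ 500 µm) and mean corresponding-point distance (≤ 400 µm), greedily by
   increasing center distance (an optimal assignment is available via
   `method = "optimal"`). Chains of matches become tracks; a tissue
   invisible in one slice terminates its track. Contour points lift to 3D
   with `z = slice_index × 100 µm`.
5. **Capping and meshing** (`add_caps()`, `fit_mesh()`,
   `clean_and_filter()`). Truncated segment ends are closed with parabolic
   domes: ring `j` of `k` is the end contour scaled about its thinning
   midpoint by `s_j = sqrt(1 − j/(k+1))` at height `(j/(k+1)) h`, with
   apex height `h` equal to the mean end-contour radius and
   `k = max(2, ceil(h / slice_distance))`. A subdivided icosphere is
   shrink-wrapped onto each capped cloud and Taubin-smoothed; overlaps
   between meshes are resolved by voxel-field boolean subtraction in
   descending volume order, and structures below 1 mm³ are neglected.
6. **Structural demonstration** (`build_fe_model()`,
   `solve_linear_elastic()`, `compare_homo_hetero()`). A plane-strain
   section with per-element tissue classes is solved under intravascular
   pressure (inner boundary traction, free outer surface, symmetry or pins
   on cut planes), once with native materials and once with every element
   forced to intact wall.

## Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| `slice_distance` | 100 | µm | physical slide spacing of the serial sections |
| `downsample_keep_fraction` | 0.15 | — | 85% reduction; label images carry no sub-pixel detail |
| inflation `t` | 0.4 | — | empirically suitable partial projection; `t = 1` would force a perfect circle |
| `max_center_distance` | 500 | µm | contour match gate; calibrated on the phantom for zero false merges |
| `max_mean_point_distance` | 400 | µm | second match gate, shape-sensitive |
| `cpd_max_iterations` | 40 | — | EM cap per registration round |
| `cpd_outlier_weight` | 0.1 | — | uniform mixture component; tolerates ~5% spurious points |
| `min_volume` | 1e9 | µm³ | 1 mm³ structure floor: below simulation resolution |
| `poisson` | 0.45 | — | soft tissue treated as nearly incompressible |
| `pressure` | 13.33 | kPa | ≈ 100 mmHg mean arterial pressure (not specified by the source data; configurable) |

The material table derives the unknown stiffnesses from two literature
values, white thrombus `E8 = 36.44` kPa and intact wall `E9 = 133.9` kPa,
by fixed texture-based rules (`derive_material_table()`): class 1 =
`(E8+E9)/2`, class 3 = `E8/4 + 3 E9/4`, class 5 = `(E3+E8)/2`, class 6 =
`E8/2`. We treat these rules as fixed formulas, not one-off choices, so
the table stays consistent under different literature inputs; full
precision is stored and printing rounds to two decimals. Classes 2, 4 and
7 have no rule: if present in the data they must be given explicitly, and
the model build aborts otherwise — silently guessing a stiffness would
corrupt the simulation.

```{r materials}
derive_material_table(36.44, 133.9)
```

## The phantom: the world the tests live in

`phantom_spec()` generates synthetic stacks with analytic ground truth.
The defaults describe a 20-slice (2 mm) segment of a vessel with a 1 mm
area-equivalent lumen radius and a 450 µm wall, rasterized at 12 µm/px on
300 × 300 px slices — the scale of an aneurysm neck, at the working
resolution after the 85% reduction. Deflation is emulated by an elliptical
lumen whose eccentricity varies smoothly along the stack while preserving
area (so the ground-truth inflated lumen is the circle of radius
`lumen_radius`); three default patches (red thrombus over 5 slices,
myointimal hyperplasia over 3, white thrombus over 8) exercise the
matching stage; optional rigid jitter (≤ 5°, ≤ 50 µm) exercises
registration and is recorded exactly.

What the phantom does *not* emulate: staining artifacts, tears and folds,
texture within classes, smooth class transitions, and non-star-shaped
lumina. A green phantom test therefore establishes that the geometry
processing chain is correct, not that manual segmentations of damaged
sections will track equally well.

## Numerical choices

* **Circle fit.** Algebraic (Kåsa) least squares: linear, deterministic,
  exact on circular data; the RMS radial misfit is reported.
* **Inflation warp.** Defined along rays from the fit center with
  per-angle radius tables (720 bins); the displacement is linear in
  position along each ray, which coincides with linear-in-radius for the
  radial projection used here. The lumen interior rescales
  proportionally so the warp is invertible per ray; the inverse is used
  for label transport. If the fitted circle would cross the outer wall,
  the displacement is clamped to 95% of the local wall thickness and a
  warning counts the affected bins.
* **CPD registration.** Affine CPD EM with the uniform-outlier component,
  on point sets normalized to zero mean and unit RMS (the outlier density
  is scale-sensitive), capped at 600 points by regular stride. Wall
  sections are dominated by concentric near-circular contours, which are
  rotation-degenerate at finite sample spacing: plain EM reliably
  converges to "slid correspondence" optima tens of µm off. The
  implementation therefore alternates a deterministic rotation search
  (mean nearest-neighbor misfit over a 2° full-circle scan, refined at
  0.25°, computed class-by-class when labels are available, with a small
  preference for small rotations that breaks exact symmetry ties) with EM
  refinement, up to three rounds; the first EM round corrects scale so
  the second search is unbiased. σ² is initialized from the mean squared
  nearest-neighbor distance — the misalignment actually present — rather
  than the classical all-pairs distance.
* **Matching.** Greedy by center distance with deterministic tie-breaks
  (mean point distance, then component id); the mean corresponding-point
  distance is minimized over cyclic index shifts because independently
  traced contours have arbitrary start vertices.
* **FEM elements.** Six-node (quadratic) plane-strain triangles with a
  3-point Gauss rule. At ν = 0.45 constant-strain triangles lock
  volumetrically (we measured −9% hoop-stress error on a 5k-element
  annulus, −41% at ν = 0.49); quadratic elements reproduce the Lamé
  thick-cylinder solution to 0.01–0.04% on the same meshes, pass the
  uniform-traction patch test to machine precision, and keep global
  equilibrium to ~1e−13. Full-ring sections pin three displacement
  components at two lumen-axis nodes (reactions vanish for
  self-equilibrated pressure); quarter sections use symmetry constraints.
* **Meshing and booleans.** The shrink-wrap start mesh is a subdivided
  icosphere (level 3; level 4 for the global wall surfaces), pulled toward
  nearest cloud points with uniform-Laplacian regularization until the
  mean vertex step drops below 0.1 µm, then Taubin-smoothed (λ = 0.5,
  µ = −0.53, 10 passes) in place of manual smoothing. Mesh booleans use
  z-directed signed-distance fields on a common grid (96 cells along the
  longest axis by default) combined with max/min and re-extracted by
  marching tetrahedra; meshes that share a subtraction interface come from
  the same field discretization, so residual pairwise overlaps measure
  exactly zero on that grid. Volume accuracy of the voxel route is ~1% at
  the default grid.
* **Cap height caveat.** The parabolic cap rule ties the apex height to
  the mean end-contour radius. For elongated plate-like segments this
  mean radius reflects the arc length, not the thickness, so caps can
  contribute a volume comparable to the slab volume of small patches;
  recovery reports therefore compare *wall* volume on the imaged slab
  (caps clipped) and list per-class mesh volumes without a pass bound.
* **Degenerate inputs.** Collinear circle fits, crossing wall contours,
  label values outside the palette, classes without materials, and
  non-watertight meshes all abort with errors naming the offending
  object; empty slices and empty match sets are valid and propagate as
  empty results.

## Design decisions on open points

* The texture-based stiffness rules are treated as fixed formulas (see
  above), so the derived table is reproducible from any literature pair.
* Wall-interior inflation displacement: linear decay in position along
  rays anchored at the outer contour — smooth, boundary-respecting, and
  reducing to the stated inner-contour interpolation at the lumen.
* Registration is pairwise-sequential with composed transforms (not
  groupwise): it matches the acquisition process, where each slide's
  orientation error is independent.
* Tissue holes/nesting inside a component are logged and ignored at the
  contour level; a single outer contour cannot carry them into meshing.
* Tracks do not skip slices: a segment invisible in one slice terminates,
  consistent with treating the inter-slice gap as the resolution limit.
* Only the 2D plane-strain FEM path is built. The 3D linear-tetrahedron
  variant would require volumetric meshing of the surface models, which
  is out of scope for this package; the homogeneous-versus-heterogeneous
  contrast that motivates the solver is fully exercised in 2D.

## Known limitations

* PNG is the only supported label-image format (lossless 8-bit RGB or
  gray); TIFF inputs must be converted upstream.
* The registration-error report on phantoms with varying lumen
  eccentricity includes genuine shape change, not only registration
  error: affine CPD correctly tracks the slice-to-slice aspect change,
  which accumulates along the stack. Constant-eccentricity phantoms
  isolate the registration error itself.
* Sections whose tissue layout is (near-)rotationally symmetric are
  genuinely ambiguous up to that symmetry; the small-rotation preference
  resolves ties deterministically but cannot recover information the data
  does not contain.
* Shrink-wrapping cannot represent through-holes or strongly non-convex
  segment shapes; such segments mesh as their wrap hull.
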