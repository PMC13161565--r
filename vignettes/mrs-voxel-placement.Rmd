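---
title: "Automated placement of a single-voxel MRS acquisition cube"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated placement of a single-voxel MRS acquisition cube}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Single-voxel proton MR spectroscopy (MRS) measures metabolite signals from
one cuboidal acquisition volume — in routine brain-tumor work a fixed
2 × 2 × 2 cm³ cube. Where that cube is prescribed matters greatly: in diffuse
gliomas, enhancing tumor, non-enhancing infiltrative tissue and necrosis
coexist within centimetres of each other, and necrotic tissue degrades
spectral quality. Manual prescription by technologists is slow and variable.
`mrsplace` automates the geometric part of the task: given anatomical MR
volumes and binary tumor sub-compartment masks (enhancing core and necrosis
on post-contrast T1, whole FLAIR-hyperintense tumor on FLAIR), it searches
over positions and rotations of the acquisition cube and returns the one
that maximizes enclosed enhancing core volume while enclosing no necrosis,
using enclosed whole-tumor volume as a tiebreaker. For lesions without
enhancement, the cube instead maximizes enclosed FLAIR hyperintensity.

Segmentations are *inputs*: in clinical use they come from a trained
segmentation model, and this package deliberately does not include one.
The phantom module generates synthetic inputs so that the entire pipeline
is exercisable and testable without clinical data.

## The procedure

1. **Preprocessing.** All images and masks are brought onto one common
   1 mm isotropic, axis-aligned RAS grid. In enhancing mode the grid is
   anchored to the post-contrast T1 image and the FLAIR image (with its
   whole-tumor mask) is rigidly co-registered onto it; in FLAIR-only mode
   the grid is anchored to FLAIR and registration is skipped. Intensity
   images are resampled trilinearly, masks always with nearest-neighbor
   so that binarity and count-based volumes are preserved.
2. **Search space.** A bounding box is drawn around the target mask
   (enhancing core, or whole tumor in FLAIR-only mode) and padded by
   2√3 cm ≈ 34.641 mm per side; this padded box limits the cube *center*.
   Candidate centers form a lattice with configurable stride inside that
   box, clipped to positions where the cube's circumscribing sphere
   (radius 10√3 mm) fits inside the image. Candidate rotations are all
   triples from {0°, step, …, 90°} about the left/right,
   anterior/posterior and superior/inferior axes, with 90° always
   included.
3. **Scoring.** For each candidate pose, the enclosed volume of each mask
   is the count of its nonzero voxel centers falling inside the rotated
   cube (1 voxel = 1 mm³).
4. **Selection.** Enhancing mode: among placements enclosing zero necrosis,
   maximize (core volume, whole-tumor volume) lexicographically.
   FLAIR-only mode: maximize whole-tumor volume. Remaining ties go to the
   earliest candidate in a fixed deterministic iteration order.
5. **Output.** The chosen cube is rasterized as a NIfTI mask on the input
   grids, together with a JSON report and optional interpretability
   heatmaps showing the enclosed target volume as a function of cube
   center at a fixed rotation, with infeasible positions marked invalid.

## Numerical and design choices

**Half-open cube membership.** A voxel center at cube-frame coordinate
`q = t(R) (x - c)` is inside the cube iff `-s/2 <= q_i < s/2` on every
axis. The half-open convention makes the axis-aligned cube at an integer
center contain exactly 20³ = 8000 voxel centers (8 cm³) and prevents
boundary voxels from being double-counted between adjacent poses;
boundary handling has no clinically established convention, so this one
is fixed and documented here.

**Rotation convention.** Rotations are extrinsic about the fixed canonical
axes, composed x then y then z (`R = Rz Ry Rx`), applied about the cube
center. Any composition order and pivot would sweep the same set of
orientations; both are fixed here and documented so results are
reproducible.

**Center-anchored candidate lattice.** The candidate-center lattice is
anchored at the center of the target's bounding box rather than at an
arbitrary image corner. Three useful properties follow: the target
centroid is always a candidate (so any target that fits inside the cube
can be enclosed completely); halving the stride yields a nested lattice
(refining the search can never worsen the optimum); and the lattice is
equivariant under 90° lattice rotations of the inputs, which makes the
rotation-symmetry property of the optimizer hold exactly. The stride is
rounded to an integer number of grid voxels so that every candidate center
sits at a fixed fractional offset from the voxel lattice.

**Exact scoring, twice.** `score_placement()` counts mask voxels inside
the cube directly. `optimize_placement()` instead exploits the lattice
structure: for each rotation, the set of voxel offsets enclosed by the
cube is a fixed kernel shared by all candidate centers; the kernel
decomposes into contiguous runs along x (the cube is convex), and counts
for all centers reduce to differences of a prefix-summed copy of the
mask. Both paths decide membership through the same compiled test, so they
agree bit-for-bit; `brute_force_oracle()` — a literal loop calling
`score_placement()` per candidate — is kept in the package and the test
suite asserts integer-exact equality on every phantom family.

**Feasibility and fallback.** A placement is feasible when it encloses no
necrosis voxel. When no candidate is feasible (possible with extensive
necrosis), erroring out would leave a
clinical user with nothing, so the optimizer returns the best placement
under (minimize necrosis, then maximize core, then whole) and sets a loud
`fallback_used` flag. `fallback = "forbid"` turns this into an error (CLI
exit status 3).

**Mode selection.** Enhancing mode requires a core mask with at least
`min_core_mm3` (default 100 mm³) of volume; smaller cores are treated as
segmentation speckle and the pipeline uses FLAIR-only mode. The threshold
is a robustness guard, not a clinical claim.

**Default search resolution.** Defaults are a 2 mm center stride and a 15°
angle step (7 angles per axis, 343 triples). At 1 mm voxel resolution,
neighboring candidates change enclosed volumes by amounts comparable to
one voxel layer, so finer strides buy little; the defaults are declared
package conventions, chosen for desk-scale runtimes at sub-voxel
objective resolution. The exhaustive optimizer-vs-oracle comparisons in the test
suite run at 4 mm / 30° on 128 mm phantoms (64 mm for the
unavoidable-necrosis family), sizes chosen so the literal per-candidate
reference loop remains tractable; the equivalence being checked is exact
at any resolution.

**Registration.** Rigid (6 DOF) registration minimizes the mean squared
intensity difference over a set of sample points, initialized by the
intensity centroid offset and refined by staged Nelder–Mead (translation
only, then all six parameters, with restarts — the simplex tends to
collapse early along the shallow rotation directions of smooth, nearly
ellipsoidal objects). Two numerical details matter. Both images are
lightly pre-smoothed for the metric so anatomy rather than noise
dominates the cost surface. And the sample points are jittered off the
voxel lattice by fixed deterministic sub-voxel offsets: trilinear
sampling attenuates image noise by an amount that depends on where a
sample falls between voxel centers, and with on-lattice samples that
smoothing differential systematically rewards slightly rotated poses
whenever the true pose lands on the grid — off-lattice samples give
every pose the same fractional-offset statistics and remove the bias.
Any rigid intensity-based method satisfying the contract (metric not
worse than identity; masks warped nearest-neighbor) would do; the
contract, not the algorithm, is the module's commitment. A pass-through
mode (`assume_registered`) accepts pre-aligned inputs.

## What the phantoms do and do not show

The phantom generator produces nested ellipsoids — necrosis inside an
enhancing core inside an edema envelope — with fixed intensity levels
(background 0, necrosis 20, edema 60, core 100, arbitrary units) and
additive Gaussian noise. Ellipsoid centers default to half-integer world
coordinates, so no mask voxel center ever lies exactly on a candidate cube
face and the half-open boundary convention is never stressed by ties.
Ellipsoids were chosen over realistic lesion shapes deliberately: enclosed
volumes have closed forms, optima have symmetries, and every optimizer
guarantee can be checked exactly. Passing tests therefore demonstrate the
correctness of the geometry, scoring, search and I/O — they do not
demonstrate segmentation quality, robustness to irregular lesion
morphology, or clinical placement quality — judgments that require expert
review of real cases.

The five phantom families map onto the algorithm's branch structure:
feasible enhancing placement with full enclosure (`small_enhancing`),
active necrosis constraint with tiebreaking
(`large_enhancing_with_necrosis`), FLAIR-only mode (`non_enhancing`),
partial enclosure (`core_larger_than_cube`), and guaranteed infeasibility
(`necrosis_everywhere`). The last family lives on a 64 mm grid: on larger
grids no nested-ellipsoid configuration can make *every* candidate cube
intersect necrosis, because corner candidates get arbitrarily far from any
ellipsoid that still fits in the image.

## Known limitations

- Scoring is binary per voxel center; partial-volume fractions at the cube
  boundary are not integrated. At 1 mm resolution the difference is below
  the stride-induced variation between neighboring candidates.
- The cube must fit entirely inside the imaged field of view
  (circumscribing-sphere test); cubes overhanging the image are not
  considered.
- Ventricles, calvarium and resection cavities are not avoided; only
  necrosis is excluded.
- Registration is rigid and intensity-based; it assumes overlapping
  anatomy and reasonable initial alignment, as is typical for
  within-session sequences.
- Anisotropic or non-cubic acquisition volumes are out of scope; the side
  length is configurable but fixed per run.

## A worked example

```{r, eval = FALSE}
library(mrsplace)

ph <- generate_phantom(phantom_spec(seed = 1))
report <- optimize_placement(ph$seg, placement_config(center_stride_mm = 4,
                                                      angle_step_deg = 30))
report
#> <placement_report> mode enhancing
#> <cube_placement> center (58.5, 48.5, 63.5) mm, angles (30, 0, 60) deg, side 20 mm
#> <placement_score> core 1242 mm^3, necrosis 0 mm^3, whole 3282 mm^3 (feasible)
#>   712448 candidates evaluated

cube <- rasterize_cube(report$placement, ph$t1c)
sum(cube$data & ph$seg$necrosis$data)   # 0: the necrosis constraint held
```

The same pipeline is available from the shell via the installed
`inst/cli/mrsplace` script (`place`, `phantom` and `validate`
subcommands).
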