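# mrsplace

Automated placement of a single-voxel MR spectroscopy (MRS) acquisition
cube over a segmented brain tumor.

## What it does, and for whom

Single-voxel proton MRS samples metabolites from one cuboidal volume —
clinically a fixed 2 × 2 × 2 cm³ cube — and the diagnostic value of the
spectrum depends on where that cube is prescribed. In diffuse glioma,
enhancing tumor, infiltrative FLAIR-hyperintense tissue and necrosis lie
within millimetres of each other, and enclosed necrosis degrades spectral
quality. `mrsplace` is for imaging scientists and MR physicists who need a
reproducible, auditable prescription: given anatomical volumes
(post-contrast T1 and/or T2-FLAIR) and binary tumor sub-compartment masks
(enhancing core, necrosis, whole tumor), it searches exhaustively over
cube centers and rotations and returns the pose

```
argmax over feasible (c, R) of  ( V_core(c, R), V_whole(c, R) )   [lexicographic]
subject to                        V_necrosis(c, R) = 0
```

where `V_m(c, R)` is the number of voxel centers of mask `m` (1 mm
isotropic grid, so counts are mm³) whose cube-frame coordinates
`q = Rᵀ(x − c)` satisfy `−s/2 ≤ q_i < s/2` with `s = 20` mm. Candidate
centers form a lattice covering the target bounding box padded by
2√3 cm per side; candidate rotations are triples from {0°, …, 90°} about
the left/right, anterior/posterior and superior/inferior axes. For
non-enhancing lesions the objective is enclosed FLAIR-hyperintense volume
and no constraint applies. If no necrosis-free pose exists, a flagged
fallback minimizes enclosed necrosis first.

Segmentation masks are inputs (clinically they come from a trained
model); a deterministic ellipsoid phantom generator stands in for them so
the whole pipeline runs and is tested without patient data.

## Worked example

```r
library(mrsplace)

ph <- generate_phantom(phantom_spec(seed = 1))   # 128 mm phantom, core + necrosis + edema
report <- optimize_placement(ph$seg, placement_config(center_stride_mm = 4,
                                                      angle_step_deg = 30))
report
#> <placement_report> mode enhancing
#> <cube_placement> center (58.5, 48.5, 63.5) mm, angles (30, 0, 60) deg, side 20 mm
#> <placement_score> core 1242 mm^3, necrosis 0 mm^3, whole 3282 mm^3 (feasible)
#>   712448 candidates evaluated

cube <- rasterize_cube(report$placement, ph$t1c)
sum(cube$data)                          # 8000 voxels = 8 cm^3
sum(cube$data & ph$seg$necrosis$data)   # 0 - the necrosis constraint held
```

The report says: among 712,448 candidate poses, the best necrosis-free
cube encloses 1242 mm³ of enhancing core (the most attainable without
touching necrosis) and 3282 mm³ of whole tumor, and its rasterization is
exactly the clinical 8 cm³ volume. `write_mask()` / `write_report()`
emit the NIfTI mask and a JSON report; `generate_heatmap()` /
`export_heatmap()` produce the interpretability overlay in which each
position is colored by the core volume a cube centered there would
enclose, with necrosis-intersecting positions left unset.

A command-line interface wrapping the same functions is installed at
`inst/cli/mrsplace` with `place`, `phantom` and `validate` subcommands,
e.g.

```sh
mrsplace place --t1c t1c.nii.gz --core core.nii.gz --necrosis necro.nii.gz \
               --flair flair.nii.gz --whole whole.nii.gz --out results/
mrsplace phantom small_enhancing --out phantoms/ --seed 7
mrsplace validate --report results/report.json --core core.nii.gz \
                  --necrosis necro.nii.gz --whole whole.nii.gz
```

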