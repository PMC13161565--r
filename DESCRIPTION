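Package: mrsplace
Title: Automated Single-Voxel MRS Acquisition Cube Placement from Brain
    Tumor Segmentations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Plans the position and rotation of a fixed-size cubic magnetic
    resonance spectroscopy (MRS) acquisition volume over a segmented brain
    tumor. Given anatomical MR volumes (post-contrast T1, T2-FLAIR) and
    binary tumor sub-compartment masks (enhancing core, necrosis, whole
    FLAIR-hyperintense tumor), the placement engine performs an exhaustive
    grid search over cube centers and rotations on a 1 mm isotropic grid,
    maximizing enclosed enhancing core volume while excluding necrosis, with
    whole-tumor volume as a tiebreaker; for non-enhancing lesions it
    maximizes enclosed FLAIR hyperintensity. Includes NIfTI input/output,
    rigid co-registration and isotropic resampling, a deterministic
    ellipsoid phantom generator for end-to-end testing, interpretability
    heatmaps, a brute-force reference optimizer, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    RNifti,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    png,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
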