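#' Read a NIfTI volume and reorient it to canonical RAS
#'
#' Reads a NIfTI-1/NIfTI-2 file (optionally gzip-compressed), reorients the
#' data so that voxel indices increase towards the patient's Right, Anterior
#' and Superior, and returns it with an affine consistent with the
#' reorientation (the world coordinates of every voxel center are
#' preserved).
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return An [image_volume()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  img <- RNifti::readNifti(path)
  nd <- length(dim(img))
  if (nd != 3L) {
    stop(sprintf("expected 3D volume, got %dD payload in %s", nd, path), call. = FALSE)
  }
  RNifti::orientation(img) <- "RAS"
  affine <- unclass(RNifti::xform(img))
  attributes(affine) <- list(dim = c(4L, 4L))
  image_volume(array(as.numeric(img), dim = dim(img)), affine)
}

#' Read a NIfTI mask onto a reference grid
#'
#' Reads a segmentation file, reorients it to RAS, binarizes it by
#' thresholding at 0.5, and (if its grid differs from `reference`) resamples
#' it onto the reference grid with nearest-neighbor interpolation so that
#' binarity is preserved.
#'
#' @param path Path to the mask file.
#' @param reference An [image_volume()] whose grid the mask must live on.
#' @return An [binary_mask()] on the reference grid.
#' @export
read_mask <- function(path, reference) {
  vol <- read_volume(path)
  if (all(is.na(vol$data))) stop(sprintf("mask is all-NaN: %s", path), call. = FALSE)
  if (anyNA(vol$data)) {
    warning(sprintf("NaN values in mask %s treated as background", path))
    vol$data[is.na(vol$data)] <- 0
  }
  bin <- array(as.integer(vol$data > 0.5), dim = dim(vol$data))
  m <- binary_mask(bin, vol)
  if (same_grid(m, reference)) {
    m$affine <- reference$affine
    return(binary_mask(m$data, reference))
  }
  res <- resample_to_grid(m, reference, interpolation = "nearest")
  binary_mask(array(as.integer(res$data > 0.5), dim = dim(res$data)), reference)
}

#' Write a binary mask as a NIfTI file
#'
#' The payload is written as unsigned 8-bit integers with the mask's affine,
#' so `read_mask(write_mask(m))` is the identity on the same grid.
#'
#' @param mask An [binary_mask()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return The path, invisibly.
#' @export
write_mask <- function(mask, path) {
  write_nifti_raw(mask$data, mask$affine, path, datatype = "uint8")
}

#' Write an intensity volume as a NIfTI file
#'
#' @param vol An [image_volume()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_volume <- function(vol, path) {
  write_nifti_raw(vol$data, vol$affine, path, datatype = "float")
}

write_nifti_raw <- function(data, affine, path, datatype) {
  img <- RNifti::asNifti(data)
  # sform only: the qform replacement normalizes to quaternion + pixdim and
  # discards non-unit scales
  RNifti::sform(img) <- structure(affine, code = 2L)
  ok <- tryCatch({
    RNifti::writeNifti(img, path, datatype = datatype)
    TRUE
  }, error = function(e) FALSE)
  if (!ok || !file.exists(path)) stop(sprintf("could not write %s", path), call. = FALSE)
  invisible(path)
}

#' Serialize a placement report to JSON
#'
#' Writes the chosen placement (center in world mm, rotation angles in
#' degrees, side length), its enclosed-volume scores (mm^3), the search
#' parameters, mode and fallback flag, plus the package version and a
#' timestamp, as a JSON file. `read_report()` inverts it.
#'
#' @param report A placement report as returned by [optimize_placement()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_report <- function(report, path) {
  payload <- report_to_list(report)
  payload$software <- list(
    package = "mrsplace",
    version = as.character(utils::packageVersion("mrsplace"))
  )
  payload$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  ok <- tryCatch({
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok || !file.exists(path)) stop(sprintf("could not write %s", path), call. = FALSE)
  invisible(path)
}

report_to_list <- function(report) {
  list(
    placement = list(
      center_mm = report$placement$center_mm,
      angles_deg = report$placement$angles_deg,
      side_mm = report$placement$side_mm
    ),
    score = list(
      core_mm3 = report$score$core_mm3,
      necrosis_mm3 = report$score$necrosis_mm3,
      whole_mm3 = report$score$whole_mm3,
      feasible = report$score$feasible
    ),
    mode = report$mode,
    fallback_used = report$fallback_used,
    n_candidates_evaluated = report$n_candidates_evaluated,
    search = list(
      target_bbox_mm = list(lo = report$search$target_bbox[1, ], hi = report$search$target_bbox[2, ]),
      pad_mm = report$search$pad_mm,
      center_stride_mm = report$search$center_stride_mm,
      angle_step_deg = report$search$angle_step_deg,
      side_mm = report$search$side_mm,
      n_centers = report$search$n_centers,
      n_angles = report$search$n_angles
    )
  )
}

#' Parse a placement report written by [write_report()]
#'
#' @param path Path to the JSON report.
#' @return A list with elements `placement` (a [cube_placement()]), `score`,
#'   `mode`, `fallback_used`, `n_candidates_evaluated`, `search`,
#'   `software` and `timestamp`.
#' @export
read_report <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(
    placement = cube_placement(raw$placement$center_mm, raw$placement$angles_deg,
                               raw$placement$side_mm),
    score = list(core_mm3 = raw$score$core_mm3,
                 necrosis_mm3 = raw$score$necrosis_mm3,
                 whole_mm3 = raw$score$whole_mm3,
                 feasible = raw$score$feasible),
    mode = raw$mode,
    fallback_used = raw$fallback_used,
    n_candidates_evaluated = raw$n_candidates_evaluated,
    search = raw$search,
    software = raw$software,
    timestamp = raw$timestamp
  )
}
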