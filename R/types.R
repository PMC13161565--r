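#' Construct an image volume
#'
#' An `mrs_volume` is a 3D scalar intensity array together with a 4x4 affine
#' mapping 0-based voxel indices to world coordinates in millimetres. All
#' geometry in the package is expressed in the canonical RAS convention:
#' world axes increase towards the patient's Right, Anterior and Superior.
#'
#' @param data 3D numeric array of intensities.
#' @param affine 4x4 numeric matrix mapping 0-based voxel index
#'   `(i, j, k, 1)` to homogeneous world coordinates (mm). Must be
#'   invertible.
#' @return An object of class `mrs_volume` with elements `data` and
#'   `affine`.
#' @examples
#' vol <- image_volume(array(0, c(8, 8, 8)), diag(4))
#' voxel_spacing(vol)
#' @export
image_volume <- function(data, affine = diag(4)) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("expected 3D volume", call. = FALSE)
  }
  if (any(dim(data) < 1L)) stop("each volume extent must be >= 1", call. = FALSE)
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L))) stop("affine must be 4x4", call. = FALSE)
  det_a <- det(affine[1:3, 1:3, drop = FALSE])
  if (!is.finite(det_a) || abs(det_a) < 1e-12) {
    stop("affine is not invertible", call. = FALSE)
  }
  structure(list(data = data, affine = affine), class = "mrs_volume")
}

#' Construct a binary mask on a reference grid
#'
#' An `mrs_mask` is an `mrs_volume` whose data take values in \{0, 1\};
#' it represents one tumor sub-compartment (enhancing core, necrosis, or
#' whole FLAIR-hyperintense tumor) on the grid of a reference image.
#'
#' @param data 3D array with values in \{0, 1\} (integer or numeric).
#' @param grid An `mrs_volume` (or another mask) supplying the grid
#'   geometry, or a 4x4 affine matrix.
#' @return An object of class `c("mrs_mask", "mrs_volume")`.
#' @export
binary_mask <- function(data, grid) {
  affine <- if (inherits(grid, "mrs_volume")) grid$affine else as.matrix(grid)
  if (inherits(grid, "mrs_volume") && !identical(dim(data), dim(grid$data))) {
    stop("mask shape does not match its reference grid", call. = FALSE)
  }
  vals <- unique(as.vector(data))
  if (!all(vals %in% c(0, 1))) {
    stop("mask values must be exactly {0, 1}", call. = FALSE)
  }
  storage.mode(data) <- "integer"
  out <- image_volume(data, affine)
  class(out) <- c("mrs_mask", "mrs_volume")
  out
}

#' Bundle tumor sub-compartment masks
#'
#' Holds the (optional) enhancing core, necrosis and whole-tumor masks used
#' by the placement engine. All masks present must share one grid; the
#' constructor is the single validation gate asserting this.
#'
#' @param core,necrosis,whole `mrs_mask` objects or `NULL`.
#' @return An object of class `mrs_segmentation`.
#' @export
tumor_segmentation <- function(core = NULL, necrosis = NULL, whole = NULL) {
  masks <- Filter(Negate(is.null), list(core = core, necrosis = necrosis, whole = whole))
  if (length(masks) == 0L || (is.null(core) && is.null(whole))) {
    stop("at least one of the core or whole masks must be present", call. = FALSE)
  }
  for (m in masks) {
    if (!inherits(m, "mrs_mask")) stop("segmentation components must be mrs_mask objects", call. = FALSE)
  }
  ref <- masks[[1L]]
  for (m in masks[-1L]) {
    if (!same_grid(ref, m)) stop("all segmentation masks must share one grid", call. = FALSE)
  }
  structure(list(core = core, necrosis = necrosis, whole = whole,
                 .cache = new.env(parent = emptyenv())),
            class = "mrs_segmentation")
}

#' Describe an MRS acquisition cube placement
#'
#' @param center_mm Length-3 numeric, cube center in world mm.
#' @param angles_deg Length-3 numeric, rotation angles in degrees about the
#'   canonical left/right (x), anterior/posterior (y) and superior/inferior
#'   (z) axes; each must lie in \[0, 90\].
#' @param side_mm Cube side length in mm (default 20, the clinical
#'   2 x 2 x 2 cm acquisition volume).
#' @return An object of class `cube_placement`.
#' @export
cube_placement <- function(center_mm, angles_deg = c(0, 0, 0), side_mm = 20) {
  center_mm <- as.numeric(center_mm)
  angles_deg <- as.numeric(angles_deg)
  stopifnot(length(center_mm) == 3L, length(angles_deg) == 3L, length(side_mm) == 1L)
  if (side_mm <= 0) stop("side_mm must be positive", call. = FALSE)
  if (any(!is.finite(center_mm)) || any(!is.finite(angles_deg))) {
    stop("placement parameters must be finite", call. = FALSE)
  }
  if (any(angles_deg < 0 | angles_deg > 90)) {
    stop("rotation angles must lie in [0, 90] degrees", call. = FALSE)
  }
  structure(list(center_mm = center_mm, angles_deg = angles_deg, side_mm = side_mm),
            class = "cube_placement")
}

## ---- geometry helpers ------------------------------------------------------

#' Voxel spacing of a volume
#'
#' @param vol An `mrs_volume`.
#' @return Length-3 numeric, mm per grid voxel along each axis (column norms
#'   of the affine).
#' @export
voxel_spacing <- function(vol) {
  sqrt(colSums(vol$affine[1:3, 1:3, drop = FALSE]^2))
}

#' Grid origin of a volume
#'
#' @param vol An `mrs_volume`.
#' @return Length-3 numeric, world coordinates (mm) of the first voxel's
#'   center.
#' @export
grid_origin <- function(vol) {
  as.numeric(vol$affine[1:3, 4])
}

is_axis_aligned <- function(vol, tol = 1e-6) {
  m <- vol$affine[1:3, 1:3, drop = FALSE]
  all(abs(m[row(m) != col(m)]) < tol) && all(diag(m) > 0)
}

assert_unit_grid <- function(vol, what = "volume") {
  if (!is_axis_aligned(vol)) {
    stop(sprintf("%s grid must be axis-aligned (RAS); run resample_isotropic() first", what),
         call. = FALSE)
  }
  if (any(abs(voxel_spacing(vol) - 1) > 1e-6)) {
    stop(sprintf("%s grid must be 1 mm isotropic; run resample_isotropic() first", what),
         call. = FALSE)
  }
  invisible(vol)
}

#' Test whether two volumes share a grid
#'
#' @param a,b `mrs_volume` objects.
#' @param tol Absolute tolerance on affine entries.
#' @return Logical scalar.
#' @export
same_grid <- function(a, b, tol = 1e-4) {
  identical(dim(a$data), dim(b$data)) && max(abs(a$affine - b$affine)) < tol
}

# World coordinates of voxel centers along one axis (axis-aligned grids).
axis_coords <- function(vol, axis) {
  grid_origin(vol)[axis] + (seq_len(dim(vol$data)[axis]) - 1) * voxel_spacing(vol)[axis]
}

# World coordinates (N x 3) of the nonzero voxels of a mask.
mask_points <- function(mask) {
  idx <- which(mask$data != 0L, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(matrix(numeric(0), 0L, 3L))
  t(vol_index_to_world(mask, t(idx)))
}

# idx: 3 x N matrix of 1-based indices -> 3 x N world coordinates.
vol_index_to_world <- function(vol, idx) {
  (vol$affine[1:3, 1:3, drop = FALSE] %*% (idx - 1)) + vol$affine[1:3, 4]
}

# Cached nonzero-voxel world coordinates for one segmentation component.
seg_points <- function(seg, which) {
  m <- seg[[which]]
  if (is.null(m)) return(matrix(numeric(0), 0L, 3L))
  cache <- seg$.cache
  if (is.null(cache)) return(mask_points(m))
  key <- paste0("pts_", which)
  if (is.null(cache[[key]])) cache[[key]] <- mask_points(m)
  cache[[key]]
}

# Volume (mm^3) of a mask: voxel count times voxel volume.
mask_volume <- function(mask) {
  sum(mask$data != 0L) * prod(voxel_spacing(mask))
}

seg_grid <- function(seg) {
  for (nm in c("core", "whole", "necrosis")) {
    if (!is.null(seg[[nm]])) return(seg[[nm]])
  }
  stop("empty segmentation", call. = FALSE)
}

#' @export
print.mrs_volume <- function(x, ...) {
  cat(sprintf("<mrs_volume> %s voxels, spacing %s mm, origin (%s) mm\n",
              paste(dim(x$data), collapse = " x "),
              paste(signif(voxel_spacing(x), 4), collapse = " x "),
              paste(signif(grid_origin(x), 4), collapse = ", ")))
  invisible(x)
}

#' @export
print.mrs_mask <- function(x, ...) {
  cat(sprintf("<mrs_mask> %s voxels, %d set (%.1f mm^3)\n",
              paste(dim(x$data), collapse = " x "),
              sum(x$data != 0L), mask_volume(x)))
  invisible(x)
}

#' @export
print.cube_placement <- function(x, ...) {
  cat(sprintf("<cube_placement> center (%s) mm, angles (%s) deg, side %g mm\n",
              paste(round(x$center_mm, 2), collapse = ", "),
              paste(round(x$angles_deg, 1), collapse = ", "),
              x$side_mm))
  invisible(x)
}

#' @export
print.mrs_segmentation <- function(x, ...) {
  comp <- function(m) if (is.null(m)) "absent" else sprintf("%.0f mm^3", mask_volume(m))
  cat(sprintf("<mrs_segmentation> core: %s, necrosis: %s, whole: %s\n",
              comp(x$core), comp(x$necrosis), comp(x$whole)))
  invisible(x)
}
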