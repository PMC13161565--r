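#' Default configuration for the placement search
#'
#' @param center_stride_mm Spacing of the candidate-center lattice, mm. Must
#'   be a positive integer multiple of the (1 mm) grid spacing.
#' @param angle_step_deg Step of the rotation-angle grid per axis; the grid
#'   is `{0, step, 2 step, ...}` up to and always including 90.
#' @param pad_mm Padding applied to the target bounding box, representing
#'   the limits for the cube center; default is the full cube diagonal of a
#'   20 mm cube, `2 * sqrt(3) * 10` mm, kept at full floating precision.
#' @param side_mm Cube side length, mm (clinical standard 20).
#' @param min_core_mm3 Minimum enhancing-core volume for selecting
#'   enhancing mode; smaller cores are treated as speckle and the pipeline
#'   falls back to FLAIR-only mode.
#' @param fallback `"allow"` or `"forbid"`: behavior when no placement with
#'   zero enclosed necrosis exists.
#' @param heatmap `"off"`, `"identity"` or `"optimal"`: whether the
#'   pipeline produces an interpretability heatmap, and at which rotation.
#' @return A list of class `placement_config`.
#' @export
placement_config <- function(center_stride_mm = 2, angle_step_deg = 15,
                             pad_mm = 2 * sqrt(3) * 10, side_mm = 20,
                             min_core_mm3 = 100,
                             fallback = c("allow", "forbid"),
                             heatmap = c("off", "identity", "optimal")) {
  stopifnot(center_stride_mm > 0, angle_step_deg > 0, angle_step_deg <= 90,
            pad_mm >= 0, side_mm > 0, min_core_mm3 >= 0)
  structure(list(center_stride_mm = center_stride_mm,
                 angle_step_deg = angle_step_deg,
                 pad_mm = pad_mm, side_mm = side_mm,
                 min_core_mm3 = min_core_mm3,
                 fallback = match.arg(fallback),
                 heatmap = match.arg(heatmap)),
            class = "placement_config")
}

#' Axis-aligned bounding box of a mask
#'
#' @param mask A nonempty [binary_mask()] on an axis-aligned grid.
#' @return A 2x3 matrix (rows `lo`, `hi`) of world coordinates (mm) of the
#'   extreme nonzero voxel centers along each axis.
#' @export
compute_bbox <- function(mask) {
  if (!is_axis_aligned(mask)) stop("bounding box requires an axis-aligned grid", call. = FALSE)
  idx <- which(mask$data != 0L, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("cannot compute the bounding box of an empty mask", call. = FALSE)
  lo_idx <- apply(idx, 2, min) - 1
  hi_idx <- apply(idx, 2, max) - 1
  sp <- voxel_spacing(mask)
  org <- grid_origin(mask)
  out <- rbind(lo = org + lo_idx * sp, hi = org + hi_idx * sp)
  colnames(out) <- c("x", "y", "z")
  out
}

#' Rotation matrix for the cube orientation sweep
#'
#' Extrinsic rotations about the fixed canonical left/right (x),
#' anterior/posterior (y) and superior/inferior (z) world axes, composed in
#' the order x, then y, then z: `R = Rz %*% Ry %*% Rx`.
#'
#' @param angles_deg Length-3 numeric vector of angles in degrees.
#' @return A 3x3 orthonormal rotation matrix with determinant +1.
#' @export
rotation_matrix <- function(angles_deg) {
  a <- as.numeric(angles_deg) * pi / 180
  if (length(a) != 3L || any(!is.finite(a))) stop("angles must be 3 finite values", call. = FALSE)
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  rz %*% ry %*% rx
}

#' Score a cube placement against a tumor segmentation
#'
#' Counts, for each present mask, the grid voxels whose centers fall inside
#' the rotated cube. Membership is half-open: the cube-frame coordinate
#' `q = t(R) %*% (x - center)` must satisfy `-side/2 <= q_i < side/2` on
#' every axis, so an axis-aligned 20 mm cube at an integer center on the
#' 1 mm grid always contains exactly 8000 voxel centers. Counts are exact
#' integers; with the 1 mm grid they equal enclosed volumes in mm^3.
#'
#' @param p A [cube_placement()].
#' @param seg A [tumor_segmentation()] on a 1 mm isotropic axis-aligned
#'   grid.
#' @return A list of class `placement_score` with `core_mm3`,
#'   `necrosis_mm3`, `whole_mm3` and `feasible` (`necrosis_mm3 == 0`).
#' @export
score_placement <- function(p, seg) {
  grid <- seg_grid(seg)
  assert_unit_grid(grid, "segmentation")
  R <- rotation_matrix(p$angles_deg)
  count1 <- function(which) {
    pts <- seg_points(seg, which)
    if (nrow(pts) == 0L) return(0)
    cpp_count_in_cube(pts, R, p$center_mm, p$side_mm)
  }
  score <- list(core_mm3 = count1("core"),
                necrosis_mm3 = count1("necrosis"),
                whole_mm3 = count1("whole"))
  score$feasible <- score$necrosis_mm3 == 0
  class(score) <- "placement_score"
  score
}

#' Rasterize a cube placement as a mask on a grid
#'
#' A grid voxel is set iff its center satisfies the same half-open
#' cube-frame membership test used by [score_placement()], so for any mask
#' `m` on the same grid, `sum(rasterize & m)` equals the corresponding
#' enclosed-volume score.
#'
#' @param p A [cube_placement()].
#' @param grid An [image_volume()] supplying the target grid (axis-aligned).
#' @return An [binary_mask()] on `grid`. If the cube lies entirely outside
#'   the grid, the mask is empty and a warning is raised.
#' @export
rasterize_cube <- function(p, grid) {
  if (!is_axis_aligned(grid)) stop("rasterization requires an axis-aligned grid", call. = FALSE)
  dm <- dim(grid$data)
  sp <- voxel_spacing(grid)
  org <- grid_origin(grid)
  r <- p$side_mm * sqrt(3) / 2
  lo <- pmax(1L, as.integer(ceiling((p$center_mm - r - org) / sp)) + 1L)
  hi <- pmin(dm, as.integer(floor((p$center_mm + r - org) / sp)) + 1L)
  out <- array(0L, dim = dm)
  if (any(lo > hi)) {
    warning("cube lies entirely outside the image grid; returning an empty mask")
    return(binary_mask(out, grid))
  }
  xs <- org[1] + (seq(lo[1], hi[1]) - 1) * sp[1]
  ys <- org[2] + (seq(lo[2], hi[2]) - 1) * sp[2]
  zs <- org[3] + (seq(lo[3], hi[3]) - 1) * sp[3]
  pts <- as.matrix(expand.grid(xs, ys, zs))
  inside <- cpp_points_in_cube(pts, rotation_matrix(p$angles_deg), p$center_mm, p$side_mm)
  if (!any(inside)) {
    warning("cube lies entirely outside the image grid; returning an empty mask")
    return(binary_mask(out, grid))
  }
  sub <- array(as.integer(inside), dim = c(length(xs), length(ys), length(zs)))
  out[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- sub
  binary_mask(out, grid)
}

#' Build the placement search space around a target mask
#'
#' The candidate cube centers form a lattice with the configured stride,
#' anchored at the center of the target's bounding box (so the box centroid
#' is always a candidate), covering the bounding box padded by `pad_mm` on
#' all sides, and clipped to positions where the rotated cube's
#' circumscribing sphere (radius `side * sqrt(3) / 2`) fits inside the
#' image field of view. Candidate rotations are all triples from
#' `{0, step, 2 step, ..., 90}` per axis (90 always included). The
#' deterministic iteration order used for tie-breaking is centers ascending
#' lexicographically by (x, y, z), then angle triples ascending by
#' (a_x, a_y, a_z).
#'
#' @param target Nonempty [binary_mask()] on the 1 mm grid (the enhancing
#'   core in enhancing mode, the whole tumor in FLAIR-only mode).
#' @param cfg A [placement_config()].
#' @return A list of class `mrs_search_space` with the target bounding box,
#'   the padded center-limit box, per-axis candidate center coordinates,
#'   the ordered angle-triple matrix, and grid geometry.
#' @export
build_search_space <- function(target, cfg = placement_config()) {
  assert_unit_grid(target, "target mask")
  sp <- voxel_spacing(target)[1]
  stride <- round(cfg$center_stride_mm / sp) * sp
  if (stride <= 0) stride <- sp
  if (abs(stride - cfg$center_stride_mm) > 1e-9) {
    warning(sprintf("center_stride_mm rounded to %g mm to align with the grid", stride))
  }
  bbox <- compute_bbox(target)
  limits <- rbind(lo = bbox[1, ] - cfg$pad_mm, hi = bbox[2, ] + cfg$pad_mm)
  anchor <- (bbox[1, ] + bbox[2, ]) / 2

  dm <- dim(target$data)
  org <- grid_origin(target)
  r_fit <- cfg$side_mm * sqrt(3) / 2
  domain_lo <- org - sp / 2
  domain_hi <- org + (dm - 1) * sp + sp / 2
  lo_b <- pmax(limits[1, ], domain_lo + r_fit)
  hi_b <- pmin(limits[2, ], domain_hi - r_fit)
  if (any(lo_b > hi_b)) {
    stop("empty candidate set: the image is too small to contain the cube", call. = FALSE)
  }
  centers <- lapply(1:3, function(i) {
    k <- seq(ceiling((lo_b[i] - anchor[i]) / stride - 1e-9),
             floor((hi_b[i] - anchor[i]) / stride + 1e-9))
    anchor[i] + k * stride
  })
  if (any(lengths(centers) == 0L)) {
    stop("empty candidate set: the image is too small to contain the cube", call. = FALSE)
  }

  steps <- unique(c(seq(0, 90, by = cfg$angle_step_deg), 90))
  g <- expand.grid(az = steps, ay = steps, ax = steps)  # az fastest
  angles <- as.matrix(g[, c("ax", "ay", "az")])
  dimnames(angles) <- NULL

  structure(list(
    target_bbox = bbox,
    limits = limits,
    pad_mm = cfg$pad_mm,
    center_stride_mm = stride,
    angle_step_deg = cfg$angle_step_deg,
    side_mm = cfg$side_mm,
    centers_x = centers[[1]], centers_y = centers[[2]], centers_z = centers[[3]],
    angles = angles,
    n_centers = prod(lengths(centers)),
    n_angles = nrow(angles),
    grid_origin = org, grid_dim = dm, grid_spacing = rep(sp, 3)
  ), class = "mrs_search_space")
}

#' @export
print.mrs_search_space <- function(x, ...) {
  cat(sprintf("<mrs_search_space> %d centers (%d x %d x %d, stride %g mm) x %d rotations = %d candidates\n",
              x$n_centers, length(x$centers_x), length(x$centers_y), length(x$centers_z),
              x$center_stride_mm, x$n_angles, x$n_centers * x$n_angles))
  invisible(x)
}

#' @export
print.placement_score <- function(x, ...) {
  cat(sprintf("<placement_score> core %g mm^3, necrosis %g mm^3, whole %g mm^3 (%s)\n",
              x$core_mm3, x$necrosis_mm3, x$whole_mm3,
              if (x$feasible) "feasible" else "infeasible"))
  invisible(x)
}

# Enumerate candidate centers of a search space as an n x 3 matrix in the
# deterministic tie-breaking order (ascending lexicographically by x, y, z).
space_centers_ordered <- function(space) {
  nx <- length(space$centers_x); ny <- length(space$centers_y); nz <- length(space$centers_z)
  cx <- rep(space$centers_x, each = ny * nz)
  cy <- rep(rep(space$centers_y, each = nz), times = nx)
  cz <- rep(space$centers_z, times = nx * ny)
  cbind(cx, cy, cz)
}
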