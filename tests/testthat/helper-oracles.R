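# Independent reference implementations used as oracles.  These deliberately
# avoid the package's compiled code paths and rotation helper.

# Rotation built from first principles: extrinsic x, then y, then z.
ref_rotation <- function(deg) {
  a <- deg * pi / 180
  Rx <- rbind(c(1, 0, 0),
              c(0, cos(a[1]), -sin(a[1])),
              c(0, sin(a[1]), cos(a[1])))
  Ry <- rbind(c(cos(a[2]), 0, sin(a[2])),
              c(0, 1, 0),
              c(-sin(a[2]), 0, cos(a[2])))
  Rz <- rbind(c(cos(a[3]), -sin(a[3]), 0),
              c(sin(a[3]), cos(a[3]), 0),
              c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

# Per-voxel loop counting mask voxel centers inside the half-open cube.
ref_enclosed_count <- function(mask, center, angles_deg, side = 20) {
  idx <- which(mask$data != 0L, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(0L)
  org <- grid_origin(mask)
  sp <- voxel_spacing(mask)
  Rt <- t(ref_rotation(angles_deg))
  n <- 0L
  for (r in seq_len(nrow(idx))) {
    x <- org + (idx[r, ] - 1) * sp
    q <- Rt %*% (x - center)
    if (all(q >= -side / 2) && all(q < side / 2)) n <- n + 1L
  }
  n
}

# 90 degree lattice rotation about the superior/inferior (z) axis for a
# cubic grid: out[i, j, k] = arr[j, N + 1 - i, k], i.e. world (x, y, z) ->
# (C - y, x, z) with C = N - 1 on a unit grid with origin 0.
rot90_z <- function(arr) {
  stopifnot(dim(arr)[1] == dim(arr)[2])
  n <- dim(arr)[1]
  aperm(arr, c(2, 1, 3))[n:1, , , drop = FALSE]
}

rot90_seg <- function(seg) {
  grid <- image_volume(array(0, dim(seg_first(seg)$data)), seg_first(seg)$affine)
  rot <- function(m) if (is.null(m)) NULL else binary_mask(rot90_z(m$data), grid)
  tumor_segmentation(core = rot(seg$core), necrosis = rot(seg$necrosis),
                     whole = rot(seg$whole))
}

seg_first <- function(seg) {
  for (nm in c("core", "whole", "necrosis")) if (!is.null(seg[[nm]])) return(seg[[nm]])
  stop("empty segmentation")
}

# A small enhancing phantom on a 48^3 grid, cheap enough for per-voxel oracles.
tiny_phantom <- function(seed = 3L, necrosis = TRUE) {
  generate_phantom(phantom_spec(
    shape = c(48L, 48L, 48L),
    core_center_mm = c(24.5, 22.5, 25.5),
    core_radii_mm = c(6, 5, 4.5),
    necrosis_radii_mm = if (necrosis) c(2.5, 2, 2) else c(0, 0, 0),
    edema_radii_mm = c(8, 7, 6.5),
    core_rotation_deg = c(10, 0, 20),
    noise_sd = 1, seed = seed))
}

# Like tiny_phantom but on a 64^3 grid, leaving room in the search space for
# cubes that dodge the central necrosis (on 48^3 every admissible cube is
# within 10 mm of it).
roomy_phantom <- function(seed = 3L) {
  generate_phantom(phantom_spec(
    shape = c(64L, 64L, 64L),
    core_center_mm = c(33.5, 30.5, 31.5),
    core_radii_mm = c(6, 5, 4.5),
    necrosis_radii_mm = c(2.5, 2, 2),
    edema_radii_mm = c(8, 7, 6.5),
    core_rotation_deg = c(10, 0, 20),
    noise_sd = 1, seed = seed))
}

report_equal <- function(a, b) {
  expect_identical(a$placement$center_mm, b$placement$center_mm)
  expect_identical(a$placement$angles_deg, b$placement$angles_deg)
  expect_identical(a$score$core_mm3, b$score$core_mm3)
  expect_identical(a$score$necrosis_mm3, b$score$necrosis_mm3)
  expect_identical(a$score$whole_mm3, b$score$whole_mm3)
  expect_identical(a$fallback_used, b$fallback_used)
}
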