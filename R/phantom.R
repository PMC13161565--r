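#' Specify a synthetic tumor phantom
#'
#' Describes an ellipsoidal tumor phantom: an enhancing core ellipsoid with
#' an interior necrosis ellipsoid, surrounded by a FLAIR-hyperintense edema
#' ellipsoid, on an isotropic grid with additive Gaussian image noise.
#' Ellipsoids are used instead of realistic lesion shapes so that enclosed
#' volumes and optima have closed forms and symmetries useful for testing.
#'
#' Default geometry emulates a moderate-size high-grade glioma: a core a
#' little larger than the 20 mm acquisition cube, a small central necrotic
#' focus, and an edema envelope a few millimetres beyond the core. The
#' ellipsoid center defaults to a half-integer world coordinate so mask
#' voxel centers never coincide with candidate cube faces.
#'
#' @param shape Grid extents (3 integers).
#' @param spacing_mm Isotropic grid spacing, mm.
#' @param core_center_mm Common center of the three ellipsoids, world mm.
#' @param core_radii_mm,necrosis_radii_mm,edema_radii_mm Semi-axes (mm) of
#'   the core, necrosis and edema ellipsoids; a zero radius means the
#'   compartment is absent. Must nest: necrosis <= core <= edema
#'   componentwise.
#' @param core_rotation_deg Rotation of all three ellipsoids about their
#'   common center ([rotation_matrix()] convention).
#' @param noise_sd Standard deviation of the additive Gaussian intensity
#'   noise (arbitrary units; masks are noise-free).
#' @param enhancing If `FALSE`, the core and necrosis masks are empty and
#'   only the whole (edema) mask is produced, emulating a non-enhancing
#'   low-grade glioma.
#' @param seed Integer seed; identical specs generate bit-identical output.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(128L, 128L, 128L), spacing_mm = 1,
                         core_center_mm = c(66.5, 60.5, 63.5),
                         core_radii_mm = c(12, 11, 10),
                         necrosis_radii_mm = c(5, 4, 4),
                         edema_radii_mm = c(16, 15, 14),
                         core_rotation_deg = c(0, 0, 0),
                         noise_sd = 2, enhancing = TRUE, seed = 1L) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 1L), spacing_mm > 0,
            length(core_center_mm) == 3L, length(core_radii_mm) == 3L,
            length(necrosis_radii_mm) == 3L, length(edema_radii_mm) == 3L,
            noise_sd >= 0)
  if (any(necrosis_radii_mm < 0) || any(core_radii_mm < 0) || any(edema_radii_mm < 0)) {
    stop("radii must be non-negative", call. = FALSE)
  }
  if (any(necrosis_radii_mm > core_radii_mm) && enhancing) {
    stop("necrosis radii must not exceed core radii", call. = FALSE)
  }
  if (enhancing && any(core_radii_mm > edema_radii_mm)) {
    stop("core radii must not exceed edema radii", call. = FALSE)
  }
  structure(list(shape = shape, spacing_mm = spacing_mm,
                 core_center_mm = as.numeric(core_center_mm),
                 core_radii_mm = as.numeric(core_radii_mm),
                 necrosis_radii_mm = as.numeric(necrosis_radii_mm),
                 edema_radii_mm = as.numeric(edema_radii_mm),
                 core_rotation_deg = as.numeric(core_rotation_deg),
                 noise_sd = noise_sd, enhancing = isTRUE(enhancing),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Intensity levels (arbitrary units). The optimizer only reads masks;
# intensities exist so registration has structure to align.
.phantom_levels <- c(background = 0, edema = 60, core = 100, necrosis = 20)

#' Generate a synthetic tumor phantom
#'
#' Produces a post-contrast T1-like volume (core bright, necrosis dark), a
#' FLAIR-like volume (edema bright), and the ground-truth segmentation:
#' `whole` = edema ellipsoid; `core` = core ellipsoid minus the necrosis
#' ellipsoid (empty for non-enhancing phantoms); `necrosis` = necrosis
#' ellipsoid. A voxel belongs to an ellipsoid when its center lies inside
#' it. Output is deterministic in the spec (including `seed`).
#'
#' @param spec A [phantom_spec()].
#' @return A list with `t1c`, `flair` ([image_volume()]), `seg`
#'   ([tumor_segmentation()]) and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  dm <- spec$shape
  sp <- spec$spacing_mm
  affine <- diag(c(sp, sp, sp, 1))
  grid <- image_volume(array(0, dim = dm), affine)

  xs <- (seq_len(dm[1]) - 1) * sp
  ys <- (seq_len(dm[2]) - 1) * sp
  zs <- (seq_len(dm[3]) - 1) * sp
  R <- rotation_matrix(spec$core_rotation_deg)

  inside_ellipsoid <- function(radii) {
    if (any(radii <= 0)) return(array(FALSE, dim = dm))
    dx <- xs - spec$core_center_mm[1]
    dy <- ys - spec$core_center_mm[2]
    dz <- zs - spec$core_center_mm[3]
    # q = t(R) d, accumulated separably to avoid materializing the point list
    acc <- array(0, dim = dm)
    for (i in 1:3) {
      qi <- outer(outer(R[1, i] * dx, R[2, i] * dy, "+"), R[3, i] * dz, "+") / radii[i]
      acc <- acc + qi^2
    }
    acc <= 1
  }

  edema <- inside_ellipsoid(spec$edema_radii_mm)
  if (spec$enhancing) {
    core_full <- inside_ellipsoid(spec$core_radii_mm)
    necro <- inside_ellipsoid(spec$necrosis_radii_mm)
    core <- core_full & !necro
  } else {
    core_full <- necro <- core <- array(FALSE, dim = dm)
  }

  lv <- .phantom_levels
  t1c_arr <- array(lv[["background"]], dim = dm)
  t1c_arr[core] <- lv[["core"]]
  t1c_arr[necro] <- lv[["necrosis"]]
  flair_arr <- array(lv[["background"]], dim = dm)
  flair_arr[edema] <- lv[["edema"]]

  if (spec$noise_sd > 0) {
    old_seed <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old_seed)) {
        if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old_seed, envir = globalenv())
    }, add = TRUE)
    set.seed(spec$seed)
    t1c_arr <- t1c_arr + array(stats::rnorm(prod(dm), sd = spec$noise_sd), dim = dm)
    flair_arr <- flair_arr + array(stats::rnorm(prod(dm), sd = spec$noise_sd), dim = dm)
  }

  seg <- tumor_segmentation(
    core = binary_mask(array(as.integer(core), dim = dm), grid),
    necrosis = binary_mask(array(as.integer(necro), dim = dm), grid),
    whole = binary_mask(array(as.integer(edema), dim = dm), grid)
  )
  list(t1c = image_volume(t1c_arr, affine),
       flair = image_volume(flair_arr, affine),
       seg = seg, spec = spec)
}

#' Fixed phantom families covering the optimizer's branch structure
#'
#' Returns seeded phantom specifications for one of five named families,
#' each exercising a distinct branch of the placement algorithm:
#' \describe{
#'   \item{`small_enhancing`}{an enhancing core small enough to be fully
#'     enclosed by the 20 mm cube (feasible, perfect enclosure).}
#'   \item{`large_enhancing_with_necrosis`}{a core wider than the cube with
#'     a central necrotic focus (partial enclosure under the zero-necrosis
#'     constraint; the edema tiebreaker is active among equal-core optima).}
#'   \item{`non_enhancing`}{no enhancement: FLAIR-only mode, whole-tumor
#'     maximization.}
#'   \item{`core_larger_than_cube`}{an enhancing core with at least one
#'     diameter exceeding the cube side (partial enclosure, no necrosis).}
#'   \item{`necrosis_everywhere`}{necrosis so extensive that every candidate
#'     cube encloses some of it; exercises the flagged fallback placement.
#'     Uses a 64-voxel grid so that the unavoidability is geometrically
#'     attainable with nested ellipsoids.}
#' }
#'
#' @param name One of the five family names.
#' @return A list of [phantom_spec()] objects.
#' @export
phantom_suite <- function(name) {
  specs <- switch(name,
    small_enhancing = list(
      phantom_spec(core_center_mm = c(66.5, 60.5, 63.5),
                   core_radii_mm = c(6, 5.5, 5),
                   necrosis_radii_mm = c(0, 0, 0),
                   edema_radii_mm = c(9, 8.5, 8),
                   core_rotation_deg = c(15, 10, 0),
                   seed = 101L)
    ),
    large_enhancing_with_necrosis = list(
      phantom_spec(core_center_mm = c(66.5, 60.5, 63.5),
                   core_radii_mm = c(12, 11, 10),
                   necrosis_radii_mm = c(5, 4, 4),
                   edema_radii_mm = c(16, 15, 14),
                   seed = 102L)
    ),
    non_enhancing = list(
      phantom_spec(core_center_mm = c(60.5, 66.5, 62.5),
                   core_radii_mm = c(0, 0, 0),
                   necrosis_radii_mm = c(0, 0, 0),
                   edema_radii_mm = c(14, 12, 11),
                   core_rotation_deg = c(0, 0, 20),
                   enhancing = FALSE,
                   seed = 103L)
    ),
    core_larger_than_cube = list(
      phantom_spec(core_center_mm = c(64.5, 62.5, 66.5),
                   core_radii_mm = c(14, 12, 11),
                   necrosis_radii_mm = c(0, 0, 0),
                   edema_radii_mm = c(17, 15, 14),
                   seed = 104L)
    ),
    necrosis_everywhere = list(
      phantom_spec(shape = c(64L, 64L, 64L),
                   core_center_mm = c(31.5, 31.5, 31.5),
                   core_radii_mm = c(17.5, 17.5, 17.5),
                   necrosis_radii_mm = c(16, 16, 16),
                   edema_radii_mm = c(19, 19, 19),
                   seed = 105L)
    ),
    stop(sprintf("unknown phantom suite '%s'", name), call. = FALSE)
  )
  specs
}

#' Names of the phantom families
#'
#' @return Character vector of the five family names accepted by
#'   [phantom_suite()].
#' @export
phantom_suite_names <- function() {
  c("small_enhancing", "large_enhancing_with_necrosis", "non_enhancing",
    "core_larger_than_cube", "necrosis_everywhere")
}
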