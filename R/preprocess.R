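#' Resample a volume onto the grid of a reference volume
#'
#' Samples `vol` at the voxel centers of `grid` using trilinear (intensity)
#' or nearest-neighbor (mask) interpolation. Points outside the source field
#' of view are set to 0.
#'
#' @param vol Source [image_volume()] or mask.
#' @param grid Reference [image_volume()] supplying the target grid.
#' @param interpolation `"linear"` or `"nearest"`; masks must use
#'   `"nearest"` so that binarity and count-based volumes are preserved.
#' @return An [image_volume()] (or [binary_mask()] if `vol` was a mask) on
#'   the reference grid.
#' @export
resample_to_grid <- function(vol, grid, interpolation = c("linear", "nearest")) {
  interpolation <- match.arg(interpolation)
  dm <- dim(grid$data)
  pts <- grid_world_points(grid)
  vals <- sample_volume(vol, pts, interpolation)
  out <- array(vals, dim = dm)
  if (inherits(vol, "mrs_mask")) {
    binary_mask(array(as.integer(out > 0.5), dim = dm), grid)
  } else {
    image_volume(out, grid$affine)
  }
}

#' Resample a volume to an isotropic axis-aligned grid
#'
#' Builds a new axis-aligned RAS grid with the requested isotropic spacing
#' covering the source field of view (anchored at the world position of the
#' source's first voxel center), and samples the input onto it.
#'
#' @param img Source [image_volume()] or mask.
#' @param spacing_mm Target spacing in mm (default 1).
#' @param interpolation `"linear"` for intensities, `"nearest"` for masks
#'   (defaults to `"nearest"` when `img` is a mask).
#' @return A resampled volume with spacing `(spacing_mm, spacing_mm,
#'   spacing_mm)`.
#' @export
resample_isotropic <- function(img, spacing_mm = 1,
                               interpolation = if (inherits(img, "mrs_mask")) "nearest" else "linear") {
  if (!is.numeric(spacing_mm) || length(spacing_mm) != 1L || spacing_mm <= 0) {
    stop("spacing_mm must be a positive scalar", call. = FALSE)
  }
  dm <- dim(img$data)
  corners <- as.matrix(expand.grid(c(0, dm[1] - 1), c(0, dm[2] - 1), c(0, dm[3] - 1)))
  world <- t(img$affine[1:3, 1:3] %*% t(corners) + img$affine[1:3, 4])
  lo <- apply(world, 2, min)
  hi <- apply(world, 2, max)
  n_out <- pmax(1L, as.integer(floor((hi - lo) / spacing_mm + 1e-9)) + 1L)
  affine <- diag(c(rep(spacing_mm, 3), 1))
  affine[1:3, 4] <- lo
  grid <- image_volume(array(0, dim = n_out), affine)
  resample_to_grid(img, grid, interpolation)
}

# World coordinates (N x 3) of every voxel center of a grid.
grid_world_points <- function(grid) {
  dm <- dim(grid$data)
  i <- rep.int(seq_len(dm[1]) - 1, times = dm[2] * dm[3])
  j <- rep.int(rep(seq_len(dm[2]) - 1L, each = dm[1]), times = dm[3])
  k <- rep(seq_len(dm[3]) - 1L, each = dm[1] * dm[2])
  idx <- cbind(i, j, k)
  m <- grid$affine
  sweep(idx %*% t(m[1:3, 1:3]), 2, m[1:3, 4], "+")
}

# Separable [1, 2, 1]/4 smoothing along each axis with edge replication.
smooth3 <- function(a) {
  d <- dim(a)
  for (ax in 1:3) {
    n <- d[ax]
    if (n < 2L) next
    lo <- c(1L, seq_len(n - 1L))
    hi <- c(seq.int(2L, n), n)
    a <- switch(ax,
                (a[lo, , , drop = FALSE] + 2 * a + a[hi, , , drop = FALSE]) / 4,
                (a[, lo, , drop = FALSE] + 2 * a + a[, hi, , drop = FALSE]) / 4,
                (a[, , lo, drop = FALSE] + 2 * a + a[, , hi, drop = FALSE]) / 4)
  }
  a
}

# Sample a volume at arbitrary world points (N x 3). Outside -> 0.
sample_volume <- function(vol, pts, interpolation = c("linear", "nearest")) {
  interpolation <- match.arg(interpolation)
  dm <- dim(vol$data)
  inv <- solve(vol$affine)
  idx <- sweep(pts %*% t(inv[1:3, 1:3]), 2, inv[1:3, 4], "+")  # 0-based
  if (interpolation == "nearest") {
    i <- round(idx[, 1]); j <- round(idx[, 2]); k <- round(idx[, 3])
    ok <- i >= 0 & i <= dm[1] - 1 & j >= 0 & j <= dm[2] - 1 & k >= 0 & k <= dm[3] - 1
    vals <- numeric(nrow(pts))
    lin <- i[ok] + dm[1] * (j[ok] + dm[2] * k[ok]) + 1
    vals[ok] <- vol$data[lin]
    return(vals)
  }
  # trilinear with clamp at a half-voxel border; fully outside -> 0
  eps <- 1e-7
  ok <- idx[, 1] >= -0.5 - eps & idx[, 1] <= dm[1] - 0.5 + eps &
        idx[, 2] >= -0.5 - eps & idx[, 2] <= dm[2] - 0.5 + eps &
        idx[, 3] >= -0.5 - eps & idx[, 3] <= dm[3] - 0.5 + eps
  vals <- numeric(nrow(pts))
  if (!any(ok)) return(vals)
  p <- idx[ok, , drop = FALSE]
  f <- floor(p + eps)
  w <- p - f
  acc <- numeric(nrow(p))
  for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
    wt <- (if (di) w[, 1] else 1 - w[, 1]) *
          (if (dj) w[, 2] else 1 - w[, 2]) *
          (if (dk) w[, 3] else 1 - w[, 3])
    nz <- wt > 0
    if (!any(nz)) next
    ii <- pmin(pmax(f[nz, 1] + di, 0), dm[1] - 1)
    jj <- pmin(pmax(f[nz, 2] + dj, 0), dm[2] - 1)
    kk <- pmin(pmax(f[nz, 3] + dk, 0), dm[3] - 1)
    acc[nz] <- acc[nz] + wt[nz] * vol$data[ii + dm[1] * (jj + dm[2] * kk) + 1]
  }
  vals[ok] <- acc
  vals
}

#' Construct a rigid transform
#'
#' Maps world points of the fixed image into the moving image's world space:
#' `x_moving = R (x_fixed - center) + center + translation`. Resampling a
#' moving image through the transform pulls its intensities onto the fixed
#' grid.
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1.
#' @param translation Length-3 numeric, mm.
#' @param center Length-3 numeric, rotation center in world mm.
#' @param fixed An [image_volume()] defining the fixed (target) grid.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0),
                            center = c(0, 0, 0), fixed) {
  rotation <- as.matrix(rotation)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6 || abs(det(rotation) - 1) > 1e-6) {
    stop("rotation must be orthonormal with determinant +1", call. = FALSE)
  }
  structure(list(rotation = rotation, translation = as.numeric(translation),
                 center = as.numeric(center),
                 fixed_affine = fixed$affine, fixed_dim = dim(fixed$data)),
            class = "rigid_transform")
}

transform_points <- function(t, pts) {
  sweep(sweep(pts, 2, t$center) %*% t(t$rotation), 2, t$center + t$translation, "+")
}

fixed_grid_of <- function(t) {
  image_volume(array(0, dim = t$fixed_dim), t$fixed_affine)
}

#' Rigidly register a moving volume onto a fixed volume
#'
#' Estimates a 6-degree-of-freedom (translation + rotation) transform that
#' aligns `moving` with `fixed` by minimizing the mean squared intensity
#' difference, using a center-of-mass translation initialization followed by
#' Nelder-Mead refinement on a subsampled point set. Used to bring the FLAIR
#' sequence (and its whole-tumor mask) into the post-contrast T1 coordinate
#' space.
#'
#' @param moving,fixed [image_volume()] objects with overlapping anatomy.
#' @param assume_registered If `TRUE`, skip estimation: the transform is
#'   exactly identity and `moving` is only grid-resampled onto `fixed`.
#' @param allow_identity_fallback If `TRUE`, a registration that fails to
#'   improve on the identity alignment returns the identity transform with a
#'   warning instead of erroring.
#' @param max_points Maximum number of sample points used by the metric.
#' @param maxit Maximum Nelder-Mead iterations per start.
#' @param restarts Number of Nelder-Mead restarts from the incumbent (the
#'   simplex collapses early along the shallow rotation directions).
#' @return A list with `resampled` (moving pulled onto the fixed grid,
#'   trilinear) and `transform` (a [rigid_transform()] with attributes
#'   `metric_before` / `metric_after`, mean squared differences).
#' @export
rigid_register <- function(moving, fixed, assume_registered = FALSE,
                           allow_identity_fallback = FALSE,
                           max_points = 40000L, maxit = 2000L, restarts = 1L) {
  center <- as.numeric(vol_index_to_world(fixed, matrix((dim(fixed$data) - 1) / 2 + 1, 3, 1)))
  if (assume_registered) {
    t <- rigid_transform(diag(3), c(0, 0, 0), center, fixed)
    return(list(resampled = resample_to_grid(moving, fixed, "linear"), transform = t))
  }
  # Pre-smooth both images for the metric only: attenuates image noise so
  # the anatomy, not the noise, dominates the cost surface.
  fixed_s <- image_volume(smooth3(fixed$data), fixed$affine)
  moving_s <- image_volume(smooth3(moving$data), moving$affine)
  dm <- dim(fixed$data)
  step <- max(1L, ceiling((prod(dm) / max_points)^(1 / 3)))
  idx <- as.matrix(expand.grid(seq(1L, dm[1], by = step),
                               seq(1L, dm[2], by = step),
                               seq(1L, dm[3], by = step))) - 1L
  # Jitter the sample points off the voxel lattice (fixed, deterministic
  # offsets). Trilinear sampling attenuates noise by an amount that depends
  # on where a sample falls between voxel centers; with on-lattice samples
  # that smoothing differential systematically favors slightly rotated
  # poses over an on-grid optimum. Off-lattice samples give every pose the
  # same fractional-offset statistics, removing the bias.
  old_seed <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(20260925L)
  jitter <- matrix(stats::runif(length(idx)), ncol = 3)
  if (is.null(old_seed)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old_seed, envir = globalenv())
  }
  idxj <- idx + jitter
  m <- fixed$affine
  pts <- sweep(idxj %*% t(m[1:3, 1:3]), 2, m[1:3, 4], "+")
  fvals <- sample_volume(fixed_s, pts, "linear")

  par_transform <- function(par) {
    rigid_transform(rotation_matrix(par[4:6]), par[1:3], center, fixed)
  }
  mse <- function(par) {
    mvals <- sample_volume(moving_s, transform_points(par_transform(par), pts), "linear")
    mean((mvals - fvals)^2)
  }

  # center-of-mass translation initialization
  com <- function(vol) {
    w <- pmax(vol$data, 0)
    s <- sum(w)
    if (s <= 0) return(as.numeric(vol_index_to_world(vol, matrix((dim(vol$data) - 1) / 2 + 1, 3, 1))))
    mi <- apply(w, 1, sum); mj <- apply(w, 2, sum); mk <- apply(w, 3, sum)
    ci <- c(sum(mi * (seq_along(mi) - 1)) / s,
            sum(mj * (seq_along(mj) - 1)) / s,
            sum(mk * (seq_along(mk) - 1)) / s)
    as.numeric(vol$affine[1:3, 1:3] %*% ci + vol$affine[1:3, 4])
  }
  t_init <- com(moving_s) - com(fixed_s)

  mse_identity <- mse(rep(0, 6))
  # Staged Nelder-Mead: translation only, then the full six degrees of
  # freedom from there, with restarts (the simplex tends to collapse early
  # along the shallow rotation directions). Keep the best pose seen.
  fit_t <- stats::optim(t_init, function(p) mse(c(p, 0, 0, 0)),
                        method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = 1e-12))
  fit <- list(par = c(fit_t$par, 0, 0, 0), value = fit_t$value)
  for (i in seq_len(1L + restarts)) {
    fit2 <- stats::optim(fit$par, mse, method = "Nelder-Mead",
                         control = list(maxit = maxit, reltol = 1e-12))
    if (fit2$value < fit$value) fit <- fit2
  }
  if (fit$value > mse_identity) {
    msg <- "rigid registration did not improve on the identity alignment"
    if (!allow_identity_fallback) stop(msg, call. = FALSE)
    warning(paste0(msg, "; returning identity transform"))
    t <- rigid_transform(diag(3), c(0, 0, 0), center, fixed)
    attr(t, "metric_before") <- mse_identity
    attr(t, "metric_after") <- mse_identity
    return(list(resampled = resample_to_grid(moving, fixed, "linear"), transform = t))
  }
  t <- par_transform(fit$par)
  attr(t, "metric_before") <- mse_identity
  attr(t, "metric_after") <- fit$value
  res <- image_volume(array(sample_volume(moving, transform_points(t, grid_world_points(fixed)), "linear"),
                            dim = dim(fixed$data)), fixed$affine)
  list(resampled = res, transform = t)
}

#' Warp a binary mask through a rigid transform
#'
#' Pulls the mask onto the transform's fixed grid with nearest-neighbor
#' interpolation, so the output is binary and integer-mm translations on a
#' 1 mm grid shift the mask by exactly that many voxels.
#'
#' @param mask An [binary_mask()] on the moving image's grid.
#' @param t A [rigid_transform()] produced against that grid.
#' @return An [binary_mask()] on the fixed grid.
#' @export
apply_transform_to_mask <- function(mask, t) {
  fixed <- fixed_grid_of(t)
  pts <- transform_points(t, grid_world_points(fixed))
  vals <- sample_volume(mask, pts, "nearest")
  binary_mask(array(as.integer(vals > 0.5), dim = t$fixed_dim), fixed)
}

#' Preprocess a study onto one common 1 mm isotropic grid
#'
#' Implements the preprocessing contract of the placement pipeline: all
#' images and masks are brought onto a single 1 mm isotropic axis-aligned
#' grid anchored to the post-contrast T1 image when enhancement imaging is
#' available, or to the FLAIR image otherwise (in which case co-registration
#' is skipped entirely).
#'
#' @param t1c,flair [image_volume()] objects or `NULL`.
#' @param core,necrosis Masks on the T1C+ grid, or `NULL`.
#' @param whole Mask on the FLAIR grid, or `NULL`.
#' @param target_spacing_mm Isotropic spacing of the common grid (default 1).
#' @param assume_registered Treat FLAIR as already aligned with T1C+ and
#'   only grid-resample it.
#' @param allow_identity_fallback Passed to [rigid_register()].
#' @return A list with `anchor` (`"t1c"` or `"flair"`), `reference` (the
#'   resampled anchor volume), `t1c`, `flair` (resampled volumes or `NULL`),
#'   `seg` (a [tumor_segmentation()] on the common grid) and `transform`
#'   (the FLAIR-to-anchor [rigid_transform()], or `NULL`).
#' @export
preprocess_study <- function(t1c = NULL, flair = NULL, core = NULL,
                             necrosis = NULL, whole = NULL,
                             target_spacing_mm = 1, assume_registered = FALSE,
                             allow_identity_fallback = FALSE) {
  enhancing_inputs <- !is.null(t1c) && !is.null(core)
  if (!enhancing_inputs && (is.null(flair) || is.null(whole))) {
    stop("supply at least (t1c + core mask) or (flair + whole mask)", call. = FALSE)
  }
  anchor <- if (enhancing_inputs) "t1c" else "flair"
  anchor_img <- if (enhancing_inputs) t1c else flair
  ref <- resample_isotropic(anchor_img, target_spacing_mm, "linear")

  out <- list(anchor = anchor, reference = ref, t1c = NULL, flair = NULL,
              transform = NULL)
  core_r <- necro_r <- whole_r <- NULL
  if (enhancing_inputs) {
    out$t1c <- ref
    core_r <- resample_to_grid(core, ref, "nearest")
    if (!is.null(necrosis)) necro_r <- resample_to_grid(necrosis, ref, "nearest")
    if (!is.null(flair)) {
      reg <- rigid_register(flair, ref, assume_registered = assume_registered,
                            allow_identity_fallback = allow_identity_fallback)
      out$flair <- reg$resampled
      out$transform <- reg$transform
      if (!is.null(whole)) whole_r <- apply_transform_to_mask(whole, reg$transform)
    }
  } else {
    out$flair <- ref
    whole_r <- resample_to_grid(whole, ref, "nearest")
  }
  out$seg <- tumor_segmentation(core = core_r, necrosis = necro_r, whole = whole_r)
  out
}
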