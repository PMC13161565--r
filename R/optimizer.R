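#' Select the placement mode for a segmentation
#'
#' Enhancing mode is used when an enhancing-core mask is present with volume
#' at least `min_core_mm3`; otherwise the pipeline falls back to FLAIR-only
#' mode (typical for non-enhancing low-grade gliomas), which requires the
#' whole-tumor mask.
#'
#' @param seg A [tumor_segmentation()].
#' @param min_core_mm3 Minimum core volume (mm^3) for enhancing mode.
#' @return `"enhancing"` or `"flair_only"`.
#' @export
select_mode <- function(seg, min_core_mm3 = 100) {
  core_vol <- if (is.null(seg$core)) 0 else mask_volume(seg$core)
  if (core_vol >= min_core_mm3) return("enhancing")
  if (is.null(seg$whole)) {
    stop("FLAIR-only mode selected but the whole-tumor mask is absent", call. = FALSE)
  }
  "flair_only"
}

## ---- exact lattice scoring machinery --------------------------------------
##
## Candidate centers form a lattice commensurate with the 1 mm voxel grid, so
## for a fixed rotation the set of voxel-center offsets enclosed by the cube
## is one fixed "kernel" shared by all centers. The kernel decomposes into
## contiguous runs along x (the cube is convex), and enclosed counts for all
## centers reduce to differences of an x-prefix-summed, zero-padded copy of
## the mask. Membership decisions go through the same compiled test as
## score_placement(), so the counts are bit-identical to per-voxel scoring.

space_kernel_geometry <- function(space) {
  side <- space$side_mm
  m_max <- as.integer(ceiling(side * sqrt(3) / 2 + 0.5))
  u0 <- c(space$centers_x[1], space$centers_y[1], space$centers_z[1]) - space$grid_origin
  b0 <- round(u0)
  eps <- b0 - u0  # constant fractional offset of centers from the voxel lattice
  mr <- seq(-m_max, m_max)
  mgrid <- as.matrix(expand.grid(mx = mr, my = mr, mz = mr))
  list(m_max = m_max, pad = m_max + 1L, eps = eps, mgrid = mgrid)
}

# Integer x-runs of the voxel-offset kernel for one rotation.
kernel_runs <- function(geom, R, side) {
  d <- sweep(geom$mgrid, 2, geom$eps, "+")
  keep <- cpp_points_in_cube(d, R, c(0, 0, 0), side)
  m <- geom$mgrid[keep, , drop = FALSE]
  key <- (m[, 3] + geom$m_max) * (2L * geom$m_max + 1L) + (m[, 2] + geom$m_max)
  o <- order(key, m[, 1])
  m <- m[o, , drop = FALSE]
  key <- key[o]
  first <- !duplicated(key)
  last <- rev(!duplicated(rev(key)))
  cbind(mx0 = m[first, 1], mx1 = m[last, 1], my = m[first, 2], mz = m[first, 3])
}

# Zero-padded, x-prefix-summed copy of a mask array.
padded_cumsum <- function(mask, pad) {
  dm <- dim(mask$data)
  pd <- dm + 2L * pad
  arr <- array(0, dim = pd)
  arr[(pad + 1):(pad + dm[1]), (pad + 1):(pad + dm[2]), (pad + 1):(pad + dm[3])] <- mask$data
  list(cums = cpp_cumsum_x(as.numeric(arr), pd), dims = pd)
}

# 0-based padded-array base indices of the candidate centers, per axis.
space_base_indices <- function(space, pad) {
  list(bx = as.integer(round(space$centers_x - space$grid_origin[1])) + pad,
       by = as.integer(round(space$centers_y - space$grid_origin[2])) + pad,
       bz = as.integer(round(space$centers_z - space$grid_origin[3])) + pad)
}

conv_scores <- function(pc, bases, runs) {
  cpp_conv_runs(pc$cums, pc$dims, runs, bases$bx, bases$by, bases$bz)
}

# Tie-breaking rank of a center cell (1-based linear index, x fastest) under
# the deterministic iteration order: centers ascending by (x, y, z).
center_rank <- function(cell, nx, ny, nz) {
  ix <- (cell - 1L) %% nx
  iy <- ((cell - 1L) %/% nx) %% ny
  iz <- (cell - 1L) %/% (nx * ny)
  (ix * ny + iy) * nz + iz + 1
}

## ---- optimizer -------------------------------------------------------------

#' Find the optimal MRS cube placement
#'
#' Exhaustively evaluates every candidate center and rotation of the search
#' space built around the target mask (enhancing core, or whole tumor in
#' FLAIR-only mode). In enhancing mode the search restricts to feasible
#' placements (zero enclosed necrosis) and maximizes the lexicographic key
#' (enclosed core volume, enclosed whole-tumor volume); in FLAIR-only mode
#' it maximizes enclosed whole-tumor volume. Remaining ties are broken by
#' the earliest candidate in the deterministic iteration order of
#' [build_search_space()]. If no feasible placement exists in enhancing
#' mode, a fallback placement minimizing enclosed necrosis (then maximizing
#' core, then whole) is returned and flagged -- or an error is raised when
#' `cfg$fallback == "forbid"`.
#'
#' The result is integer-exactly identical to [brute_force_oracle()] for
#' the same inputs and configuration.
#'
#' @param seg A [tumor_segmentation()] on the common 1 mm grid.
#' @param cfg A [placement_config()].
#' @return A list of class `placement_report` with elements `placement`
#'   ([cube_placement()]), `score`, `mode`, `fallback_used`, `search` and
#'   `n_candidates_evaluated`.
#' @export
optimize_placement <- function(seg, cfg = placement_config()) {
  mode <- select_mode(seg, cfg$min_core_mm3)
  target <- if (mode == "enhancing") seg$core else seg$whole
  space <- build_search_space(target, cfg)
  geom <- space_kernel_geometry(space)
  bases <- space_base_indices(space, geom$pad)
  nx <- length(space$centers_x); ny <- length(space$centers_y); nz <- length(space$centers_z)
  n_angles <- space$n_angles

  if (mode == "enhancing") {
    pc_core <- padded_cumsum(seg$core, geom$pad)
    pc_necro <- if (!is.null(seg$necrosis)) padded_cumsum(seg$necrosis, geom$pad) else NULL
    best_feas <- NULL   # list(core, cells = list of (r, cellidx))
    best_inf <- NULL    # list(necro, core, cells)
    for (r in seq_len(n_angles)) {
      runs <- kernel_runs(geom, rotation_matrix(space$angles[r, ]), space$side_mm)
      core_sc <- conv_scores(pc_core, bases, runs)
      necro_sc <- if (is.null(pc_necro)) numeric(length(core_sc)) else conv_scores(pc_necro, bases, runs)
      feas <- necro_sc == 0
      if (any(feas)) {
        mx <- max(core_sc[feas])
        if (is.null(best_feas) || mx > best_feas$core) {
          best_feas <- list(core = mx, cells = list())
        }
        if (mx == best_feas$core) {
          cells <- which(feas & core_sc == mx)
          best_feas$cells[[length(best_feas$cells) + 1L]] <- cbind(r, cells)
        }
      } else if (is.null(best_feas)) {
        mn <- min(necro_sc)
        mc <- max(core_sc[necro_sc == mn])
        if (is.null(best_inf) || mn < best_inf$necro ||
            (mn == best_inf$necro && mc > best_inf$core)) {
          best_inf <- list(necro = mn, core = mc, cells = list())
        }
        if (mn == best_inf$necro && mc == best_inf$core) {
          cells <- which(necro_sc == mn & core_sc == mc)
          best_inf$cells[[length(best_inf$cells) + 1L]] <- cbind(r, cells)
        }
      }
    }
    fallback_used <- is.null(best_feas)
    if (fallback_used && cfg$fallback == "forbid") {
      stop(errorCondition(
        "no feasible placement: every candidate cube encloses necrosis and fallback is forbidden",
        class = c("mrsplace_infeasible", "error", "condition")))
    }
    pool <- do.call(rbind, if (fallback_used) best_inf$cells else best_feas$cells)
    win <- resolve_ties(pool, space, seg, nx, ny, nz, tiebreak_whole = TRUE)
    placement <- cube_placement(win$center, space$angles[win$r, ], space$side_mm)
    score <- score_placement(placement, seg)
  } else {
    pc_whole <- padded_cumsum(seg$whole, geom$pad)
    best <- NULL
    for (r in seq_len(n_angles)) {
      runs <- kernel_runs(geom, rotation_matrix(space$angles[r, ]), space$side_mm)
      whole_sc <- conv_scores(pc_whole, bases, runs)
      mx <- max(whole_sc)
      if (is.null(best) || mx > best$whole) best <- list(whole = mx, cells = list())
      if (mx == best$whole) {
        cells <- which(whole_sc == mx)
        best$cells[[length(best$cells) + 1L]] <- cbind(r, cells)
      }
    }
    fallback_used <- FALSE
    pool <- do.call(rbind, best$cells)
    win <- resolve_ties(pool, space, seg, nx, ny, nz, tiebreak_whole = FALSE)
    placement <- cube_placement(win$center, space$angles[win$r, ], space$side_mm)
    score <- list(core_mm3 = 0, necrosis_mm3 = 0, whole_mm3 = best$whole, feasible = TRUE)
    class(score) <- "placement_score"
  }

  structure(list(placement = placement, score = score, mode = mode,
                 fallback_used = fallback_used, search = space,
                 n_candidates_evaluated = space$n_centers * space$n_angles),
            class = "placement_report")
}

# Resolve remaining ties in a candidate pool (matrix of rotation index r and
# center cell): maximize enclosed whole-tumor volume (enhancing mode), then
# take the earliest candidate in the deterministic iteration order.
resolve_ties <- function(pool, space, seg, nx, ny, nz, tiebreak_whole) {
  r <- pool[, 1]
  cell <- pool[, 2]
  ranks <- center_rank(cell, nx, ny, nz)
  if (tiebreak_whole && !is.null(seg$whole) && nrow(pool) > 1L) {
    pts <- seg_points(seg, "whole")
    whole <- vapply(seq_len(nrow(pool)), function(i) {
      ctr <- c(space$centers_x[(cell[i] - 1L) %% nx + 1L],
               space$centers_y[((cell[i] - 1L) %/% nx) %% ny + 1L],
               space$centers_z[(cell[i] - 1L) %/% (nx * ny) + 1L])
      if (nrow(pts) == 0L) 0 else
        cpp_count_in_cube(pts, rotation_matrix(space$angles[r[i], ]), ctr, space$side_mm)
    }, numeric(1))
    keep <- whole == max(whole)
    r <- r[keep]; cell <- cell[keep]; ranks <- ranks[keep]
  }
  g <- (ranks - 1) * space$n_angles + r
  i <- which.min(g)
  cell_i <- cell[i]
  center <- c(space$centers_x[(cell_i - 1L) %% nx + 1L],
              space$centers_y[((cell_i - 1L) %/% nx) %% ny + 1L],
              space$centers_z[(cell_i - 1L) %/% (nx * ny) + 1L])
  list(r = r[i], center = center)
}

#' Brute-force reference optimizer
#'
#' Literal loop over every candidate placement of the search space, calling
#' [score_placement()] once per placement with no precomputation shared
#' across placements, applying the same objective, fallback and tie rules
#' as [optimize_placement()]. Serves as the independent reference that the
#' fast optimizer must match integer-exactly; guarded to small candidate
#' sets.
#'
#' @param seg A [tumor_segmentation()] on the common 1 mm grid.
#' @param cfg A [placement_config()].
#' @param guard Maximum admissible number of placements.
#' @return A `placement_report`, as [optimize_placement()].
#' @export
brute_force_oracle <- function(seg, cfg = placement_config(), guard = 1e6) {
  mode <- select_mode(seg, cfg$min_core_mm3)
  target <- if (mode == "enhancing") seg$core else seg$whole
  space <- build_search_space(target, cfg)
  n_total <- space$n_centers * space$n_angles
  if (n_total > guard) {
    stop(sprintf("candidate set too large for the brute-force oracle (%g > %g)",
                 n_total, guard), call. = FALSE)
  }
  centers <- space_centers_ordered(space)
  n_angles <- space$n_angles

  best <- NULL  # list(key, g, placement, score)
  better <- function(a, b) {
    # lexicographic comparison of candidate keys; TRUE if a strictly better
    for (i in seq_along(a)) {
      if (a[i] > b[i]) return(TRUE)
      if (a[i] < b[i]) return(FALSE)
    }
    FALSE
  }
  for (r in seq_len(n_angles)) {
    ang <- space$angles[r, ]
    for (ci in seq_len(nrow(centers))) {
      p <- cube_placement(centers[ci, ], ang, space$side_mm)
      sc <- score_placement(p, seg)
      key <- if (mode == "flair_only") {
        sc$whole_mm3
      } else if (sc$feasible) {
        c(1, sc$core_mm3, sc$whole_mm3, 0)
      } else {
        c(0, -sc$necrosis_mm3, sc$core_mm3, sc$whole_mm3)
      }
      g <- (ci - 1) * n_angles + r
      if (is.null(best) || better(key, best$key) ||
          (!better(best$key, key) && g < best$g)) {
        best <- list(key = key, g = g, placement = p, score = sc)
      }
    }
  }
  fallback_used <- mode == "enhancing" && !best$score$feasible
  score <- best$score
  if (mode == "flair_only") {
    score <- list(core_mm3 = 0, necrosis_mm3 = 0, whole_mm3 = best$score$whole_mm3,
                  feasible = TRUE)
    class(score) <- "placement_score"
  }
  structure(list(placement = best$placement, score = score, mode = mode,
                 fallback_used = fallback_used, search = space,
                 n_candidates_evaluated = n_total),
            class = "placement_report")
}

#' @export
print.placement_report <- function(x, ...) {
  cat(sprintf("<placement_report> mode %s%s\n", x$mode,
              if (x$fallback_used) " (FALLBACK: no necrosis-free placement)" else ""))
  print(x$placement)
  print(x$score)
  cat(sprintf("  %d candidates evaluated\n", x$n_candidates_evaluated))
  invisible(x)
}

## ---- heatmaps --------------------------------------------------------------

#' Interpretability heatmap of enclosed volume over candidate centers
#'
#' For one fixed rotation, computes the enclosed target volume (enhancing
#' core, or whole tumor in FLAIR-only mode) of a cube centered at every
#' candidate lattice position. Cells whose cube would enclose necrosis
#' (enhancing mode) are marked invalid so a renderer can leave them
#' uncolored; positions outside the search space are absent from the
#' lattice altogether and export as the NaN sentinel.
#'
#' @param seg A [tumor_segmentation()] on the common 1 mm grid.
#' @param rotation_deg Fixed rotation triple for the map (default identity).
#' @param cfg A [placement_config()].
#' @return A list of class `mrs_heatmap` with 3D arrays `values` (mm^3) and
#'   `valid` over the candidate-center lattice, plus the lattice
#'   coordinates, rotation, target name and mode.
#' @export
generate_heatmap <- function(seg, rotation_deg = c(0, 0, 0), cfg = placement_config()) {
  mode <- select_mode(seg, cfg$min_core_mm3)
  target_name <- if (mode == "enhancing") "core" else "whole"
  space <- build_search_space(seg[[target_name]], cfg)
  geom <- space_kernel_geometry(space)
  bases <- space_base_indices(space, geom$pad)
  runs <- kernel_runs(geom, rotation_matrix(rotation_deg), space$side_mm)
  nx <- length(space$centers_x); ny <- length(space$centers_y); nz <- length(space$centers_z)

  vals <- conv_scores(padded_cumsum(seg[[target_name]], geom$pad), bases, runs)
  valid <- rep(TRUE, length(vals))
  if (mode == "enhancing" && !is.null(seg$necrosis)) {
    necro <- conv_scores(padded_cumsum(seg$necrosis, geom$pad), bases, runs)
    valid <- necro == 0
  }
  structure(list(values = array(vals, dim = c(nx, ny, nz)),
                 valid = array(valid, dim = c(nx, ny, nz)),
                 rotation_deg = as.numeric(rotation_deg),
                 target = target_name, mode = mode,
                 centers_x = space$centers_x, centers_y = space$centers_y,
                 centers_z = space$centers_z,
                 center_stride_mm = space$center_stride_mm,
                 side_mm = space$side_mm),
            class = "mrs_heatmap")
}

#' Export a heatmap as a NIfTI overlay (and optional mid-slice image)
#'
#' Spreads the candidate-lattice values onto the reference grid with
#' nearest-neighbor interpolation; grid voxels outside the candidate
#' lattice, and invalid cells, receive the NaN sentinel. Optionally also
#' writes a PNG of the axial mid-slice for quick review (requires the
#' `png` package).
#'
#' @param h An `mrs_heatmap`.
#' @param reference [image_volume()] whose grid the overlay is written on.
#' @param path Output NIfTI path.
#' @param slice_png Optional path for a PNG of the axial mid-slice.
#' @return `path`, invisibly.
#' @export
export_heatmap <- function(h, reference, path, slice_png = NULL) {
  dm <- dim(reference$data)
  pts <- grid_world_points(reference)
  stride <- h$center_stride_mm
  ci <- round((pts[, 1] - h$centers_x[1]) / stride)
  cj <- round((pts[, 2] - h$centers_y[1]) / stride)
  ck <- round((pts[, 3] - h$centers_z[1]) / stride)
  nx <- length(h$centers_x); ny <- length(h$centers_y); nz <- length(h$centers_z)
  ok <- ci >= 0 & ci < nx & cj >= 0 & cj < ny & ck >= 0 & ck < nz
  vals <- rep(NaN, nrow(pts))
  lin <- ci[ok] + nx * (cj[ok] + ny * ck[ok]) + 1
  v <- h$values[lin]
  v[!h$valid[lin]] <- NaN
  vals[ok] <- v
  out <- image_volume(array(vals, dim = dm), reference$affine)
  write_volume(out, path)
  if (!is.null(slice_png)) {
    if (!requireNamespace("png", quietly = TRUE)) {
      warning("the png package is not installed; skipping mid-slice image")
    } else {
      sl <- out$data[, , ceiling(dm[3] / 2)]
      mx <- suppressWarnings(max(sl, na.rm = TRUE))
      if (!is.finite(mx) || mx <= 0) mx <- 1
      img <- sl / mx
      img[is.na(img)] <- 0
      # flip to a conventional row-major raster (anterior up)
      png::writePNG(t(img)[rev(seq_len(ncol(sl))), , drop = FALSE], slice_png)
    }
  }
  invisible(path)
}
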