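test_that("mode selection honors the minimum core volume", {
  ph <- tiny_phantom()
  grid <- ph$t1c
  empty <- binary_mask(array(0L, dim(grid$data)), grid)
  expect_identical(select_mode(tumor_segmentation(core = empty, whole = ph$seg$whole)),
                   "flair_only")
  expect_identical(select_mode(ph$seg, min_core_mm3 = 100), "enhancing")
  # a 50 mm^3 speck falls below the default threshold
  speck <- array(0L, dim(grid$data)); speck[20:23, 20:23, 20:22] <- 1L  # 48 voxels
  seg_speck <- tumor_segmentation(core = binary_mask(speck, grid), whole = ph$seg$whole)
  expect_identical(select_mode(seg_speck, min_core_mm3 = 100), "flair_only")
  expect_identical(select_mode(seg_speck, min_core_mm3 = 10), "enhancing")
  expect_error(select_mode(tumor_segmentation(core = empty)), "whole-tumor mask is absent")
})

test_that("the fast optimizer equals the brute-force loop on small cases", {
  cfg <- placement_config(center_stride_mm = 8, angle_step_deg = 45)
  for (ph in list(tiny_phantom(seed = 31L), tiny_phantom(seed = 32L, necrosis = FALSE))) {
    report_equal(optimize_placement(ph$seg, cfg), brute_force_oracle(ph$seg, cfg))
  }
  # FLAIR-only phantom
  spec <- phantom_spec(shape = c(48L, 48L, 48L), core_center_mm = c(23.5, 25.5, 24.5),
                       core_radii_mm = c(0, 0, 0), necrosis_radii_mm = c(0, 0, 0),
                       edema_radii_mm = c(8, 7, 6), enhancing = FALSE, seed = 33L)
  ph <- generate_phantom(spec)
  r1 <- optimize_placement(ph$seg, cfg)
  r2 <- brute_force_oracle(ph$seg, cfg)
  expect_identical(r1$mode, "flair_only")
  expect_identical(r1$score$core_mm3, 0)
  report_equal(r1, r2)
})

test_that("a containable spherical core is fully enclosed", {
  spec <- phantom_spec(shape = c(64L, 64L, 64L), core_center_mm = c(32.5, 30.5, 33.5),
                       core_radii_mm = c(8, 8, 8), necrosis_radii_mm = c(0, 0, 0),
                       edema_radii_mm = c(10, 10, 10), seed = 41L)
  ph <- generate_phantom(spec)
  rep <- optimize_placement(ph$seg, placement_config(center_stride_mm = 4, angle_step_deg = 45))
  expect_identical(rep$score$core_mm3, as.numeric(sum(ph$seg$core$data)))
  expect_false(rep$fallback_used)
})

test_that("unavoidable necrosis triggers the flagged fallback", {
  ph <- generate_phantom(phantom_suite("necrosis_everywhere")[[1]])
  cfg <- placement_config(center_stride_mm = 8, angle_step_deg = 45)
  rep <- optimize_placement(ph$seg, cfg)
  expect_true(rep$fallback_used)
  expect_false(rep$score$feasible)
  expect_gt(rep$score$necrosis_mm3, 0)
  report_equal(rep, brute_force_oracle(ph$seg, cfg))
  expect_error(optimize_placement(ph$seg, placement_config(center_stride_mm = 8,
                                                           angle_step_deg = 45,
                                                           fallback = "forbid")),
               class = "mrsplace_infeasible")
})

test_that("non-fallback placements truly enclose no necrosis", {
  ph <- roomy_phantom()
  rep <- optimize_placement(ph$seg, placement_config(center_stride_mm = 4, angle_step_deg = 45))
  expect_false(rep$fallback_used)
  cube <- rasterize_cube(rep$placement, ph$t1c)
  expect_equal(sum(cube$data & ph$seg$necrosis$data), 0)
})

test_that("optimization is deterministic for fixed inputs", {
  ph <- tiny_phantom()
  cfg <- placement_config(center_stride_mm = 8, angle_step_deg = 45)
  report_equal(optimize_placement(ph$seg, cfg), optimize_placement(ph$seg, cfg))
})

test_that("heatmaps agree with the optimizer restricted to their rotation", {
  ph <- roomy_phantom()
  cfg <- placement_config(center_stride_mm = 4, angle_step_deg = 45)
  rep <- optimize_placement(ph$seg, cfg)
  h <- generate_heatmap(ph$seg, rep$placement$angles_deg, cfg)
  expect_identical(max(h$values[h$valid]), rep$score$core_mm3)
  expect_true(all(h$values >= 0))
  expect_true(all(h$values <= 20^3))

  # without necrosis every in-lattice cell is valid
  ph2 <- tiny_phantom(necrosis = FALSE)
  h2 <- generate_heatmap(ph2$seg, c(0, 0, 0), cfg)
  expect_true(all(h2$valid))

  # with unavoidable necrosis no cell is valid
  ph3 <- generate_phantom(phantom_suite("necrosis_everywhere")[[1]])
  h3 <- generate_heatmap(ph3$seg, c(0, 0, 0), placement_config(center_stride_mm = 8))
  expect_false(any(h3$valid))
})

test_that("exported heatmaps carry values and NaN sentinels onto the grid", {
  ph <- tiny_phantom()
  cfg <- placement_config(center_stride_mm = 4, angle_step_deg = 45)
  h <- generate_heatmap(ph$seg, c(0, 0, 0), cfg)
  f <- tempfile(fileext = ".nii.gz")
  png_path <- if (requireNamespace("png", quietly = TRUE)) tempfile(fileext = ".png") else NULL
  export_heatmap(h, ph$t1c, f, slice_png = png_path)
  vol <- read_volume(f)
  expect_identical(dim(vol$data), dim(ph$t1c$data))
  expect_true(anyNA(vol$data))  # outside the lattice -> sentinel
  # lattice points round-trip exactly
  i <- round(h$centers_x[1]) + 1L; j <- round(h$centers_y[1]) + 1L; k <- round(h$centers_z[1]) + 1L
  expect_identical(vol$data[i, j, k],
                   if (h$valid[1, 1, 1]) h$values[1, 1, 1] else NaN)
  if (!is.null(png_path)) {
    img <- png::readPNG(png_path)
    expect_identical(dim(img)[1:2], dim(ph$t1c$data)[c(2, 1)])
  }
})

test_that("report invariants hold across modes", {
  ph <- tiny_phantom()
  cfg <- placement_config(center_stride_mm = 8, angle_step_deg = 45)
  rep <- optimize_placement(ph$seg, cfg)
  if (!rep$fallback_used) expect_true(rep$score$feasible)
  expect_identical(rep$n_candidates_evaluated, rep$search$n_centers * rep$search$n_angles)

  spec <- phantom_spec(shape = c(48L, 48L, 48L), core_center_mm = c(24.5, 24.5, 24.5),
                       core_radii_mm = c(0, 0, 0), necrosis_radii_mm = c(0, 0, 0),
                       edema_radii_mm = c(8, 7.5, 7), enhancing = FALSE, seed = 51L)
  rf <- optimize_placement(generate_phantom(spec)$seg, cfg)
  expect_identical(rf$mode, "flair_only")
  expect_identical(rf$score$core_mm3, 0)
  expect_false(rf$fallback_used)
})

test_that("the oracle guard rejects oversized candidate sets", {
  ph <- tiny_phantom()
  expect_error(brute_force_oracle(ph$seg, placement_config(center_stride_mm = 1,
                                                           angle_step_deg = 5)),
               "too large")
})
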