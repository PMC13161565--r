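test_that("bounding boxes are tight around nonzero voxel centers", {
  grid <- image_volume(array(0, c(20, 20, 20)), diag(4))
  arr <- array(0L, c(20, 20, 20))
  arr[6, 6, 6] <- 1L  # 0-based index (5,5,5)
  bb <- compute_bbox(binary_mask(arr, grid))
  expect_equal(unname(bb["lo", ]), c(5, 5, 5))
  expect_equal(unname(bb["hi", ]), c(5, 5, 5))

  arr2 <- array(0L, c(20, 20, 20))
  arr2[3:8, 4:5, 1:10] <- 1L
  bb2 <- compute_bbox(binary_mask(arr2, grid))
  expect_equal(unname(bb2["lo", ]), c(2, 3, 0))
  expect_equal(unname(bb2["hi", ]), c(7, 4, 9))

  expect_error(compute_bbox(binary_mask(array(0L, c(20, 20, 20)), grid)), "empty")
})

test_that("a spherical core's bounding box matches its analytic extent", {
  spec <- phantom_spec(shape = c(48L, 48L, 48L), core_center_mm = c(24.5, 23.5, 24.5),
                       core_radii_mm = c(10, 10, 10), necrosis_radii_mm = c(0, 0, 0),
                       edema_radii_mm = c(12, 12, 12), noise_sd = 0)
  ph <- generate_phantom(spec)
  bb <- compute_bbox(ph$seg$core)
  ctr <- spec$core_center_mm
  expect_lt(max(abs(bb["lo", ] - (ctr - 10))), 1)
  expect_lt(max(abs(bb["hi", ] - (ctr + 10))), 1)
})

test_that("rotation matrices follow the extrinsic x-y-z convention", {
  expect_equal(rotation_matrix(c(0, 0, 0)), diag(3), tolerance = 1e-12)
  # 90 degrees about x maps +y to +z
  expect_equal(as.numeric(rotation_matrix(c(90, 0, 0)) %*% c(0, 1, 0)),
               c(0, 0, 1), tolerance = 1e-9)
  set.seed(5)
  for (i in 1:20) {
    ang <- stats::runif(3, 0, 90)
    R <- rotation_matrix(ang)
    expect_lt(max(abs(crossprod(R) - diag(3))), 1e-9)
    expect_equal(det(R), 1, tolerance = 1e-9)
    expect_equal(R, ref_rotation(ang), tolerance = 1e-12)
  }
})

test_that("scores equal an independent per-voxel loop oracle exactly", {
  ph <- tiny_phantom()
  set.seed(11)
  for (i in 1:25) {
    ctr <- round(stats::runif(3, 15, 33)) + 0.5
    ang <- stats::runif(3, 0, 90)
    p <- cube_placement(ctr, ang, 20)
    sc <- score_placement(p, ph$seg)
    expect_identical(sc$core_mm3, as.numeric(ref_enclosed_count(ph$seg$core, ctr, ang)))
    expect_identical(sc$necrosis_mm3, as.numeric(ref_enclosed_count(ph$seg$necrosis, ctr, ang)))
    expect_identical(sc$whole_mm3, as.numeric(ref_enclosed_count(ph$seg$whole, ctr, ang)))
    expect_identical(sc$feasible, sc$necrosis_mm3 == 0)
  }
})

test_that("empty segmentations score zero and are feasible", {
  grid <- image_volume(array(0, c(30, 30, 30)), diag(4))
  empty <- binary_mask(array(0L, c(30, 30, 30)), grid)
  seg <- tumor_segmentation(core = empty, necrosis = empty, whole = empty)
  sc <- score_placement(cube_placement(c(15, 15, 15)), seg)
  expect_identical(c(sc$core_mm3, sc$necrosis_mm3, sc$whole_mm3), c(0, 0, 0))
  expect_true(sc$feasible)
})

test_that("an axis-aligned cube footprint at an integer center scores 8000", {
  grid <- image_volume(array(0, c(48, 48, 48)), diag(4))
  arr <- array(0L, c(48, 48, 48))
  # voxel centers in [14, 34) per axis: 0-based 14..33 -> 1-based 15..34
  arr[15:34, 15:34, 15:34] <- 1L
  seg <- tumor_segmentation(core = binary_mask(arr, grid))
  sc <- score_placement(cube_placement(c(24, 24, 24)), seg)
  expect_identical(sc$core_mm3, 8000)
})

test_that("scoring refuses grids that are not 1 mm isotropic", {
  grid <- image_volume(array(0, c(20, 20, 20)), diag(c(2, 2, 2, 1)))
  arr <- array(0L, c(20, 20, 20)); arr[10, 10, 10] <- 1L
  seg <- tumor_segmentation(core = binary_mask(arr, grid))
  expect_error(score_placement(cube_placement(c(20, 20, 20)), seg), "1 mm isotropic")
})

test_that("rasterization counts and cross-operation consistency hold", {
  ph <- tiny_phantom()
  p0 <- cube_placement(c(24, 24, 24), c(0, 0, 0))
  expect_identical(sum(rasterize_cube(p0, ph$t1c)$data), 8000L)
  # a 90 degree rotation about any single axis maps the lattice to itself
  for (ax in 1:3) {
    ang <- c(0, 0, 0); ang[ax] <- 90
    expect_identical(sum(rasterize_cube(cube_placement(c(24, 24, 24), ang), ph$t1c)$data), 8000L)
  }
  set.seed(13)
  for (i in 1:20) {
    p <- cube_placement(round(stats::runif(3, 16, 32)) + 0.5, stats::runif(3, 0, 90))
    cube <- rasterize_cube(p, ph$t1c)
    sc <- score_placement(p, ph$seg)
    expect_identical(as.numeric(sum(cube$data & ph$seg$core$data)), sc$core_mm3)
    expect_identical(as.numeric(sum(cube$data & ph$seg$whole$data)), sc$whole_mm3)
  }
  expect_warning(out <- rasterize_cube(cube_placement(c(500, 500, 500)), ph$t1c),
                 "outside")
  expect_equal(sum(out$data), 0)
})

test_that("the search space pads the target box by the full cube diagonal", {
  grid <- image_volume(array(0, c(200, 200, 200)), diag(4))
  arr <- array(0L, c(200, 200, 200))
  arr[96:106, 96:106, 96:106] <- 1L  # bbox (95..105)^3
  target <- binary_mask(arr, grid)
  space <- build_search_space(target, placement_config())
  pad <- 2 * sqrt(3) * 10
  expect_equal(unname(space$limits["lo", ]), rep(95 - pad, 3), tolerance = 1e-12)
  expect_equal(unname(space$limits["hi", ]), rep(105 + pad, 3), tolerance = 1e-12)
  # pad kept at full floating precision, not rounded to 34.64
  expect_identical(space$pad_mm, 2 * sqrt(3) * 10)
  # lattice counts match the closed-form arithmetic per axis
  stride <- space$center_stride_mm
  anchor <- 100
  lo_b <- max(95 - pad, -0.5 + 10 * sqrt(3))
  hi_b <- min(105 + pad, 199.5 - 10 * sqrt(3))
  n_axis <- floor((hi_b - anchor) / stride) + floor((anchor - lo_b) / stride) + 1
  expect_identical(length(space$centers_x), as.integer(n_axis))
  expect_identical(space$n_centers, as.integer(n_axis)^3)
  # the target centroid itself is always a candidate
  expect_true(100 %in% space$centers_x)
})

test_that("angle grids include both endpoints", {
  grid <- image_volume(array(0, c(64, 64, 64)), diag(4))
  arr <- array(0L, c(64, 64, 64)); arr[30:34, 30:34, 30:34] <- 1L
  target <- binary_mask(arr, grid)
  s45 <- build_search_space(target, placement_config(angle_step_deg = 45))
  expect_identical(sort(unique(s45$angles[, 1])), c(0, 45, 90))
  expect_identical(nrow(s45$angles), 27L)
  s37 <- build_search_space(target, placement_config(angle_step_deg = 37))
  expect_identical(sort(unique(s37$angles[, 1])), c(0, 37, 74, 90))
})

test_that("cubes that cannot fit in the image yield an empty candidate set", {
  grid <- image_volume(array(0, c(20, 20, 20)), diag(4))
  arr <- array(0L, c(20, 20, 20)); arr[10, 10, 10] <- 1L
  expect_error(build_search_space(binary_mask(arr, grid), placement_config()),
               "too small")
})

test_that("enlarging a mask never decreases its enclosed volume", {
  ph <- tiny_phantom()
  dilate1 <- function(arr) {
    out <- arr
    d <- dim(arr)
    out[1:(d[1] - 1), , ] <- out[1:(d[1] - 1), , ] | arr[2:d[1], , ]
    out[2:d[1], , ] <- out[2:d[1], , ] | arr[1:(d[1] - 1), , ]
    array(as.integer(out), d)
  }
  grid <- ph$t1c
  bigger <- binary_mask(dilate1(ph$seg$core$data), grid)
  seg_small <- tumor_segmentation(core = ph$seg$core)
  seg_big <- tumor_segmentation(core = bigger)
  set.seed(17)
  for (i in 1:10) {
    p <- cube_placement(round(stats::runif(3, 16, 32)) + 0.5, stats::runif(3, 0, 90))
    expect_gte(score_placement(p, seg_big)$core_mm3, score_placement(p, seg_small)$core_mm3)
  }
})

test_that("scores are equivariant under integer-mm translations", {
  ph <- tiny_phantom()
  d <- dim(ph$seg$core$data)
  shift <- c(4L, -3L, 2L)
  shift_arr <- function(arr) {
    out <- array(0L, d)
    out[(1 + shift[1]):d[1], 1:(d[2] + shift[2]), (1 + shift[3]):d[3]] <-
      arr[1:(d[1] - shift[1]), (1 - shift[2]):d[2], 1:(d[3] - shift[3])]
    out
  }
  grid <- ph$t1c
  seg2 <- tumor_segmentation(core = binary_mask(shift_arr(ph$seg$core$data), grid),
                             necrosis = binary_mask(shift_arr(ph$seg$necrosis$data), grid),
                             whole = binary_mask(shift_arr(ph$seg$whole$data), grid))
  set.seed(19)
  for (i in 1:10) {
    ctr <- round(stats::runif(3, 16, 30)) + 0.5
    ang <- stats::runif(3, 0, 90)
    a <- score_placement(cube_placement(ctr, ang), ph$seg)
    b <- score_placement(cube_placement(ctr + shift, ang), seg2)
    expect_identical(c(a$core_mm3, a$necrosis_mm3, a$whole_mm3),
                     c(b$core_mm3, b$necrosis_mm3, b$whole_mm3))
  }
})
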