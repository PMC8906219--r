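test_that("type constructors enforce their invariants", {
  expect_error(image3d(array(1, c(2, 2)), c(1, 1, 1)), "3D")
  expect_error(image3d(array(1, c(2, 2, 2)), c(1, -1, 1)), "spacing")
  expect_error(binary_mask(array(2L, c(2, 2, 2))), "0 or 1")
  expect_error(displacement_field(array(NA_real_, c(2, 2, 2, 3))), "finite")
  expect_error(displacement_field(array(0, c(2, 2, 2, 2))), "nx, ny, nz, 3")
  expect_error(landmark_set(c("a", "a"), 1:2, 1:2, 1:2), "unique")
})

test_that("apply_warp: identity, ramp shift, and nearest mode", {
  img <- ramp_image(c(9, 7, 5), axis = 1, a = 2, b = 3)
  # zero field is the identity (bit-exact on linear too: integer positions)
  expect_identical(apply_warp(img, zero_field(img))$voxels, img$voxels)
  expect_identical(apply_warp(img, zero_field(img), "nearest")$voxels,
                   img$voxels)

  # constant displacement -s * spacing along x samples the ramp exactly:
  # linear interpolation is exact on linear functions
  s <- 1.5
  f <- constant_field(img, c(s * img$spacing[1], 0, 0))
  w <- apply_warp(img, f, "linear", background = NA_real_)
  interior <- 1:(9 - 2)  # sampled positions stay inside
  expect_equal(w$voxels[interior, , ], img$voxels[interior, , ] + 3 * s,
               tolerance = 1e-12)
  # out-of-extent samples take the background
  expect_true(all(is.na(w$voxels[9, , ])))

  # warping across grids: moving on a different (offset) grid
  img2 <- image3d(img$voxels, img$spacing, origin = c(1, 0, 0))
  w2 <- apply_warp(img2, zero_field(img), background = NA_real_)
  expect_equal(w2$voxels[2:9, , ], img$voxels[1:8, , ], tolerance = 1e-12)
})

test_that("warp_mask preserves binarity and voxel counts under translation", {
  mk <- cube_mask(c(12, 12, 12), c(4, 4, 4), c(7, 7, 7))
  expect_identical(warp_mask(mk, zero_field(mk))$voxels, mk$voxels)
  # one-voxel translation: volume preserved (interior), position shifted
  f <- constant_field(mk, c(-1, 0, 0))  # content moves +1 voxel in x
  w <- warp_mask(mk, f)
  expect_equal(sum(w$voxels), sum(mk$voxels))
  expect_identical(w$voxels[5:8, 4:7, 4:7],
                   array(1L, c(4, 4, 4)))
  # empty mask stays empty under any field
  empty <- binary_mask(array(0L, c(12, 12, 12)))
  expect_equal(sum(warp_mask(empty, f)$voxels), 0)
  # linear+threshold variant also returns {0,1}
  wl <- warp_mask(mk, constant_field(mk, c(-0.5, 0, 0)), "linear_threshold")
  expect_true(all(wl$voxels %in% c(0L, 1L)))
})

test_that("resample_to_grid handles identity, constants and ramps", {
  img <- ramp_image(c(9, 9, 9), axis = 2, b = 2)
  expect_equal(resample_to_grid(img, img)$voxels, img$voxels, tolerance = 1e-12)
  cst <- image3d(array(7, c(8, 8, 8)), c(2, 2, 2))
  coarse <- image3d(array(0, c(4, 4, 4)), c(4, 4, 4))
  expect_true(all(resample_to_grid(cst, coarse)$voxels == 7))
  # 2x upsampling of a ramp halves the per-voxel increment
  fine <- image3d(array(0, c(17, 9, 9)), c(0.5, 1, 1))
  up <- resample_to_grid(ramp_image(c(9, 9, 9)), fine)
  expect_equal(diff(up$voxels[, 1, 1]), rep(0.5, 16), tolerance = 1e-12)
})

test_that("jacobian determinant: zero, translation, and linear fields", {
  img <- image3d(array(0, c(8, 8, 8)), c(2, 2, 2))
  expect_equal(jacobian_determinant(zero_field(img))$voxels,
               array(1, c(8, 8, 8)))
  expect_equal(jacobian_determinant(constant_field(img, c(3, -2, 5)))$voxels,
               array(1, c(8, 8, 8)))
  # u_x = 0.1 * x  ->  det = 1.1 everywhere (exact for a linear field)
  f <- zero_field(img)
  f$vectors[, , , 1] <- 0.1 * (0:7) * 2
  expect_equal(jacobian_determinant(f)$voxels, array(1.1, c(8, 8, 8)),
               tolerance = 1e-12)
})

test_that("compose_fields reproduces sequential warping", {
  ph <- small_phantom()
  img <- ph$image
  uA <- make_ground_truth_warp(img, 32, 4, seed = 21)
  uB <- make_ground_truth_warp(img, 32, 3, seed = 22)
  w_seq <- apply_warp(apply_warp(img, uA), uB)
  w_comp <- apply_warp(img, compose_fields(uA, uB))
  # equal up to one linear-interpolation error of the double resampling
  err <- abs(w_seq$voxels - w_comp$voxels)
  expect_lt(median(err), 1e-6 + 0.02 * diff(range(img$voxels)))
})

test_that("grid mismatches are rejected with both shapes in the message", {
  a <- image3d(array(0, c(6, 6, 6)))
  b <- image3d(array(0, c(5, 6, 6)))
  expect_error(ncc(a, b), "6x6x6.*5x6x6")
  expect_error(joint_histogram(a, b, 16), "6x6x6.*5x6x6")
})
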