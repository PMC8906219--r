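test_that("dsc: identity, disjoint, half-overlap, symmetry, monotonicity", {
  a <- cube_mask(c(14, 10, 10), c(3, 4, 4), c(4, 5, 5))   # 2x2x2 = 8 voxels
  expect_equal(dsc(a, a), 1)
  b <- cube_mask(c(14, 10, 10), c(9, 4, 4), c(10, 5, 5))
  expect_equal(dsc(a, b), 0)
  # |A| = |B| = 8 cubes overlapping in 4 voxels -> 0.5
  c_ <- cube_mask(c(14, 10, 10), c(3, 4, 5), c(4, 5, 6))
  expect_equal(sum(a$voxels & c_$voxels), 4)
  expect_equal(dsc(a, c_), 0.5)
  expect_identical(dsc(a, c_), dsc(c_, a))
  expect_error(dsc(cube_mask(c(4, 4, 4), c(1, 1, 1), c(1, 1, 1)),
                   binary_mask(array(0L, c(4, 4, 4)))), NA)
  empty <- binary_mask(array(0L, c(14, 10, 10)))
  expect_error(dsc(empty, empty), "empty")
  # translating a cube strictly decreases DSC until disjoint
  base <- cube_mask(c(20, 10, 10), c(3, 3, 3), c(6, 6, 6))
  d_prev <- 1
  for (s in 1:4) {
    m <- cube_mask(c(20, 10, 10), c(3 + s, 3, 3), c(6 + s, 6, 6))
    d_cur <- dsc(base, m)
    expect_lt(d_cur, d_prev)
    d_prev <- d_cur
  }
})

test_that("hausdorff: exact cases and brute-force oracle equivalence", {
  a <- cube_mask(c(12, 12, 12), c(5, 5, 5), c(5, 5, 5))
  expect_equal(hausdorff_directed(a, a), 0)
  expect_equal(hausdorff(a, a), 0)
  # single voxels offset by (3, 4, 0) at 1 mm -> 5 mm
  b <- cube_mask(c(12, 12, 12), c(8, 9, 5), c(8, 9, 5))
  expect_equal(hausdorff_directed(a, b), 5)
  expect_equal(hausdorff_directed(b, a), 5)
  # anisotropic spacing enters in mm
  a2 <- cube_mask(c(12, 12, 12), c(5, 5, 5), c(5, 5, 5), spacing = c(2, 1, 3))
  b2 <- cube_mask(c(12, 12, 12), c(8, 9, 5), c(8, 9, 5), spacing = c(2, 1, 3))
  expect_equal(hausdorff_directed(a2, b2), sqrt(36 + 16))

  # surface convention: A strictly inside B with a 2-voxel margin gives a
  # positive directed HD(A, B); over full point sets it would be 0
  inner <- cube_mask(c(16, 16, 16), c(7, 7, 7), c(9, 9, 9))
  outer <- cube_mask(c(16, 16, 16), c(4, 4, 4), c(12, 12, 12))
  expect_gt(hausdorff_directed(inner, outer), 0)
  expect_equal(hausdorff_directed(inner, outer),
               oracle_hausdorff_directed(inner, outer), tolerance = 1e-12)

  # random masks <= 10^3 voxels: production == exhaustive oracle
  set.seed(17)
  for (rep in 1:4) {
    v1 <- array(as.integer(runif(1000) < 0.2), c(10, 10, 10))
    v2 <- array(as.integer(runif(1000) < 0.2), c(10, 10, 10))
    m1 <- binary_mask(v1, spacing = c(1.5, 1, 2))
    m2 <- binary_mask(v2, spacing = c(1.5, 1, 2))
    expect_equal(hausdorff_directed(m1, m2),
                 oracle_hausdorff_directed(m1, m2), tolerance = 1e-12)
    expect_gte(hausdorff(m1, m2),
               max(hausdorff_directed(m1, m2), hausdorff_directed(m2, m1)) - 1e-12)
  }
  expect_error(hausdorff_directed(a, binary_mask(array(0L, c(12, 12, 12)))),
               "empty")
})

test_that("marker centroid: single voxel, symmetric disc, two-point mean", {
  m <- binary_mask(array(0L, c(8, 8, 8)))
  m$voxels[3, 4, 5] <- 1L
  expect_equal(marker_centroid(m), c(2, 3, 4))
  # 3x3x1 disc centred at (4,4,2) (0-based), anisotropic spacing
  d <- binary_mask(array(0L, c(9, 9, 4)), spacing = c(2, 2, 3))
  d$voxels[4:6, 4:6, 3] <- 1L
  expect_equal(marker_centroid(d), c(8, 8, 6))
  two <- binary_mask(array(0L, c(8, 4, 4)))
  two$voxels[1, 1, 1] <- 1L
  two$voxels[4, 1, 1] <- 1L
  expect_equal(marker_centroid(two)[1], 1.5)
  expect_error(marker_centroid(binary_mask(array(0L, c(4, 4, 4)))), "empty")
})

test_that("tre: zero field, known offset, and exact-translation recovery", {
  mk <- cube_mask(c(16, 16, 16), c(7, 7, 4), c(9, 9, 4))
  expect_equal(tre(mk, mk, zero_field(mk)), 0)
  off <- cube_mask(c(16, 16, 16), c(7, 7, 7), c(9, 9, 7))
  expect_equal(tre(mk, off, zero_field(mk)), 3)  # (0,0,3) voxels at 1 mm
  # field equal to the exact translation: TRE 0 within half a voxel
  # (backward field: sampling position of the moving `off` marker, which
  # sits 3 voxels deeper, is x + 3)
  f <- constant_field(mk, c(0, 0, 3))
  expect_lt(tre(off, mk, f), 0.5)
})

test_that("paired t-test matches stats::t.test and the closed form", {
  x <- c(5, 7, 6, 9); y <- x - c(1, 2, 3, 4)
  got <- paired_t_test(x, y)
  # closed form: mean 2.5, sd ~1.2910, t = 2.5/(sd/2) ~ 3.873, df 3
  expect_equal(got$t, 2.5 / (sd(c(1, 2, 3, 4)) / 2), tolerance = 1e-12)
  expect_equal(got$t, 3.872983, tolerance = 1e-6)
  expect_equal(got$df, 3)
  # oracle: base R's t.test (independent implementation of statistic and p)
  or <- stats::t.test(x, y, paired = TRUE)
  expect_equal(got$t, unname(or$statistic), tolerance = 1e-12)
  expect_equal(got$p, or$p.value, tolerance = 1e-12)
  # antisymmetry
  swap <- paired_t_test(y, x)
  expect_equal(swap$t, -got$t, tolerance = 1e-12)
  expect_equal(swap$p, got$p, tolerance = 1e-12)
  # randomized oracle sweep
  set.seed(23)
  for (rep in 1:5) {
    a <- rnorm(6 + rep); b <- rnorm(6 + rep)
    g <- paired_t_test(a, b)
    o <- stats::t.test(a, b, paired = TRUE)
    expect_equal(g$t, unname(o$statistic), tolerance = 1e-10)
    expect_equal(g$p, o$p.value, tolerance = 1e-10)
  }
  expect_error(paired_t_test(x, x), "variance")
  expect_error(paired_t_test(1, 2), "n >= 2")
  expect_error(paired_t_test(1:3, 1:4), "lengths")
})

test_that("evaluate_case assembles metrics consistently and flags gaps", {
  cs <- small_case_clean()
  field <- cs$gt_field
  warped <- apply_warp(cs$moving, field)
  pairs <- lapply(c("larynx", "mandible"), function(nm)
    list(fixed = cs$masks_fixed[[nm]], moving = cs$masks_moving[[nm]]))
  names(pairs) <- c("larynx", "mandible")
  pairs$ghost <- list(fixed = NULL, moving = cs$masks_moving$parotid)
  markers <- lapply(paste0("P", 1:2), function(p)
    list(fixed = cs$masks_fixed[[p]], moving = cs$masks_moving[[p]]))
  names(markers) <- paste0("P", 1:2)
  rep <- evaluate_case(cs$fixed, warped, pairs, markers, field)
  # report matches individually computed metrics bit-for-bit
  expect_identical(rep$metrics$ncc, ncc(cs$fixed, warped))
  wl <- warp_mask(cs$masks_moving$larynx, field)
  expect_identical(rep$structures$dsc[1], dsc(cs$masks_fixed$larynx, wl))
  expect_identical(rep$structures$hd[1],
                   hausdorff(cs$masks_fixed$larynx, wl))
  expect_identical(rep$markers$tre_post_mm[1],
                   tre(cs$masks_moving$P1, cs$masks_fixed$P1, field))
  # missing structure flagged, others computed
  expect_equal(rep$structures$status, c("ok", "ok", "missing"))
  expect_true(all(is.na(rep$structures$dsc[3])))
  expect_true(all(rep$structures$dsc[1:2] > 0.9))  # gt field propagates well
  # identity case: perfect scores
  rep0 <- evaluate_case(cs$moving, cs$moving,
                        list(l = list(fixed = cs$masks_moving$larynx,
                                      moving = cs$masks_moving$larynx)),
                        list(P1 = list(fixed = cs$masks_moving$P1,
                                       moving = cs$masks_moving$P1)),
                        zero_field(cs$moving))
  expect_equal(rep0$structures$dsc, 1)
  expect_equal(rep0$structures$hd, 0)
  expect_equal(rep0$markers$tre_post_mm, 0)
})

test_that("endpoint_error measures mean vector distance over a mask", {
  img <- image3d(array(0, c(6, 6, 6)), c(2, 2, 2))
  a <- constant_field(img, c(3, 0, 4))
  expect_equal(endpoint_error(a, zero_field(img)), 5)
  mk <- cube_mask(c(6, 6, 6), c(1, 1, 1), c(2, 2, 2), spacing = c(2, 2, 2))
  expect_equal(endpoint_error(a, zero_field(img), mk), 5)
})
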