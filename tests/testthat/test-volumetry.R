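# LD, ellipsoidal TV, ETV, FTV (single pair and grid), relative changes,
# and histogram-threshold mask refinement.

test_that("ellipsoidal TV matches closed forms and is symmetric", {
  expect_equal(ellipsoid_tv(c(2, 2, 2)), 4 / 3 * pi)       # unit-radius sphere
  expect_equal(ellipsoid_tv(c(1, 2, 3)), pi)
  expect_equal(ellipsoid_tv(c(0, 5, 5)), 0)
  d <- c(1.3, 2.9, 0.7)
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1)))
    expect_equal(ellipsoid_tv(d[perm]), ellipsoid_tv(d))
  expect_error(diameter_triplet(-1, 2, 3), ">= 0")
})

test_that("longest dimension is the max diameter", {
  expect_equal(longest_dimension(diameter_triplet(2.8, 1.2, 2.0)), 2.8)
  expect_equal(longest_dimension(c(1, 1, 1)), 1)
  expect_equal(longest_dimension(c(0, 0, 0)), 0)
})

test_that("ETV is voxel volume times mask count", {
  m <- array(FALSE, dim = c(10, 10, 10))
  m[1:10, 1:10, 1:10] <- TRUE
  expect_equal(etv(tumor_mask(m), c(2, 2, 2)), 8)           # 1000 x 8 mm3
  expect_equal(etv(tumor_mask(array(FALSE, dim = c(4, 4, 4))), c(1, 1, 1)), 0)
  set.seed(21)
  mr <- array(stats::runif(6 * 5 * 4) < 0.4, dim = c(6, 5, 4))
  n <- 0L
  for (i in 1:6) for (j in 1:5) for (k in 1:4) n <- n + mr[i, j, k]
  expect_equal(etv(tumor_mask(mr), c(1.5, 1.5, 2)), n * 1.5 * 1.5 * 2 / 1000)
})

test_that("FTV equals the per-voxel brute-force count", {
  set.seed(31)
  s <- random_study(shape = c(8, 8, 4))
  maps <- enhancement_maps(s)
  mask <- tumor_mask(array(stats::runif(prod(dim(maps$pe))) < 0.6,
                           dim = dim(maps$pe)))
  sp <- c(1.5, 1.5, 2)
  for (thr in list(c(30, 0.40), c(0, 0), c(220, 2))) {
    expect_equal(ftv(mask, maps, thr[1], thr[2], sp),
                 oracle_ftv_count(mask$mask, maps, thr[1], thr[2]) *
                   voxel_volume_cm3(sp))
  }
  # thresholds above every voxel value
  expect_equal(ftv(mask, maps, 1e6, 1e6, sp), 0)
  bad_mask <- tumor_mask(array(TRUE, dim = c(2, 2, 2)))
  expect_error(ftv(bad_mask, maps, 0, 0, sp), "grids do not match")
})

test_that("ftv_grid equals looping ftv over all 1845 pairs", {
  set.seed(32)
  s <- random_study(shape = c(12, 12, 3), s0 = 100, noise = 60)
  maps <- enhancement_maps(s)
  mask <- tumor_mask(array(stats::runif(12 * 12 * 3) < 0.7, dim = c(12, 12, 3)))
  grid <- build_grid()
  sp <- c(1, 1, 1.5)
  g <- ftv_grid(mask, maps, grid, sp)
  expect_identical(dim(g), c(45L, 41L))
  pairwise <- matrix(0, 45, 41)
  for (i in seq_along(grid$pe)) for (j in seq_along(grid$ser))
    pairwise[i, j] <- ftv(mask, maps, grid$pe[i], grid$ser[j], sp)
  expect_equal(unname(g), pairwise)
})

test_that("ftv_grid respects strict inequality on single voxels and empty masks", {
  d <- c(3, 3, 1)
  maps <- structure(list(
    pe = array(NA_real_, dim = d), ser = array(NA_real_, dim = d),
    valid = array(FALSE, dim = d), early_phase_label = 1),
    class = "enhancement_maps")
  maps$pe[2, 2, 1] <- 50
  maps$ser[2, 2, 1] <- 1.0
  maps$valid[2, 2, 1] <- TRUE
  mask <- tumor_mask(array(TRUE, dim = d))
  g <- ftv_grid(mask, maps, build_grid(), c(10, 10, 10))
  grid <- build_grid()
  nonzero <- outer(grid$pe < 50, grid$ser < 1.0, "&")
  expect_equal(unname(g) > 0, nonzero)

  empty <- tumor_mask(array(FALSE, dim = d))
  expect_true(all(ftv_grid(empty, maps, build_grid(), c(10, 10, 10)) == 0))
})

test_that("FTV is monotone in both thresholds and bounded by ETV", {
  set.seed(33)
  for (rep in 1:3) {
    s <- random_study(shape = c(10, 10, 4), noise = 50)
    maps <- enhancement_maps(s)
    mask <- tumor_mask(array(stats::runif(10 * 10 * 4) < 0.5,
                             dim = c(10, 10, 4)))
    sp <- c(1, 1, 1)
    g <- ftv_grid(mask, maps, build_grid(), sp)
    expect_true(all(diff(g) <= 0))           # non-increasing in PE
    expect_true(all(t(diff(t(g))) <= 0))     # non-increasing in SER
    expect_true(all(g <= etv(mask, sp)))
  }
})

test_that("relative change matches its definition and missing rule", {
  expect_equal(relative_change(10, 5), -50)
  expect_equal(relative_change(10, 0), -100)
  expect_equal(relative_change(10, 10), 0)
  expect_true(is.na(relative_change(0, 5)))
  x <- c(2.5, 7, 0.4)
  expect_equal(relative_change(x, x), c(0, 0, 0))
})

test_that("histogram refinement keeps the enhancing mode and is idempotent", {
  d <- c(20, 10, 1)
  mask <- tumor_mask(array(TRUE, dim = d))
  img <- array(c(rep(5, 100), rep(200, 100)), dim = d)
  ref <- refine_mask_histogram(mask, img)
  expect_identical(ref$source, "refined")
  expect_equal(sum(ref$mask), 100)
  expect_true(all(img[ref$mask] == 200))
  # subset of input, idempotent on its own output
  expect_true(all(ref$mask <= mask$mask))
  ref2 <- refine_mask_histogram(ref, img)
  expect_equal(ref2$mask, ref$mask)

  # constant intensities: unchanged
  flat <- array(7, dim = d)
  expect_equal(refine_mask_histogram(mask, flat)$mask, mask$mask)
})

test_that("refinement threshold equals the brute-force Otsu maximum", {
  set.seed(41)
  for (rep in 1:4) {
    d <- c(12, 12, 2)
    mask <- tumor_mask(array(stats::runif(prod(d)) < 0.8, dim = d))
    img <- array(0, dim = d)
    n <- sum(mask$mask)
    img[mask$mask] <- c(stats::rnorm(ceiling(n / 2), 20, 8),
                        stats::rnorm(floor(n / 2), 150, 25))
    ref <- refine_mask_histogram(mask, img)
    thr <- oracle_otsu(img[mask$mask])
    expect_equal(ref$mask, mask$mask & img > thr)
  }
})

test_that("mask bounding-box diameters recover synthetic ellipsoid axes", {
  cfg <- tiny_config(n = 4, seed = 5, noise = 0)
  set.seed(cfg$seed)
  p <- generate_patient(cfg, "non_pCR", "P1")
  d_est <- mask_to_diameters(p$masks$BL, cfg$spacing_mm)
  d_true <- p$truth$BL$diameters_cm
  # bounding box of a voxelized ellipsoid matches truth to within one voxel
  expect_true(all(abs(unname(d_est$diameters) - d_true) <=
                    cfg$spacing_mm / 10 + 1e-9))
  expect_equal(unname(mask_to_diameters(
    tumor_mask(array(FALSE, dim = c(3, 3, 3))), c(1, 1, 1))$diameters),
    c(0, 0, 0))
})
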