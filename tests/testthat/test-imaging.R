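test_that("PET standardization follows the dose/decay/weight relation", {
  v <- vol3(1.0, c(1, 1, 1))
  # t = t_i: exponent vanishes, v -> v*d/w
  out <- standardize_pet(v, std_acq(dose = 300, weight = 75, dt = 0))
  expect_equal(out$data[1, 1, 1], 300 / 75)
  # one half-life elapsed, plain convention: 300/75 * e^-1
  out <- standardize_pet(v, std_acq(dt = 6586.2, tau = 6586.2))
  expect_equal(out$data[1, 1, 1], 4 * exp(-1), tolerance = 1e-12)
  expect_equal(out$data[1, 1, 1], 1.47152, tolerance = 1e-5)
  # ln2 convention: true physical half-life, activity halves
  out2 <- standardize_pet(v, std_acq(dt = 6586.2, tau = 6586.2), "ln2")
  expect_equal(out2$data[1, 1, 1], 4 * 0.5, tolerance = 1e-12)
  # all-zero volume stays zero; geometry untouched
  z <- vol3(0, c(2, 3, 4), spacing = c(1, 2, 3))
  outz <- standardize_pet(z, std_acq(dt = 123))
  expect_true(all(outz$data == 0))
  expect_identical(outz$spacing, z$spacing)
})

test_that("standardization is linear in voxel value and dose, inverse in weight", {
  set.seed(1)
  v <- vol3(runif(24), c(2, 3, 4))
  a <- standardize_pet(v, std_acq(dose = 100, weight = 80, dt = 500))
  v2 <- v; v2$data <- v$data * 3
  expect_equal(standardize_pet(v2, std_acq(100, 80, 500))$data, 3 * a$data)
  expect_equal(standardize_pet(v, std_acq(dose = 200, weight = 80, dt = 500))$data,
               2 * a$data)
  expect_equal(standardize_pet(v, std_acq(dose = 100, weight = 40, dt = 500))$data,
               2 * a$data)
})

test_that("invalid acquisition parameters are rejected", {
  expect_error(acquisition_info(-1, 75, 0, 0), "dose")
  expect_error(acquisition_info(300, 0, 0, 0), "weight")
  expect_error(acquisition_info(300, 75, 0, 0, half_life_s = 0), "half_life")
  expect_error(acquisition_info(300, 75, 100, 50), "acquisition_time")
})

test_that("mask transfer: identity, refinement and empty masks", {
  m <- mask3(c(rep(0L, 10), 1L, 1L, rep(0L, 15)), c(3, 3, 3))
  # identical target geometry: identical mask
  same <- resample_mask_to_grid(m, m)
  expect_identical(same$data, m$data)
  # 1mm -> 0.5mm grid over the same extent: each voxel covers 8 targets.
  # Oracle: brute-force nearest-neighbour lookup over all target voxels.
  tgt <- list(dim = c(6, 6, 6), spacing = c(0.5, 0.5, 0.5),
              origin = c(-0.25, -0.25, -0.25))
  fine <- resample_mask_to_grid(m, tgt)
  expect_equal(sum(fine$data), 8 * sum(m$data))
  brute <- array(0L, c(6, 6, 6))
  for (i in 0:5) for (j in 0:5) for (k in 0:5) {
    w <- c(-0.25, -0.25, -0.25) + 0.5 * c(i, j, k)
    src <- round(w)  # source index = world coord on the 1mm grid
    if (all(src >= 0) && all(src <= 2))
      brute[i + 1, j + 1, k + 1] <- m$data[src[1] + 1, src[2] + 1, src[3] + 1]
  }
  expect_identical(fine$data, brute)
  # empty mask stays empty on the target grid
  e <- resample_mask_to_grid(mask3(0L, c(3, 3, 3)), tgt)
  expect_equal(sum(e$data), 0)
  expect_equal(dim(e$data), c(6L, 6L, 6L))
})

test_that("mask transfer preserves binarity and is idempotent on a fixed grid", {
  for (s in 1:5) {
    set.seed(s)
    m <- mask3(rbinom(27, 1, 0.5), c(3, 3, 3), spacing = c(1, 1.5, 2))
    tgt <- list(dim = c(5, 4, 3), spacing = c(0.7, 1.1, 2.3),
                origin = c(-0.2, 0.1, 0))
    r <- resample_mask_to_grid(m, tgt)
    expect_true(all(r$data %in% c(0L, 1L)))
    expect_identical(resample_mask_to_grid(r, r)$data, r$data)
  }
})

test_that("discretization yields consecutive levels from 1", {
  m <- full_mask(c(2, 2, 1))
  v <- vol3(c(0, 1, 2, 3), c(2, 2, 1))
  lev <- discretize_intensities(v, m, discretization("fixed-bin-count", 2))
  expect_equal(as.vector(lev), c(1L, 1L, 2L, 2L))
  # constant region: single level regardless of bin count
  lc <- discretize_intensities(vol3(7, c(2, 2, 1)), m,
                               discretization("fixed-bin-count", 64))
  expect_true(all(lc[!is.na(lc)] == 1L))
  # bin count 1: everything level 1
  l1 <- discretize_intensities(v, m, discretization("fixed-bin-count", 1))
  expect_true(all(l1[!is.na(l1)] == 1L))
  # fixed width 1 on 0..3: four levels
  lw <- discretize_intensities(v, m, discretization("fixed-bin-width", 1))
  expect_equal(sort(unique(as.vector(lw[!is.na(lw)]))), 1:4)
  expect_error(discretize_intensities(v, mask3(0L, c(2, 2, 1)),
                                      discretization()), "empty")
})

test_that("reference texture features match hand-derived tiny cases", {
  m <- full_mask(c(3, 1, 1))
  v <- vol3(c(0, 0, 10), c(3, 1, 1))
  d2 <- discretization("fixed-bin-count", 2)
  # histogram {2/3, 1/3}
  expect_equal(reference_texture_feature("first_order_entropy", v, m, d2),
               -(2 / 3) * log2(2 / 3) - (1 / 3) * log2(1 / 3))
  # dependencies {2,2,1} -> mean of squares 3
  expect_equal(
    reference_texture_feature("gldm_large_dependence_emphasis", v, m, d2), 3)
  # 38 runs over 13 directions, one of length 2 -> 1406/54872
  expect_equal(reference_texture_feature("glrlm_run_variance", v, m, d2),
               0.0256232686980609, tolerance = 1e-12)
  # s = (0.5, 1), p = (2/3, 1/3) -> strength 2/1.5
  expect_equal(reference_texture_feature("ngtdm_strength", v, m, d2), 4 / 3)
  # constant region: zero entropy, one bit for a half/half split
  expect_equal(reference_texture_feature("first_order_entropy",
                                         vol3(5, c(2, 2, 2)),
                                         full_mask(c(2, 2, 2)),
                                         discretization()), 0)
  expect_equal(reference_texture_feature("first_order_entropy",
                                         vol3(c(0, 0, 9, 9), c(4, 1, 1)),
                                         full_mask(c(4, 1, 1)), d2), 1)
  expect_error(reference_texture_feature("bogus", v, m, d2))
})

test_that("first-order entropy is invariant to voxel permutation within the mask", {
  for (s in 1:10) {
    v <- random_phantom_4(s)
    m <- full_mask(c(4, 4, 4))
    e1 <- reference_texture_feature("first_order_entropy", v, m)
    set.seed(s + 1000)
    vp <- vol3(sample(as.vector(v$data)), c(4, 4, 4))
    expect_equal(reference_texture_feature("first_order_entropy", vp, m), e1)
    # texture-matrix features generally are not permutation invariant: the
    # dependence structure changes even though the histogram does not
  }
})

test_that("reference shape features match brute-force voxel conventions", {
  single <- mask3(c(1L, rep(0L, 7)), c(2, 2, 2), spacing = c(2, 3, 4))
  expect_equal(reference_shape_feature("max_3d_diameter", single), 0)
  one_mm <- mask3(1L, c(1, 1, 1))
  expect_equal(reference_shape_feature("surface_volume_ratio", one_mm), 6)
  cube <- full_mask(c(2, 2, 2))
  expect_equal(reference_shape_feature("surface_volume_ratio", cube), 3)
  expect_equal(reference_shape_feature("max_3d_diameter", cube), sqrt(3))
  expect_error(reference_shape_feature("max_3d_diameter",
                                       mask3(0L, c(2, 2, 2))), "empty")
})
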