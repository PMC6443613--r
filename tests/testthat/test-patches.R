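test_that("patch_spec validates edge and scales", {
  expect_error(patch_spec(10), "odd")
  expect_error(patch_spec(11, c(1, 1)), "differ")
  expect_error(patch_spec(11, c(2)), "two positive")
})

test_that("constant volumes give constant patches on every plane and scale", {
  vol <- ct_volume(array(100, c(20, 20, 20)))
  ps <- extract_triplanar_patches(vol, c(3, 10, 18), patch_spec(11, c(1, 3)))
  expect_length(ps, 6)
  for (p in ps) expect_true(all(p == 100))
})

test_that("the centre pixel of every fine-scale patch is the target voxel", {
  set.seed(1)
  vol <- array(rnorm(24^3, 100, 40), c(24, 24, 24))
  for (vox in list(c(1, 1, 1), c(12, 7, 20), c(24, 24, 24))) {
    ps <- extract_triplanar_patches(vol, vox, patch_spec(11, c(1, 3)))
    ctr <- (11 + 1) / 2
    expect_equal(ps$axial_fine[ctr, ctr], vol[vox[1], vox[2], vox[3]])
    expect_equal(ps$coronal_fine[ctr, ctr], vol[vox[1], vox[2], vox[3]])
    expect_equal(ps$sagittal_fine[ctr, ctr], vol[vox[1], vox[2], vox[3]])
  }
})

test_that("voxels outside the grid are rejected", {
  vol <- array(0, c(8, 8, 8))
  expect_error(extract_triplanar_patches(vol, c(0, 4, 4), patch_spec(5)),
               "outside")
  expect_error(extract_triplanar_patches(vol, c(4, 4, 9), patch_spec(5)),
               "outside")
})

test_that("vectorized extraction equals the brute-force slicing oracle", {
  set.seed(7)
  vol <- array(rnorm(32^3, 100, 50), c(32, 32, 32))
  voxels <- cbind(sample(32, 50, TRUE), sample(32, 50, TRUE),
                  sample(32, 50, TRUE))
  spec <- patch_spec(11, c(1, 3))
  for (i in seq_len(nrow(voxels))) {
    vox <- voxels[i, ]
    got <- extract_triplanar_patches(vol, vox, spec)
    for (scale_name in c("fine", "coarse")) {
      scale <- if (scale_name == "fine") spec$scales[1] else spec$scales[2]
      want <- oracle_triplanar(vol, vox, spec$patch_edge, scale)
      expect_equal(got[[paste0("axial_", scale_name)]], want$axial)
      expect_equal(got[[paste0("coronal_", scale_name)]], want$coronal)
      expect_equal(got[[paste0("sagittal_", scale_name)]], want$sagittal)
    }
  }
})

test_that("non-integer scales interpolate linearly and match the oracle", {
  set.seed(9)
  vol <- array(rnorm(20^3, 0, 1), c(20, 20, 20))
  spec <- patch_spec(7, c(1, 2.5))
  for (i in 1:20) {
    vox <- c(sample(20, 1), sample(20, 1), sample(20, 1))
    got <- extract_triplanar_patches(vol, vox, spec)
    want <- oracle_triplanar(vol, vox, 7, 2.5)
    expect_equal(got$axial_coarse, want$axial, tolerance = 1e-12)
    expect_equal(got$coronal_coarse, want$coronal, tolerance = 1e-12)
    expect_equal(got$sagittal_coarse, want$sagittal, tolerance = 1e-12)
  }
})
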