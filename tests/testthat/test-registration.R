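test_that("resampling through the identity is exact", {
  ph <- small_phantom()
  tm <- make_template(ph)
  out <- resample(tm, NULL, target = tm)
  expect_equal(out$data, tm$data, tolerance = 1e-12)
  # constant volumes stay constant in the interior under any affine
  cv <- brain_volume(array(7, c(16, 16, 16)))
  tr <- affine_transform(translation = c(0.3, -0.4, 0.2),
                         rotation = c(5, 3, -8))
  rc <- resample(cv, tr, target = cv)
  expect_equal(rc$data[4:13, 4:13, 4:13],
               array(7, c(10, 10, 10)), tolerance = 1e-9)
  expect_error(resample(cv, list(matrix = matrix(0, 4, 4))), "singular")
})

test_that("integer voxel translations shift the array exactly", {
  set.seed(6)
  v <- brain_volume(array(rnorm(20^3), c(20, 20, 20)), spacing = rep(1, 3))
  tr <- affine_transform(translation = c(1, 0, 0))
  out <- resample(v, tr, target = v)
  # t moves source content +1 voxel: out[i] = v[i-1]
  expect_equal(out$data[2:20, , ], v$data[1:19, , ], tolerance = 1e-9)
})

test_that("round-trip resampling returns near the original", {
  ph <- small_phantom()
  tm <- make_template(ph)
  tr <- affine_transform(translation = c(0.4, -0.3, 0.2),
                         rotation = c(6, -4, 8),
                         center = skelex:::world_center(tm))
  back <- resample(resample(tm, tr), invert_transform(tr))
  core <- 6:27
  mae <- mean(abs(back$data[core, core, core] - tm$data[core, core, core]))
  expect_lt(mae, 0.05 * diff(range(tm$data)))
})

test_that("energy upsampling multiplies the grid and conserves mass", {
  ph <- small_phantom()
  panel <- expression_panel_spec(seed = 2)
  m <- make_energy_maps(ph, panel)[["Maz"]]
  up <- upsample_energy(m, factor = 8L)
  expect_equal(dim(up$data), dim(m$data) * 8L)
  expect_equal(up$spacing, m$spacing / 8)
  valid_lo <- m$data != -1
  valid_hi <- up$data != -1
  ratio <- sum(up$data[valid_hi]) / sum(m$data[valid_lo])
  expect_equal(ratio, 512, tolerance = 0.02 * 512)
  # sentinel is propagated, never blended: no value below the valid minimum
  expect_true(all(up$data[!valid_hi] == -1))
  expect_gt(min(up$data[valid_hi]), 0)
  # constant interior stays constant (away from the half-voxel border
  # where the fine grid extends beyond the coarse voxel centres)
  cm <- brain_volume(array(2, c(6, 6, 6)), spacing = rep(0.2, 3))
  cu <- upsample_energy(cm)
  expect_equal(unique(as.numeric(cu$data[5:44, 5:44, 5:44])), 2)
})

test_that("affine registration recovers identity and planted transforms", {
  ph <- phantom_spec(grid_shape = c(48, 48, 48), spacing = 0.25)
  tm <- make_template(ph)
  cfg <- fast_reg_cfg()
  # self-registration stays at the identity
  tr0 <- affine_register(tm, tm, cfg)
  expect_lt(sqrt(sum(tr0$params[1:3]^2)) / ph$spacing[1], 0.1)
  expect_lt(sqrt(sum(tr0$params[4:6]^2)), 0.5)
  # pure translation of (2, 3, -1) voxels
  sp <- ph$spacing[1]
  tt <- affine_transform(translation = c(2, 3, -1) * sp,
                         center = skelex:::world_center(tm))
  moving <- resample(tm, invert_transform(tt), target = tm)
  tr1 <- affine_register(moving, tm, cfg)
  expect_lt(sqrt(sum((tr1$params[1:3] - tt$params[1:3])^2)) / sp, 0.2)
  # rotation + isotropic scale
  tt2 <- affine_transform(rotation = c(0, 0, 10), scale = rep(1.1, 3),
                          center = skelex:::world_center(tm))
  moving2 <- resample(tm, invert_transform(tt2), target = tm)
  tr2 <- affine_register(moving2, tm, cfg)
  expect_lt(abs(tr2$params[6] - 10), 1)
  expect_lt(max(abs(tr2$params[7:9] - 1.1)), 0.02)
  expect_error(affine_register(brain_volume(array(1, c(8, 8, 8))), tm),
               "constant")
})

test_that("histogram QC scores transformations as expected", {
  ph <- small_phantom()
  panel <- expression_panel_spec(seed = 4)
  m <- make_energy_maps(ph, panel)[["Maz"]]
  expect_equal(histogram_qc(m, m)$score, 0)
  # voxel permutation leaves the histogram unchanged
  perm <- m
  valid <- perm$data != -1
  set.seed(8)
  perm$data[valid] <- sample(perm$data[valid])
  expect_equal(histogram_qc(m, perm)$score, 0)
  # global shift separates the distributions
  shifted <- m
  shifted$data[valid] <- shifted$data[valid] + 1
  qc <- histogram_qc(m, shifted)
  expect_gt(qc$score, 0)
  # rigid resampling of a smooth map barely moves the histogram
  sm_arr <- m$data
  fill <- sm_arr; fill[!valid] <- mean(sm_arr[valid])
  sm <- skelex:::gaussian_smooth(fill, 3)
  m_s <- m; m_s$data[valid] <- sm[valid]
  tr <- affine_transform(translation = c(0.2, -0.1, 0.15),
                         rotation = c(4, -3, 5),
                         center = skelex:::world_center(m_s))
  rs <- resample(m_s, tr, target = m_s)
  expect_lt(histogram_qc(m_s, rs)$score, 0.02)
  allmiss <- brain_volume(array(-1, c(4, 4, 4)), missing_value = -1)
  expect_error(histogram_qc(allmiss, allmiss), "missing")
})

test_that("the most typical volume wins the warp tournament", {
  ph <- phantom_spec(grid_shape = c(24, 24, 24), spacing = 0.5)
  tm <- make_template(ph)
  cfg <- fast_reg_cfg(pyramid = c(2, 1), maxit = c(200, 80))
  # identical volumes: zero warps, tie broken to index 1
  same <- list(tm, tm, tm)
  res0 <- select_most_typical(same, cfg)
  expect_equal(res0$index, 1L)
  expect_equal(dim(res0$warp_matrix), c(3L, 3L))
  expect_true(all(diag(res0$warp_matrix) == 0))
  expect_lt(max(res0$warp_matrix), 0.2)
  # one pristine volume among jittered copies is the typical one
  vols <- list(tm,
               make_misaligned_pair(tm, jitter = c(1.2, 8), seed = 21)$moving,
               make_misaligned_pair(tm, jitter = c(1.2, 8), seed = 22)$moving)
  res <- select_most_typical(vols, cfg)
  expect_equal(res$index, 1L)
})
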