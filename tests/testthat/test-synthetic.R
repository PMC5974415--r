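test_that("template generation is deterministic and brain-shaped", {
  ph <- small_phantom()
  t1 <- make_template(ph)
  t2 <- make_template(ph)
  expect_identical(t1$data, t2$data)
  frac <- mean(t1$data > 0)
  expect_gt(frac, 0.2)
  expect_lt(frac, 0.8)
  # background zero at the corners
  expect_equal(t1$data[1, 1, 1], 0)
})

test_that("brain world volume is resolution-consistent", {
  ph1 <- phantom_spec(grid_shape = c(48, 48, 48), spacing = 0.25)
  ph2 <- phantom_spec(grid_shape = c(24, 24, 24), spacing = 0.5)
  vol_of <- function(ph) {
    m <- structure_mask(ph, "brain")
    sum(m$data) * prod(m$spacing)
  }
  expect_equal(vol_of(ph1), vol_of(ph2), tolerance = 0.05)
})

test_that("default cohort matches the study design", {
  co <- cohort_spec()
  expect_equal(sum(co$n_per_group), 21)
  expect_equal(unname(co$n_per_group),
               c(6, 4, 6, 5))
  expect_error(cohort_spec(n_per_group = c(male_wt = 1, male_del = 4,
                                           female_wt = 6, female_del = 5)),
               "at least 2")
  expect_error(cohort_spec(noise_sd = -0.1), ">= 0")
})

test_that("noise-free cohort with no effects is a constant cohort", {
  ph <- small_phantom()
  co <- cohort_spec(n_per_group = c(male_wt = 2, male_del = 2,
                                    female_wt = 2, female_del = 2),
                    effects = list(), noise_sd = 0, misalignment_sd = 0)
  animals <- make_fa_cohort(ph, co)
  expect_length(animals, 8)
  for (a in animals[-1])
    expect_identical(a$volume$data, animals[[1]]$volume$data)
  expect_equal(animals[[1]]$true_transform$matrix, diag(4))
})

test_that("planted group effects land on the target structure", {
  ph <- small_phantom()
  co <- cohort_spec(n_per_group = c(male_wt = 3, male_del = 3,
                                    female_wt = 2, female_del = 2),
                    effects = list(tube = c(male_del = 0.15)),
                    noise_sd = 0.01, misalignment_sd = 0, seed = 3)
  animals <- make_fa_cohort(ph, co)
  tube <- structure_mask(ph, "tube")$data > 0
  grp <- vapply(animals, function(a) a$meta$group, "")
  mean_tube <- function(sel)
    mean(vapply(animals[sel], function(a) mean(a$volume$data[tube]),
                numeric(1)))
  diff_tube <- mean_tube(grp == "male_del") - mean_tube(grp == "male_wt")
  expect_equal(diff_tube, 0.15, tolerance = 0.02)

  # monotonicity: a larger offset never lowers the group mean
  co2 <- cohort_spec(n_per_group = co$n_per_group,
                     effects = list(tube = c(male_del = 0.25)),
                     noise_sd = 0.01, misalignment_sd = 0, seed = 3)
  animals2 <- make_fa_cohort(ph, co2)
  mean_tube2 <- mean(vapply(animals2[grp == "male_del"],
                            function(a) mean(a$volume$data[tube]),
                            numeric(1)))
  expect_gte(mean_tube2, mean_tube(grp == "male_del"))
})

test_that("energy maps have planted enrichment and a missing shell", {
  ph <- small_phantom()
  panel <- expression_panel_spec(seed = 9)
  maps <- make_energy_maps(ph, panel)
  expect_length(maps, 26)
  brain <- structure_mask(ph, "brain", "expression")$data > 0
  tube <- structure_mask(ph, "tube", "expression")$data > 0
  m <- maps[["Mvp"]]
  # outside the brain shell: sentinel everywhere
  expect_true(all(m$data[!brain] == -1))
  expect_true(all(m$data[brain] > 0))
  ratio <- median(m$data[tube]) / median(m$data[brain & !tube])
  expect_equal(ratio, 3, tolerance = 0.2 * 3)
  # non-enriched gene: no regional shift beyond noise
  u <- maps[["Maz"]]
  ratio0 <- median(u$data[tube]) / median(u$data[brain & !tube])
  expect_equal(ratio0, 1, tolerance = 0.2)
  # determinism
  maps2 <- make_energy_maps(ph, panel)
  expect_identical(maps2[["Mvp"]]$data, m$data)
  expect_error(
    expression_panel_spec(genes = c("Mvp"),
                          enriched_sets = list(tube = list(genes = "Nope",
                                                           factor = 3))),
    "not in panel")
})

test_that("misaligned pairs carry their true transform", {
  ph <- small_phantom()
  tm <- make_template(ph)
  # zero jitter: identity transform, volume unchanged
  p0 <- make_misaligned_pair(tm, jitter = c(0, 0), seed = 4)
  expect_equal(p0$true_transform$matrix, diag(4), tolerance = 1e-12)
  expect_equal(p0$moving$data, tm$data, tolerance = 1e-6)
  # same seed, same transform
  pa <- make_misaligned_pair(tm, jitter = c(1, 5), seed = 5)
  pb <- make_misaligned_pair(tm, jitter = c(1, 5), seed = 5)
  expect_identical(pa$true_transform$matrix, pb$true_transform$matrix)
  # pure integer translation shifts the array
  sp <- tm$spacing[1]
  tr <- affine_transform(translation = c(2 * sp, 0, 0),
                         center = skelex:::world_center(tm))
  moved <- resample(tm, invert_transform(tr), target = tm)
  core_i <- 5:28
  expect_equal(moved$data[core_i, , ], tm$data[core_i + 2, , ],
               tolerance = 1e-6)
})
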