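test_that("mean FA equals the arithmetic mean oracle", {
  set.seed(11)
  vols <- lapply(1:4, function(i)
    brain_volume(array(runif(10^3), c(10, 10, 10))))
  m <- build_mean_fa(vols)
  oracle <- (vols[[1]]$data + vols[[2]]$data + vols[[3]]$data +
               vols[[4]]$data) / 4
  expect_equal(m$data, oracle)
  expect_equal(build_mean_fa(vols[c(1, 1)])$data, vols[[1]]$data)
  expect_equal(build_mean_fa(list(
    brain_volume(array(0, c(4, 4, 4))),
    brain_volume(array(1, c(4, 4, 4)))))$data,
    array(0.5, c(4, 4, 4)))
  bad <- brain_volume(array(0, c(9, 10, 10)))
  expect_error(build_mean_fa(list(vols[[1]], bad)), "mismatch")
})

test_that("skeletonization finds tube centerlines and respects the threshold", {
  # straight tube along x with Gaussian cross-section, peak 0.6
  n <- 32
  fa <- array(0, c(n, n, n))
  for (j in 1:n) for (k in 1:n)
    fa[, j, k] <- 0.6 * exp(-((j - 16)^2 + (k - 16)^2) / (2 * 2^2))
  vol <- brain_volume(fa)
  sk <- skeletonize(vol, 0.2)
  expect_gt(length(sk$vox), 0)
  d <- dim(vol$data)
  ijk <- cbind(sk$vox %% d[1], (sk$vox %/% d[1]) %% d[2],
               sk$vox %/% (d[1] * d[2]))
  # away from the tube's open ends, skeleton voxels hug the centerline
  # (j = k = 15, 0-based) to within one voxel
  interior <- ijk[, 1] >= 3 & ijk[, 1] <= n - 4
  off <- sqrt((ijk[interior, 2] - 15)^2 + (ijk[interior, 3] - 15)^2)
  expect_lte(max(off), sqrt(2))
  # centerline coverage along the tube interior
  expect_gte(length(unique(ijk[interior, 1][off < 1])), n - 10)

  # sub-threshold maps give an empty skeleton
  expect_warning(sk0 <- skeletonize(brain_volume(array(0.1, c(8, 8, 8)))),
                 "empty")
  expect_length(sk0$vox, 0)
  # raising the threshold never adds skeleton voxels
  sk3 <- skeletonize(vol, 0.3)
  expect_true(all(sk3$vox %in% sk$vox))
})

test_that("skeleton projection picks up perpendicular maxima", {
  fix <- study_fa_skeleton()
  sk <- fix$skel
  # projecting the mean FA itself returns the skeleton values
  proj <- project_onto_skeleton(fix$fa, sk)
  expect_gte(min(proj - fix$fa$data[sk$vox + 1]), 0)
  # radius 0 is the voxel value itself
  proj0 <- project_onto_skeleton(fix$fa, sk, search_radius = 0)
  expect_equal(proj0, fix$fa$data[sk$vox + 1])
  # a 1-voxel perpendicular shift of a straight tube is absorbed by the
  # search: centerline values project back to the unshifted ones
  n <- 32
  fa <- array(0, c(n, n, n))
  for (j in 1:n) for (k in 1:n)
    fa[, j, k] <- 0.6 * exp(-((j - 16)^2 + (k - 16)^2) / (2 * 2^2))
  tube_vol <- brain_volume(fa)
  tsk <- skeletonize(tube_vol, 0.2)
  base <- project_onto_skeleton(tube_vol, tsk)
  shifted <- resample(tube_vol,
                      affine_transform(translation = c(0, 1, 0)),
                      target = tube_vol)
  projs <- project_onto_skeleton(shifted, tsk)
  keep <- tsk$vox %% n >= 3 & tsk$vox %% n <= n - 4
  expect_lt(mean(abs(projs - base)[keep]), 0.02)
  expect_error(project_onto_skeleton(
    brain_volume(array(0, c(4, 4, 4))), sk), "mismatch")
})

test_that("TFCE matches its closed forms and is monotone", {
  # all-zero map stays zero
  z <- tfce(brain_volume(array(0, c(6, 6, 6))))
  expect_true(all(z$data == 0))
  # isolated voxel, height h: integral -> h^(H+1)/(H+1)
  s <- array(0, c(7, 7, 7)); s[4, 4, 4] <- 2
  e <- tfce(brain_volume(s), E = 0.5, H = 2, dh = 2 / 1000)
  expect_equal(e$data[4, 4, 4], 8 / 3, tolerance = 0.005)
  # two connected voxels, E = 0.5: extent sqrt(2) throughout
  s2 <- s; s2[5, 4, 4] <- 2
  e2 <- tfce(brain_volume(s2), E = 0.5, H = 2, dh = 2 / 1000)
  expect_equal(e2$data[4, 4, 4], sqrt(2) * 8 / 3, tolerance = 0.01)
  expect_equal(e2$data[5, 4, 4], e2$data[4, 4, 4])
  # negative lobes are enhanced as their negation
  e3 <- tfce(brain_volume(-s2), E = 0.5, H = 2, dh = 2 / 1000)
  expect_equal(e3$data, -e2$data)
  # monotonicity: pointwise-larger stat maps enhance to pointwise >=
  set.seed(12)
  for (i in 1:5) {
    a <- array(pmax(0, rnorm(5^3, 0.3, 0.5)), c(5, 5, 5))
    b <- a + array(runif(5^3, 0, 0.3), c(5, 5, 5))
    ea <- tfce(brain_volume(a), E = 0.5, H = 2, dh = 0.01)
    eb <- tfce(brain_volume(b), E = 0.5, H = 2, dh = 0.01)
    expect_true(all(eb$data - ea$data >= -1e-9))
  }
})

test_that("permutation test is symmetric and matches exact enumeration", {
  fix <- study_fa_skeleton()
  sk <- fix$skel
  ph <- study_phantom()
  co <- cohort_spec(n_per_group = c(male_wt = 4, male_del = 4,
                                    female_wt = 2, female_del = 2),
                    effects = list(tube = c(male_del = 0.08)),
                    noise_sd = 0.03, misalignment_sd = 0, seed = 31)
  animals <- make_fa_cohort(ph, co)[1:8]
  vals <- do.call(rbind, lapply(animals, function(a)
    project_onto_skeleton(a$volume, sk)))
  geno <- factor(vapply(animals, function(a) a$meta$genotype, ""),
                 levels = c("wt", "del"))
  # C(8,4) = 70 <= n_perm: exact enumeration kicks in
  res <- permutation_group_test(vals, geno, sk, n_perm = 500, seed = 1)
  expect_true(res$a_gt_b$exact_enumeration)
  expect_equal(res$a_gt_b$n_permutations, 70)
  expect_true(all(res$a_gt_b$p_skel >= 1 / 70))
  # swapping the label roles swaps the two directions exactly
  geno2 <- factor(as.character(geno), levels = c("del", "wt"))
  res2 <- permutation_group_test(vals, geno2, sk, n_perm = 500, seed = 1)
  expect_equal(res2$a_gt_b$p_skel, res$b_gt_a$p_skel)
  expect_equal(res2$b_gt_a$tfce_skel, res$a_gt_b$tfce_skel)

  # independent exact-enumeration oracle on a tiny sub-skeleton
  keep <- which(sk$vox %in% sk$vox[1:40])
  subvals <- vals[, keep, drop = FALSE]
  subskel <- sk
  subskel$vox <- sk$vox[keep]
  subskel$dirs <- sk$dirs[keep, , drop = FALSE]
  adj <- skelex:::skeleton_adjacency(subskel)
  combos <- utils::combn(8, 4, simplify = FALSE)
  del_first <- levels(geno2)
  null_max <- vapply(combos, function(sel) {
    ina <- seq_len(8) %in% sel
    tt <- skelex:::t_stat_matrix(subvals, ina)
    max(c(0, tfce(pmax(tt, 0), E = 1, H = 2, skel = subskel)))
  }, numeric(1))
  obs <- tfce(pmax(skelex:::t_stat_matrix(
    subvals, geno2 == "del"), 0), E = 1, H = 2, skel = subskel)
  p_oracle <- vapply(obs, function(o) perm_count_guard(null_max, o),
                     numeric(1))
  res_sub <- permutation_group_test(subvals, geno2, subskel,
                                    n_perm = 500, seed = 1)
  expect_equal(res_sub$a_gt_b$p_skel, p_oracle, tolerance = 1e-12)

  expect_error(permutation_group_test(vals, factor(rep("a", 8)), sk),
               "two levels")
})

test_that("cluster extraction is deterministic and size-ordered", {
  fix <- study_fa_skeleton()
  sk <- fix$skel
  nv <- length(sk$vox)
  fake <- structure(list(
    label = "x", skel = sk, p_skel = rep(1, nv),
    tfce_skel = rep(0, nv), alpha = 0.05,
    tfce_map = brain_volume(array(0, dim(sk$mask)),
                            spacing = sk$mean_fa$spacing,
                            affine = sk$mean_fa$affine)),
    class = "contrast_result")
  # nothing significant: no clusters
  expect_length(extract_clusters(fake)$clusters, 0)
  # alpha = 1: every skeleton voxel is significant; clusters partition it
  all_sig <- fake
  all_sig$p_skel <- rep(0, nv)
  cl <- extract_clusters(all_sig, alpha = 1)$clusters
  expect_equal(sum(vapply(cl, `[[`, integer(1), "size")), nv)
  sizes <- vapply(cl, `[[`, integer(1), "size")
  expect_true(all(diff(sizes) <= 0))
  # two planted blobs of known sizes come back in size order
  two <- fake
  # pick two spatially distant runs of skeleton voxels
  ord <- order(sk$vox)
  sel <- ord[c(1:30, (nv - 11):nv)]
  two$p_skel[sel] <- 0
  cl2 <- extract_clusters(two)$clusters
  expect_gte(length(cl2), 2)
  expect_equal(sum(vapply(cl2, `[[`, integer(1), "size")), 42)
})
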