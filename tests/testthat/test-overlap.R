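test_that("the packaged gene panel mirrors the deletion table", {
  panel <- load_gene_panel()
  expect_equal(nrow(panel), 27)
  expect_equal(sum(panel$available), 26)
  expect_equal(panel$gene_symbol[!panel$available], "Prrt2")
  expect_false(anyDuplicated(panel$gene_symbol) > 0)
  # malformed panels are rejected
  f <- withr::local_tempfile(fileext = ".tsv")
  d <- panel[, c("gene_symbol", "gene_name", "aliases", "plane",
                 "experiment_id")]
  d$gene_symbol[2] <- d$gene_symbol[1]
  utils::write.table(d, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_gene_panel(f), "duplicate")
})

test_that("packaged contrast lists have the published counts and exclusives", {
  lists <- load_contrast_gene_lists()
  expect_equal(vapply(lists, length, integer(1)),
               c(male_increase = 7L, male_decrease = 8L,
                 female_increase = 3L, female_decrease = 5L))
  rep <- exclusivity_report(lists, panel = load_gene_panel())
  expect_equal(rep$exclusive$male_increase, c("Mvp", "Sez6l2", "Taok2"))
})

test_that("exclusivity is a set difference with stable ordering", {
  same <- list(a = c("X", "Y"), b = c("X", "Y"),
               c = c("X", "Y"), d = c("X", "Y"))
  rep0 <- exclusivity_report(same)
  expect_true(all(vapply(rep0$exclusive, length, integer(1)) == 0))
  disj <- list(a = "A", b = "B", c = "C", d = "D")
  repd <- exclusivity_report(disj)
  expect_equal(repd$exclusive, list(a = "A", b = "B", c = "C", d = "D"))
  expect_error(
    exclusivity_report(list(a = "NotAGene", b = "Mvp"),
                       panel = load_gene_panel()),
    "NotAGene")
})

test_that("cluster transport to the expression grid lands correctly", {
  ph <- small_phantom()
  fine <- skelex:::empty_grid(ph, "diffusion")
  coarse <- skelex:::empty_grid(ph, "expression")
  cl <- list(list(voxels = c(100L, 101L, 132L), size = 3L))
  # same grid, identity chain: mask voxels are the cluster voxels
  m0 <- map_clusters_to_expression_grid(cl, fine, NULL, fine)
  expect_equal(which(m0$data != 0) - 1L, c(100L, 101L, 132L))
  # known translation moves the centroid accordingly
  shift <- affine_transform(translation = c(2 * ph$spacing[1], 0, 0))
  m1 <- map_clusters_to_expression_grid(cl, fine, shift, fine)
  c0 <- colMeans(which(m0$data != 0, arr.ind = TRUE))
  c1 <- colMeans(which(m1$data != 0, arr.ind = TRUE))
  expect_equal(unname(c1 - c0), c(2, 0, 0), tolerance = 0.5)
  # cross-resolution transport reaches the coarse grid
  m2 <- map_clusters_to_expression_grid(cl, fine, NULL, coarse)
  expect_gte(sum(m2$data), 1)
  expect_warning(map_clusters_to_expression_grid(list(), fine, NULL,
                                                 coarse),
                 "empty")
})

test_that("sample extraction respects masks and the missing sentinel", {
  a <- array(-1, c(5, 5, 5))
  a[2:4, 2:4, 2:4] <- 3
  e <- brain_volume(a, missing_value = -1)
  mask_all <- brain_volume((a != -1) * 1)
  expect_equal(extract_sample(e, mask_all), rep(3, 27))
  # 15-voxel mask with 3 missing -> 12 values
  m <- array(0, c(5, 5, 5))
  m[which(a == 3)[1:12]] <- 1   # 12 valid voxels
  m[which(a == -1)[1:3]] <- 1   # 3 voxels in the missing shell
  expect_length(extract_sample(e, brain_volume(m)), 12)
  # pooling two disjoint masks adds their samples
  m1 <- array(0, c(5, 5, 5)); m1[2:4, 2, 2] <- 1
  m2 <- array(0, c(5, 5, 5)); m2[2:3, 4, 4] <- 1
  expect_length(extract_sample(e, brain_volume(m1 + m2)), 5)
  empty <- brain_volume(array(0, c(5, 5, 5)))
  expect_error(extract_sample(e, empty), "no valid voxels")
})

test_that("gene classification recovers planted enrichment with direction calls", {
  ph <- small_phantom()
  panel_spec <- expression_panel_spec(seed = 14)
  maps <- make_energy_maps(ph, panel_spec)
  brain <- structure_mask(ph, "brain", "expression")
  tube <- structure_mask(ph, "tube", "expression")
  res <- classify_genes(maps, list(male_increase = tube), brain,
                        alpha = 0.05, panel = load_gene_panel())
  over <- attr(res, "overexpressed")$male_increase
  planted <- c("Mvp", "Sez6l2", "Taok2")
  # full sensitivity for a x3 enrichment...
  expect_true(all(planted %in% over))
  # ...with the planted genes separating cleanly from the null genes
  tested <- res[res$status == "tested", ]
  expect_equal(sort(tested$gene[order(tested$p_value)][1:3]), planted)
  # null genes exceed the raw threshold only at the alpha-level rate
  expect_lte(length(setdiff(over, planted)), 3)
  # a gene depleted in the clusters is called under, never overexpressed
  dep <- maps
  tmask <- tube$data > 0
  dep[["Maz"]]$data[tmask] <- dep[["Maz"]]$data[tmask] / 5
  res2 <- classify_genes(dep, list(male_increase = tube), brain)
  row <- res2[res2$gene == "Maz", ]
  expect_equal(row$direction, "under")
  expect_false("Maz" %in% attr(res2, "overexpressed")$male_increase)
  # unavailable panel genes are reported as no_map, not as negatives
  expect_true(all(res$status[res$gene == "Prrt2"] == "no_map"))
  expect_true(all(res$direction[res$gene == "Prrt2"] == "none"))
  # rank invariance under monotone transforms of one gene's map
  mono <- maps
  mono[["Mvp"]]$data[mono[["Mvp"]]$data != -1] <-
    log1p(mono[["Mvp"]]$data[mono[["Mvp"]]$data != -1])
  res3 <- classify_genes(mono, list(male_increase = tube), brain)
  expect_equal(res3$p_value[res3$gene == "Mvp"],
               res$p_value[res$gene == "Mvp"])
})

test_that("reports are deterministic and complete", {
  ph <- small_phantom()
  panel_spec <- expression_panel_spec(seed = 15)
  maps <- make_energy_maps(ph, panel_spec)
  brain <- structure_mask(ph, "brain", "expression")
  tube <- structure_mask(ph, "tube", "expression")
  sheet <- structure_mask(ph, "sheet", "expression")
  res <- classify_genes(maps, list(male_increase = tube,
                                   male_decrease = sheet),
                        brain, panel = load_gene_panel())
  # one row per available gene x contrast plus no_map rows
  expect_equal(sum(res$status != "no_map"), 26 * 2)
  excl <- exclusivity_report(attr(res, "overexpressed"))
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  render_report(res, excl, dir1)
  render_report(res, excl, dir2)
  for (f in c("gene_overlap.tsv", "table2_matrix.tsv",
              "exclusivity.json")) {
    expect_true(file.exists(file.path(dir1, f)))
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)))
  }
  tab <- utils::read.delim(file.path(dir1, "table2_matrix.tsv"),
                           colClasses = "character")
  expect_equal(ncol(tab), 2)
})
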