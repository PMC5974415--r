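#' End-to-end synthetic pipeline
#'
#' Orchestrates simulate -> register -> skeleton statistics -> expression
#' overlap as one reproducible run: a single global seed fans out to
#' per-stage seeds by fixed offsets, so each stage is independently
#' reproducible, and a manifest records parameters, seeds, stage timings
#' and (when writing to disk) output hashes.
#'
#' @name cli_pipeline
NULL

#' Default pipeline configuration
#'
#' A plain serialisable list mirroring the study conditions: 64^3 phantom
#' at 0.125 mm with a 0.2 mm expression grid, cohort 6/4/6/5, 500
#' permutations, FA threshold 0.2, raw alpha 0.05.
#'
#' @param seed global integer seed.
#' @param outdir optional output directory; `NULL` keeps results in
#'   memory.
#' @return A nested configuration list.
#' @export
default_config <- function(seed = 1L, outdir = NULL) {
  list(
    seed = as.integer(seed),
    outdir = outdir,
    phantom = list(grid_shape = c(64L, 64L, 64L), spacing = 0.125,
                   expression_spacing = 0.2),
    cohort = list(n_per_group = c(male_wt = 6L, male_del = 4L,
                                  female_wt = 6L, female_del = 5L),
                  noise_sd = 0.03, misalignment_sd = c(0.15, 1.5)),
    registration = list(enabled = TRUE, metric = "ncc",
                        rotation_search = 0, rotation_step = 0,
                        pyramid = c(4, 2), maxit = c(300, 200)),
    stats = list(n_perm = 500L, fa_threshold = 0.2, E = 1, H = 2,
                 nsteps = 100L, search_radius = 4L, alpha = 0.05),
    expression = list(baseline_level = 1, noise_sigma = 0.3),
    overlap = list(alpha = 0.05, correction = "none", pooling = "voxels")
  )
}

#' Validate a pipeline configuration
#'
#' Checks every block against its invariants and returns a character
#' vector of issues naming the offending keys (empty when valid); never
#' throws.
#'
#' @param config a configuration list as from [default_config].
#' @return Character vector of issues.
#' @export
validate_config <- function(config) {
  issues <- character(0)
  add <- function(msg) issues <<- c(issues, msg)
  if (is.null(config$seed) || !is.finite(config$seed))
    add("seed: must be a finite integer")
  ph <- config$phantom
  if (is.null(ph) || any(ph$grid_shape < 8))
    add("phantom.grid_shape: must be >= 8 per axis")
  if (!is.null(ph) && any(ph$spacing <= 0))
    add("phantom.spacing: must be strictly positive")
  if (!is.null(ph) && any(ph$expression_spacing <= 0))
    add("phantom.expression_spacing: must be strictly positive")
  co <- config$cohort
  if (is.null(co)) add("cohort: missing block")
  else {
    if (any(co$n_per_group < 2)) add("cohort.n_per_group: need >= 2 per group")
    if (is.null(co$noise_sd) || co$noise_sd < 0)
      add("cohort.noise_sd: must be >= 0")
    if (any(co$misalignment_sd < 0))
      add("cohort.misalignment_sd: must be >= 0")
  }
  st <- config$stats
  if (is.null(st) || is.null(st$n_perm) || st$n_perm < 1)
    add("stats.n_perm: must be >= 1")
  if (!is.null(st) && (st$fa_threshold < 0 || st$fa_threshold > 1))
    add("stats.fa_threshold: must be in [0, 1]")
  if (!is.null(st) && (st$alpha <= 0 || st$alpha >= 1))
    add("stats.alpha: must be in (0, 1)")
  ov <- config$overlap
  if (!is.null(ov) && (ov$alpha <= 0 || ov$alpha >= 1))
    add("overlap.alpha: must be in (0, 1)")
  ex <- config$expression
  if (!is.null(ex) && !is.null(ex$noise_sigma) && ex$noise_sigma < 0)
    add("expression.noise_sigma: must be >= 0")
  issues
}

#' Run the full synthetic pipeline
#'
#' Simulates the phantom cohort and expression maps, realigns each
#' animal's FA volume to the template (recovering the planted
#' misalignments), builds the mean-FA skeleton, runs the four
#' sex-by-direction permutation contrasts with TFCE, transports the
#' significant clusters and the skeleton onto the expression grid, and
#' classifies overexpressed genes per contrast with the rank-sum test.
#'
#' @param config a configuration list ([default_config]); validated
#'   before any computation.
#' @return Invisibly, a list with `manifest`, `skeleton`, `contrasts`
#'   (each with clusters), `gene_results`, `overexpressed`, and
#'   `exclusivity`.
#' @export
run_pipeline <- function(config = default_config()) {
  issues <- validate_config(config)
  if (length(issues))
    stop("invalid configuration:\n  ", paste(issues, collapse = "\n  "))
  seed <- as.integer(config$seed)
  t0 <- proc.time()[3]
  timings <- c()
  tick <- function(name) {
    now <- proc.time()[3]
    timings[name] <<- unname(now - t0)
    t0 <<- now
  }

  phantom <- phantom_spec(grid_shape = config$phantom$grid_shape,
                          spacing = config$phantom$spacing,
                          expression_spacing =
                            config$phantom$expression_spacing,
                          seed = seed)
  cohort <- cohort_spec(n_per_group = config$cohort$n_per_group,
                        noise_sd = config$cohort$noise_sd,
                        misalignment_sd = config$cohort$misalignment_sd,
                        seed = seed + 1L)
  panel_spec <- expression_panel_spec(baseline_level =
                                        config$expression$baseline_level,
                                      noise_sigma =
                                        config$expression$noise_sigma,
                                      seed = seed + 2L)
  template <- make_template(phantom)
  animals <- make_fa_cohort(phantom, cohort)
  tick("simulate")

  if (isTRUE(config$registration$enabled) &&
      any(config$cohort$misalignment_sd > 0)) {
    cfg <- registration_config(
      metric = config$registration$metric,
      rotation_search = config$registration$rotation_search,
      rotation_step = config$registration$rotation_step,
      pyramid = config$registration$pyramid,
      maxit = config$registration$maxit)
    aligned <- lapply(animals, function(a) {
      tr <- affine_register(a$volume, template, cfg)
      resample(a$volume, tr, target = template)
    })
  } else {
    aligned <- lapply(animals, `[[`, "volume")
  }
  tick("register")

  st <- config$stats
  mean_fa <- build_mean_fa(aligned)
  skel <- skeletonize(mean_fa, fa_threshold = st$fa_threshold)
  values <- do.call(rbind, lapply(aligned, project_onto_skeleton,
                                  skel = skel,
                                  search_radius = st$search_radius))
  meta <- do.call(rbind, lapply(animals, function(a)
    data.frame(a$meta, stringsAsFactors = FALSE)))
  contrasts <- list()
  for (sx in c("male", "female")) {
    rows <- meta$sex == sx
    res <- permutation_group_test(
      values[rows, , drop = FALSE],
      factor(meta$genotype[rows], levels = c("del", "wt")),
      skel, n_perm = st$n_perm, E = st$E, H = st$H, nsteps = st$nsteps,
      alpha = st$alpha, seed = seed + 3L + (sx == "female"),
      labels_a_gt_b = paste0(sx, "_increase"),
      labels_b_gt_a = paste0(sx, "_decrease"))
    contrasts[[paste0(sx, "_increase")]] <-
      extract_clusters(res$a_gt_b, alpha = st$alpha)
    contrasts[[paste0(sx, "_decrease")]] <-
      extract_clusters(res$b_gt_a, alpha = st$alpha)
  }
  tick("skeleton_stats")

  energy <- make_energy_maps(phantom, panel_spec)
  egrid <- energy[[1]]
  chain <- affine_transform(source_space = "diffusion",
                            target_space = "expression")
  cluster_masks <- suppressWarnings(
    lapply(contrasts, map_clusters_to_expression_grid,
           source_grid = mean_fa, chain = chain, target_grid = egrid))
  skel_mask <- map_skeleton_to_expression_grid(skel, chain = chain,
                                               target_grid = egrid)
  panel <- load_gene_panel()
  gene_results <- suppressWarnings(
    classify_genes(energy, cluster_masks, skel_mask,
                   alpha = config$overlap$alpha, panel = panel,
                   correction = config$overlap$correction,
                   pooling = config$overlap$pooling))
  over <- attr(gene_results, "overexpressed")
  excl <- exclusivity_report(over, panel = panel)
  tick("expression_overlap")

  manifest <- list(
    package_version = as.character(utils::packageVersion("skelex")),
    seed = seed,
    stage_seeds = c(phantom = seed, cohort = seed + 1L,
                    expression = seed + 2L, perm_male = seed + 3L,
                    perm_female = seed + 4L),
    parameters = config[setdiff(names(config), "outdir")],
    n_animals = length(animals),
    contrasts = names(contrasts),
    n_gene_results_per_contrast =
      vapply(names(contrasts), function(cn)
        sum(gene_results$contrast == cn & gene_results$status != "no_map"),
        integer(1)),
    n_clusters = vapply(contrasts, function(cr)
      length(cr$clusters), integer(1)),
    skeleton_voxels = length(skel$vox),
    timings_sec = as.list(round(timings, 3)))

  out <- list(manifest = manifest, template = template, mean_fa = mean_fa,
              skeleton = skel, meta = meta, contrasts = contrasts,
              gene_results = gene_results, overexpressed = over,
              exclusivity = excl)
  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    write_volume(mean_fa, file.path(config$outdir, "mean_fa.nii.gz"))
    skel_vol <- brain_volume(skel$mask * 1.0, spacing = mean_fa$spacing,
                             affine = mean_fa$affine)
    write_volume(skel_vol, file.path(config$outdir, "skeleton.nii.gz"))
    for (cn in names(contrasts))
      write_volume(contrasts[[cn]]$corrected_p_map,
                   file.path(config$outdir, paste0("pmap_", cn, ".nii.gz")))
    utils::write.table(meta, file.path(config$outdir, "cohort.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    render_report(gene_results, excl, config$outdir)
    files <- list.files(config$outdir, full.names = TRUE)
    manifest$output_hashes <- as.list(tools::md5sum(files))
    out$manifest <- manifest
    jsonlite::write_json(manifest,
                         file.path(config$outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }
  invisible(out)
}
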