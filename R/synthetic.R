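#' Synthetic brain phantoms with known ground truth
#'
#' The generator emulates everything the real study obtained from ex vivo
#' MRI and the expression atlas: a brain-shaped template with internal
#' structures, per-animal FA volumes with tract-like high-FA structures,
#' sex-by-genotype effects, noise and small affine misalignments, and
#' per-gene expression energy volumes on a coarser atlas-style grid with a
#' missing-data sentinel outside the brain. Every output is deterministic
#' under (spec, seed).
#'
#' @name synthetic
NULL

# Run code under a seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Phantom geometry specification
#'
#' Describes the synthetic brain in world coordinates (mm): an ellipsoidal
#' brain shell plus three internal structures mimicking the anatomy that
#' carries the planted effects — a thin "callosal" sheet, a medial
#' "peristriatal" tube and a "cerebellar" blob. Two grids are generated
#' from one spec: a fine diffusion grid and a coarse expression grid, so
#' the resolution-mismatch path of the pipeline is exercised.
#'
#' @param grid_shape voxel counts of the diffusion grid.
#' @param spacing diffusion-grid voxel size in mm (default 0.125 mm, the
#'   acquisition scale).
#' @param expression_spacing expression-grid voxel size in mm (default
#'   0.2 mm, the atlas scale).
#' @param structures named list of geometric primitives in world mm; the
#'   defaults fit inside the default shell.
#' @param seed integer RNG seed.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(64, 64, 64),
                         spacing = c(0.125, 0.125, 0.125),
                         expression_spacing = 0.2,
                         structures = NULL, seed = 1L) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3)
  extent <- grid_shape * spacing
  if (is.null(structures)) {
    structures <- list(
      brain = list(type = "ellipsoid", center = c(0, 0, 0),
                   semiaxes = c(0.46, 0.38, 0.32) * extent),
      sheet = list(type = "sheet", center = c(0, 0, 0.10 * extent[3]),
                   normal_axis = 3, half_thickness = 0.20,
                   half_extent = c(0.28 * extent[1], 0.20 * extent[2]),
                   sigma = 0.25, fa_amp = 0.5),
      tube = list(type = "tube", center = c(0, -0.12 * extent[2],
                                            -0.06 * extent[3]),
                  axis = 1, radius = 0.35, half_length = 0.26 * extent[1],
                  sigma = 0.30, fa_amp = 0.5),
      blob = list(type = "blob", center = c(0, 0.22 * extent[2],
                                            -0.16 * extent[3]),
                  radius = 0.6, sigma = 0.35, fa_amp = 0.35))
  }
  spec <- structure(list(grid_shape = as.integer(grid_shape),
                         spacing = spacing,
                         expression_spacing = rep(expression_spacing, 3)[1:3],
                         structures = structures, seed = as.integer(seed)),
                    class = "phantom_spec")
  check_structures_inside(spec)
  spec
}

check_structures_inside <- function(spec) {
  br <- spec$structures$brain
  inside <- function(pt) sum(((pt - br$center) / br$semiaxes)^2) <= 1
  for (nm in setdiff(names(spec$structures), "brain")) {
    st <- spec$structures[[nm]]
    if (!inside(st$center))
      stop("structure '", nm, "' lies outside the brain shell")
  }
  ext <- spec$grid_shape * spec$spacing / 2
  if (any(br$semiaxes > ext))
    stop("brain shell exceeds the grid")
  invisible(TRUE)
}

# world coordinates (mm) of every voxel of a grid, as three arrays
grid_world_coords <- function(shape, affine) {
  i <- (seq_len(shape[1]) - 1)
  j <- (seq_len(shape[2]) - 1)
  k <- (seq_len(shape[3]) - 1)
  I <- array(rep(i, times = shape[2] * shape[3]), shape)
  J <- array(rep(rep(j, each = shape[1]), times = shape[3]), shape)
  K <- array(rep(k, each = shape[1] * shape[2]), shape)
  list(x = affine[1, 1] * I + affine[1, 2] * J + affine[1, 3] * K + affine[1, 4],
       y = affine[2, 1] * I + affine[2, 2] * J + affine[2, 3] * K + affine[2, 4],
       z = affine[3, 1] * I + affine[3, 2] * J + affine[3, 3] * K + affine[3, 4])
}

empty_grid <- function(spec, which = c("diffusion", "expression")) {
  which <- match.arg(which)
  if (which == "diffusion") {
    shape <- spec$grid_shape; sp <- spec$spacing
  } else {
    extent <- spec$grid_shape * spec$spacing
    sp <- spec$expression_spacing
    shape <- as.integer(ceiling(extent / sp))
  }
  brain_volume(array(0, shape), spacing = sp)
}

# signed profile in [0,1] of a structure: 1 at its core, Gaussian falloff
structure_profile <- function(st, w) {
  if (st$type == "ellipsoid") {
    r2 <- ((w$x - st$center[1]) / st$semiaxes[1])^2 +
          ((w$y - st$center[2]) / st$semiaxes[2])^2 +
          ((w$z - st$center[3]) / st$semiaxes[3])^2
    return((r2 <= 1) * 1.0)
  }
  if (st$type == "sheet") {
    ax <- st$normal_axis
    coords <- list(w$x, w$y, w$z)
    d <- coords[[ax]] - st$center[ax]
    inplane <- setdiff(1:3, ax)
    ok <- abs(coords[[inplane[1]]] - st$center[inplane[1]]) <=
            st$half_extent[1] &
          abs(coords[[inplane[2]]] - st$center[inplane[2]]) <=
            st$half_extent[2]
    return(exp(-d^2 / (2 * st$sigma^2)) * ok)
  }
  if (st$type == "tube") {
    perp <- setdiff(1:3, st$axis)
    coords <- list(w$x, w$y, w$z)
    r2 <- (coords[[perp[1]]] - st$center[perp[1]])^2 +
          (coords[[perp[2]]] - st$center[perp[2]])^2
    ok <- abs(coords[[st$axis]] - st$center[st$axis]) <= st$half_length
    return(exp(-r2 / (2 * st$sigma^2)) * ok)
  }
  if (st$type == "blob") {
    r2 <- (w$x - st$center[1])^2 + (w$y - st$center[2])^2 +
          (w$z - st$center[3])^2
    return(exp(-r2 / (2 * st$sigma^2)))
  }
  stop("unknown structure type: ", st$type)
}

#' Binary mask of one phantom structure
#'
#' The core of a structure (profile at half maximum or better, clipped to
#' the brain shell), on either grid. These masks are the ground truth for
#' planted effects and enrichment regions.
#'
#' @param spec a [phantom_spec].
#' @param name structure name (`"brain"`, `"sheet"`, `"tube"`, `"blob"`).
#' @param grid `"diffusion"` or `"expression"`.
#' @return A [brain_volume] of 0/1 values.
#' @export
structure_mask <- function(spec, name, grid = c("diffusion", "expression")) {
  grid <- match.arg(grid)
  if (!name %in% names(spec$structures)) stop("unknown structure: ", name)
  g <- empty_grid(spec, grid)
  w <- grid_world_coords(dim(g$data), g$affine)
  prof <- structure_profile(spec$structures[[name]], w)
  brain <- structure_profile(spec$structures$brain, w)
  m <- if (name == "brain") prof >= 0.5 else (prof >= 0.5 & brain >= 0.5)
  brain_volume(m * 1.0, spacing = g$spacing, affine = g$affine)
}

# separable Gaussian smoothing (sigma in voxels), truncated at 3 sigma
gaussian_smooth <- function(a, sigma = 1) {
  if (sigma <= 0) return(a)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  sm_axis <- function(x, axis) {
    out <- array(0, dim(x))
    n <- dim(x)[axis]
    for (t in seq(-r, r)) {
      src <- pmin(pmax(seq_len(n) + t, 1L), n)
      idx <- list(quote(expr = ), quote(expr = ), quote(expr = ))
      idx[[axis]] <- src
      out <- out + k[t + r + 1] *
        do.call(`[`, c(list(x), idx, list(drop = FALSE)))
    }
    out
  }
  a <- sm_axis(a, 1); a <- sm_axis(a, 2); sm_axis(a, 3)
}

#' Build the anatomical template volume
#'
#' A smooth brain-shaped intensity volume (background 0) with internal
#' structure contrast, standing in for the standard-space template images.
#'
#' @param spec a [phantom_spec].
#' @param grid `"diffusion"` or `"expression"`.
#' @return A [brain_volume].
#' @export
make_template <- function(spec, grid = c("diffusion", "expression")) {
  grid <- match.arg(grid)
  g <- empty_grid(spec, grid)
  w <- grid_world_coords(dim(g$data), g$affine)
  br <- spec$structures$brain
  r2 <- ((w$x - br$center[1]) / br$semiaxes[1])^2 +
        ((w$y - br$center[2]) / br$semiaxes[2])^2 +
        ((w$z - br$center[3]) / br$semiaxes[3])^2
  intens <- pmax(0, 1 - r2) # smooth shell profile, 1 at centre, 0 outside
  for (nm in setdiff(names(spec$structures), "brain")) {
    st <- spec$structures[[nm]]
    intens <- intens + 0.5 * structure_profile(st, w) * (r2 <= 1)
  }
  intens <- gaussian_smooth(intens, sigma = 1)
  intens[r2 > 1.2] <- 0
  brain_volume(intens, spacing = g$spacing, affine = g$affine)
}

# noise-free FA template: low background FA inside the brain, tract-like
# high FA along sheet/tube (peak ~0.6), moderate blob
fa_template <- function(spec) {
  g <- empty_grid(spec, "diffusion")
  w <- grid_world_coords(dim(g$data), g$affine)
  brain <- structure_profile(spec$structures$brain, w)
  fa <- 0.1 * brain
  for (nm in setdiff(names(spec$structures), "brain")) {
    st <- spec$structures[[nm]]
    fa <- fa + st$fa_amp * structure_profile(st, w) * brain
  }
  fa <- pmin(fa, 1)
  brain_volume(fa, spacing = g$spacing, affine = g$affine)
}

#' Cohort specification for the synthetic study
#'
#' Group sizes, planted FA effects, noise and misalignment scales. The
#' default group sizes (6 male WT, 4 male del/+, 6 female WT, 5 female
#' del/+; 21 animals) match the study cohort; the default effects mirror
#' its qualitative endophenotype: a male-del/+-only FA increase on the
#' medial tube, an FA decrease in both sexes on the callosal sheet, and a
#' small female-only increase on the cerebellar blob.
#'
#' @param n_per_group named counts for `male_wt`, `male_del`, `female_wt`,
#'   `female_del` (each >= 2).
#' @param effects named list: per structure, a named vector of FA offsets
#'   by group.
#' @param noise_sd additive Gaussian FA noise inside the brain (FA units).
#' @param misalignment_sd length-2 (mm, deg) scale of the random true
#'   affine misalignment applied per animal; 0 disables it.
#' @param seed integer RNG seed.
#' @export
cohort_spec <- function(n_per_group = c(male_wt = 6, male_del = 4,
                                        female_wt = 6, female_del = 5),
                        effects = list(
                          tube = c(male_del = 0.15),
                          sheet = c(male_del = -0.10, female_del = -0.10),
                          blob = c(female_del = 0.05)),
                        noise_sd = 0.03,
                        misalignment_sd = c(0.15, 1.5),
                        seed = 1L) {
  grp <- c("male_wt", "male_del", "female_wt", "female_del")
  if (!all(grp %in% names(n_per_group)))
    stop("n_per_group must name male_wt, male_del, female_wt, female_del")
  if (any(n_per_group[grp] < 2))
    stop("need at least 2 animals per group")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (length(misalignment_sd) == 1L)
    misalignment_sd <- c(misalignment_sd, misalignment_sd)
  structure(list(n_per_group = n_per_group[grp], effects = effects,
                 noise_sd = noise_sd, misalignment_sd = misalignment_sd,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Simulate the FA cohort
#'
#' Per animal: tract FA template + group effect offsets on the structure
#' core masks + Gaussian noise inside the brain, clipped to \[0, 1\], then
#' warped through a small random true affine (returned, so registration
#' recovery is testable). Metadata records sex and genotype.
#'
#' @param phantom a [phantom_spec].
#' @param cohort a [cohort_spec].
#' @return List of animals; each element has `meta` (id, sex, genotype,
#'   group), `volume` (a [brain_volume]) and `true_transform` (an
#'   [affine_transform] aligning the animal back to template space).
#' @export
make_fa_cohort <- function(phantom, cohort) {
  base <- fa_template(phantom)
  brain <- structure_mask(phantom, "brain")$data > 0
  masks <- lapply(setdiff(names(phantom$structures), "brain"),
                  function(nm) structure_mask(phantom, nm)$data > 0)
  names(masks) <- setdiff(names(phantom$structures), "brain")
  grp_of <- rep(names(cohort$n_per_group), times = cohort$n_per_group)
  with_seed(cohort$seed, {
    lapply(seq_along(grp_of), function(a) {
      g <- grp_of[a]
      fa <- base$data
      for (nm in names(cohort$effects)) {
        eff <- cohort$effects[[nm]]
        if (g %in% names(eff)) fa <- fa + eff[[g]] * masks[[nm]]
      }
      if (any(fa < -1e-6) || any(fa > 1 + 1e-6))
        warning("planted effects push FA outside [0,1]; clipping")
      if (cohort$noise_sd > 0)
        fa <- fa + stats::rnorm(length(fa), 0, cohort$noise_sd) * brain
      fa <- pmin(pmax(fa, 0), 1)
      vol <- brain_volume(fa, spacing = base$spacing, affine = base$affine)
      if (any(cohort$misalignment_sd > 0)) {
        pair <- make_misaligned_pair(
          vol, jitter = cohort$misalignment_sd,
          seed = sample.int(.Machine$integer.max, 1))
        vol <- pair$moving
        tr <- pair$true_transform
      } else {
        tr <- affine_transform(center = world_center(vol))
      }
      list(meta = list(id = sprintf("animal_%02d", a),
                       sex = sub("_.*", "", g),
                       genotype = sub(".*_", "", g), group = g),
           volume = vol, true_transform = tr)
    })
  })
}

world_center <- function(vol) {
  as.numeric(vox_to_world(vol, matrix((dim(vol$data) - 1) / 2, 1)))
}

#' Generate a misaligned copy of a volume with known truth
#'
#' Draws a random affine at the given jitter scale (uniform in
#' +/- scale for translation mm and rotation deg, optionally log-scale),
#' resamples the volume through its inverse and returns both the moving
#' image and the true transform, i.e. the transform that aligns `moving`
#' back onto `vol` (`resample(moving, true_transform)` recovers `vol` up
#' to interpolation blur).
#'
#' @param vol a [brain_volume].
#' @param jitter numeric: `c(translation_mm, rotation_deg)` or
#'   `c(translation_mm, rotation_deg, log_scale)`.
#' @param seed integer seed (same seed, same transform).
#' @return `list(moving = brain_volume, true_transform = affine_transform)`.
#' @export
make_misaligned_pair <- function(vol, jitter = c(0.5, 5), seed = 1L) {
  if (any(jitter < 0)) stop("jitter must be >= 0")
  jt <- jitter[1]
  jr <- if (length(jitter) >= 2) jitter[2] else 0
  js <- if (length(jitter) >= 3) jitter[3] else 0
  ctr <- world_center(vol)
  tr <- with_seed(seed, {
    affine_transform(
      translation = stats::runif(3, -jt, jt),
      rotation = stats::runif(3, -jr, jr),
      scale = exp(stats::runif(3, -js, js)),
      center = ctr)
  })
  moving <- resample(vol, invert_transform(tr), target = vol)
  list(moving = moving, true_transform = tr)
}

#' Expression panel specification
#'
#' Which genes get synthetic energy maps and where enrichment is planted.
#' The default panel is the packaged deletion panel minus its unavailable
#' member, with the three male-endophenotype genes enriched on the tube,
#' two shared-decrease genes on the callosal sheet and one on the
#' cerebellar blob, all at a factor well above the noise.
#'
#' @param genes character vector of gene symbols (default: the packaged
#'   panel's available genes).
#' @param enriched_sets named list (names = structure names) of
#'   `list(genes = ..., factor = ...)`, factor > 1.
#' @param baseline_level median baseline expression (arbitrary units).
#' @param noise_sigma log-normal sigma of voxelwise expression noise.
#' @param seed integer RNG seed.
#' @export
expression_panel_spec <- function(genes = NULL,
                                  enriched_sets = list(
                                    tube = list(genes = c("Mvp", "Sez6l2",
                                                          "Taok2"),
                                                factor = 3),
                                    sheet = list(genes = c("Doc2a",
                                                           "Ino80e"),
                                                 factor = 3),
                                    blob = list(genes = "Kif22",
                                                factor = 3)),
                                  baseline_level = 1,
                                  noise_sigma = 0.3, seed = 1L) {
  if (is.null(genes)) {
    panel <- load_gene_panel()
    genes <- panel$gene_symbol[panel$available]
  }
  for (nm in names(enriched_sets)) {
    es <- enriched_sets[[nm]]
    if (!all(es$genes %in% genes))
      stop("enriched gene(s) not in panel: ",
           paste(setdiff(es$genes, genes), collapse = ", "))
    if (es$factor <= 1) stop("enrichment factor must be > 1")
  }
  structure(list(genes = genes, enriched_sets = enriched_sets,
                 baseline_level = baseline_level,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "expression_panel_spec")
}

#' Generate synthetic expression energy maps
#'
#' One atlas-style energy volume per gene on the coarse expression grid:
#' log-normal baseline expression inside the brain, the missing sentinel
#' (-1) outside, and each enriched gene's values multiplied by its factor
#' inside its target structure.
#'
#' @param phantom a [phantom_spec].
#' @param panel an [expression_panel_spec].
#' @return Named list of [brain_volume]s (one per gene), each with
#'   `missing_value = -1`.
#' @export
make_energy_maps <- function(phantom, panel) {
  g <- empty_grid(phantom, "expression")
  brain <- structure_mask(phantom, "brain", "expression")$data > 0
  region_masks <- lapply(names(panel$enriched_sets), function(nm)
    structure_mask(phantom, nm, "expression")$data > 0)
  names(region_masks) <- names(panel$enriched_sets)
  with_seed(panel$seed, {
    maps <- lapply(panel$genes, function(gene) {
      vals <- panel$baseline_level *
        exp(stats::rnorm(length(brain), 0, panel$noise_sigma))
      for (nm in names(panel$enriched_sets)) {
        es <- panel$enriched_sets[[nm]]
        if (gene %in% es$genes)
          vals[region_masks[[nm]]] <- vals[region_masks[[nm]]] * es$factor
      }
      arr <- array(-1, dim(brain))
      arr[brain] <- vals[brain]
      brain_volume(arr, spacing = g$spacing, affine = g$affine,
                   missing_value = -1)
    })
    names(maps) <- panel$genes
    maps
  })
}
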