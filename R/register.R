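#' Registration configuration
#'
#' Controls the similarity metric and the deterministic multi-resolution
#' optimizer of [affine_register]. The default metric is normalized
#' mutual information (32 bins), robust to the cross-modality contrast of
#' histology-to-MR steps; normalized cross-correlation (`"ncc"`) is the
#' better choice for same-modality steps such as FA-to-template. The rotation search covers +/- `rotation_search`
#' degrees per axis on a coarse grid at the lowest pyramid level before
#' local refinement; there is no unseeded randomness anywhere.
#'
#' @param metric `"ncc"` or `"nmi"`.
#' @param rotation_search half-width of the rotation search per axis, deg.
#' @param rotation_step grid step of the coarse rotation search, deg.
#' @param pyramid integer downsampling factors, coarse to fine.
#' @param maxit Nelder-Mead iteration budget per pyramid level.
#' @param tol relative convergence tolerance of the refinement.
#' @param bins histogram bins for the NMI metric.
#' @param interpolation `"trilinear"` or `"nearest"` (resampling mode used
#'   during metric evaluation).
#' @export
registration_config <- function(metric = c("nmi", "ncc"),
                                rotation_search = 90, rotation_step = 30,
                                pyramid = c(4, 2, 1),
                                maxit = c(400, 150, 80),
                                tol = 1e-9, bins = 32,
                                interpolation = c("trilinear", "nearest")) {
  metric <- match.arg(metric)
  interpolation <- match.arg(interpolation)
  if (length(maxit) == 1L) maxit <- rep(maxit, length(pyramid))
  structure(list(metric = metric, rotation_search = rotation_search,
                 rotation_step = rotation_step, pyramid = pyramid,
                 maxit = maxit, tol = tol, bins = bins,
                 interpolation = interpolation),
            class = "registration_config")
}

# target grid spec from a brain_volume or list(shape, spacing, affine)
as_grid <- function(target) {
  if (inherits(target, "brain_volume"))
    list(shape = dim(target$data), spacing = target$spacing,
         affine = target$affine)
  else {
    stopifnot(all(c("shape", "affine") %in% names(target)))
    target
  }
}

#' Resample a volume through an affine transform
#'
#' Output voxel value = source volume interpolated at `t^-1`(world point
#' of the target voxel). Trilinear by default; voxels equal to the source
#' `missing_value` are excluded from interpolation (weights renormalised
#' over valid corners) and never blended into valid data. Out-of-field
#' voxels receive the missing sentinel when one is set, else 0.
#'
#' @param vol source [brain_volume].
#' @param t an [affine_transform] mapping source world to target world
#'   (NULL = identity, pure regridding).
#' @param target a [brain_volume] or `list(shape, spacing, affine)`
#'   defining the output grid (default: the source grid).
#' @param mode `"trilinear"` or `"nearest"`.
#' @return A [brain_volume] on the target grid.
#' @export
resample <- function(vol, t = NULL, target = vol,
                     mode = c("trilinear", "nearest")) {
  mode <- match.arg(mode)
  grid <- as_grid(target)
  tm <- if (is.null(t)) diag(4) else t$matrix
  if (abs(det(tm)) < .Machine$double.eps) stop("singular transform")
  # target voxel -> target world -> t^-1 -> source world -> source voxel
  M <- solve(vol$affine) %*% solve(tm) %*% grid$affine
  has_missing <- !is.null(vol$missing_value)
  bg <- if (has_missing) vol$missing_value else 0
  out <- resample_affine(as.numeric(vol$data), dim(vol$data), M,
                         as.integer(grid$shape), background = bg,
                         has_missing = has_missing,
                         missing = if (has_missing) vol$missing_value else -1,
                         nearest = (mode == "nearest"))
  brain_volume(array(out, grid$shape), spacing = grid$spacing,
               affine = grid$affine, missing_value = vol$missing_value)
}

# trilinear point sampling at fractional 0-based voxel coords (n x 3)
sample_points <- function(vol, ijk) {
  d <- dim(vol$data)
  x <- pmin(pmax(ijk[, 1], 0), d[1] - 1)
  y <- pmin(pmax(ijk[, 2], 0), d[2] - 1)
  z <- pmin(pmax(ijk[, 3], 0), d[3] - 1)
  x0 <- pmin(floor(x), d[1] - 2); y0 <- pmin(floor(y), d[2] - 2)
  z0 <- pmin(floor(z), d[3] - 2)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  at <- function(i, j, k) vol$data[cbind(i + 1, j + 1, k + 1)]
  (1 - fx) * (1 - fy) * (1 - fz) * at(x0, y0, z0) +
    fx * (1 - fy) * (1 - fz) * at(x0 + 1, y0, z0) +
    (1 - fx) * fy * (1 - fz) * at(x0, y0 + 1, z0) +
    fx * fy * (1 - fz) * at(x0 + 1, y0 + 1, z0) +
    (1 - fx) * (1 - fy) * fz * at(x0, y0, z0 + 1) +
    fx * (1 - fy) * fz * at(x0 + 1, y0, z0 + 1) +
    (1 - fx) * fy * fz * at(x0, y0 + 1, z0 + 1) +
    fx * fy * fz * at(x0 + 1, y0 + 1, z0 + 1)
}

# block-mean pyramid level: smooth then decimate by integer factor
downsample_volume <- function(vol, factor) {
  if (factor <= 1) return(vol)
  a <- gaussian_smooth(vol$data, sigma = factor / 2)
  d <- dim(a)
  nd <- pmax(1L, d %/% factor)
  idx <- lapply(1:3, function(ax) pmin(d[ax], (seq_len(nd[ax]) - 1) *
                                         factor + 1 + (factor %/% 2)))
  a <- a[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  aff <- vol$affine
  scale_m <- diag(4)
  scale_m[cbind(1:3, 1:3)] <- factor
  scale_m[1:3, 4] <- factor %/% 2
  brain_volume(array(a, nd), spacing = vol$spacing * factor,
               affine = aff %*% scale_m)
}

metric_value <- function(moving, fixed, tmat, cfg, center) {
  tr <- list(matrix = tmat)
  M <- solve(moving$affine) %*% solve(tmat) %*% fixed$affine
  mv <- resample_affine(as.numeric(moving$data), dim(moving$data), M,
                        dim(fixed$data), background = 0,
                        has_missing = FALSE, missing = -1, nearest = FALSE)
  fx <- as.numeric(fixed$data)
  if (cfg$metric == "ncc") {
    sm <- stats::sd(mv); sf <- stats::sd(fx)
    if (sm == 0 || sf == 0) return(0)
    return(stats::cor(mv, fx))
  }
  # normalized mutual information, joint histogram over `bins` bins
  b <- cfg$bins
  rx <- range(mv); ry <- range(fx)
  ix <- pmin(b, 1L + floor((mv - rx[1]) / (diff(rx) / b)))
  iy <- pmin(b, 1L + floor((fx - ry[1]) / (diff(ry) / b)))
  jt <- tabulate(ix + b * (iy - 1L), b * b)
  p <- matrix(jt / sum(jt), b, b)
  px <- rowSums(p); py <- colSums(p)
  hx <- -sum(px[px > 0] * log(px[px > 0]))
  hy <- -sum(py[py > 0] * log(py[py > 0]))
  hxy <- -sum(p[p > 0] * log(p[p > 0]))
  if (hxy == 0) return(0)
  (hx + hy) / hxy
}

#' Affine registration of two volumes
#'
#' Finds the 12-parameter affine transform (about the centre of the fixed
#' volume) that maximises the similarity between the resampled moving
#' volume and the fixed volume. Deterministic: a coarse rotation grid over
#' the configured search range at the lowest resolution, then
#' Nelder-Mead refinement of all 12 parameters through the pyramid.
#'
#' @param moving,fixed [brain_volume]s with overlapping world extents;
#'   neither may be constant.
#' @param cfg a [registration_config].
#' @param source_space,target_space optional space labels for the result.
#' @return An [affine_transform] mapping moving world onto fixed world.
#' @export
affine_register <- function(moving, fixed, cfg = registration_config(),
                            source_space = NULL, target_space = NULL) {
  if (stats::sd(moving$data) == 0 || stats::sd(fixed$data) == 0)
    stop("cannot register a constant image (similarity metric undefined)")
  center <- world_center(fixed)
  pyr_m <- lapply(cfg$pyramid, function(f) downsample_volume(moving, f))
  pyr_f <- lapply(cfg$pyramid, function(f) downsample_volume(fixed, f))
  p <- c(rep(0, 6), rep(1, 3), rep(0, 3))
  names(p) <- param_names()
  # intensity centre-of-mass initialisation of the translation
  p[1:3] <- intensity_com(fixed) - intensity_com(moving)
  # scaled coordinates so one Nelder-Mead step is comparable across blocks
  q_scale <- c(rep(1, 3), rep(2, 3), rep(0.02, 3), rep(0.02, 3))
  q_off <- c(rep(0, 6), rep(1, 3), rep(0, 3))
  p_to_q <- function(p) (p - q_off) / q_scale
  q_to_p <- function(q) {
    p2 <- q * q_scale + q_off
    names(p2) <- param_names()
    p2
  }
  neg_metric <- function(p2, mv, fx) {
    tm <- params_to_matrix(p2, center)
    if (det(tm[1:3, 1:3]) <= 0) return(1e6)
    -metric_value(mv, fx, tm, cfg, center)
  }
  # coarse rotation grid at the lowest resolution
  if (cfg$rotation_search > 0 && cfg$rotation_step > 0 &&
      cfg$rotation_step <= cfg$rotation_search) {
    angles <- seq(-cfg$rotation_search, cfg$rotation_search,
                  by = cfg$rotation_step)
    best <- Inf; best_r <- c(0, 0, 0)
    mv <- pyr_m[[1]]; fx <- pyr_f[[1]]
    for (rx in angles) for (ry in angles) for (rz in angles) {
      pr <- p; pr[4:6] <- c(rx, ry, rz)
      v <- neg_metric(pr, mv, fx)
      if (v < best) { best <- v; best_r <- c(rx, ry, rz) }
    }
    p[4:6] <- best_r
  }
  # per level: rigid block first, then all 12 parameters
  refine <- function(p, free, mv, fx, maxit) {
    q_full <- p_to_q(p)
    obj <- function(q_free) {
      q_full[free] <- q_free
      neg_metric(q_to_p(q_full), mv, fx)
    }
    fit <- stats::optim(q_full[free], obj, method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = cfg$tol))
    fit <- stats::optim(fit$par, obj, method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = cfg$tol))
    q_full[free] <- fit$par
    q_to_p(q_full)
  }
  for (lev in seq_along(cfg$pyramid)) {
    mv <- pyr_m[[lev]]; fx <- pyr_f[[lev]]
    p <- refine(p, 1:6, mv, fx, cfg$maxit[lev])
    p <- refine(p, 1:12, mv, fx, cfg$maxit[lev])
  }
  # cyclic coordinate polish at full resolution: Brent line searches
  # tighten each parameter after the simplex has collapsed
  mv <- pyr_m[[length(cfg$pyramid)]]; fx <- pyr_f[[length(cfg$pyramid)]]
  q <- p_to_q(p)
  for (sweep in 1:2) {
    for (d in 1:12) {
      f1 <- function(qi) { q2 <- q; q2[d] <- qi; neg_metric(q_to_p(q2), mv, fx) }
      opt <- stats::optimize(f1, c(q[d] - 1, q[d] + 1), tol = 1e-5)
      if (opt$objective <= neg_metric(q_to_p(q), mv, fx)) q[d] <- opt$minimum
    }
  }
  p <- q_to_p(q)
  affine_transform(translation = p[1:3], rotation = p[4:6], scale = p[7:9],
                   shear = p[10:12], center = center,
                   source_space = source_space, target_space = target_space)
}

#' Upsample an expression energy volume
#'
#' Refines the atlas-resolution grid by an integer factor per axis
#' (default 8: 0.2 mm to 0.025 mm) with trilinear interpolation, keeping
#' world geometry; missing-sentinel voxels are propagated, never
#' interpolated across.
#'
#' @param vol200 a [brain_volume] on the coarse grid.
#' @param factor integer upsampling factor per axis.
#' @return A [brain_volume] with each axis length multiplied by `factor`.
#' @export
upsample_energy <- function(vol200, factor = 8L) {
  factor <- as.integer(factor)
  stopifnot(factor >= 1)
  d <- dim(vol200$data)
  nd <- d * factor
  # fine voxel i maps to coarse index (i - (f-1)/2)/f: centres align
  scale_m <- diag(4)
  scale_m[cbind(1:3, 1:3)] <- 1 / factor
  scale_m[1:3, 4] <- -(factor - 1) / (2 * factor)
  aff <- vol200$affine %*% scale_m
  resample(vol200, t = NULL,
           target = list(shape = nd, spacing = vol200$spacing / factor,
                         affine = aff))
}

#' Apply a saved transform chain to an energy map
#'
#' Composes the chain into a single affine and resamples the energy map
#' into the target space in one interpolation pass (never sequential
#' regridding, which would compound interpolation loss).
#'
#' @param energy a [brain_volume] (typically with `missing_value = -1`).
#' @param chain a [transform_chain], list of transforms, or single
#'   [affine_transform].
#' @param target target grid ([brain_volume] or `list(shape, spacing,
#'   affine)`).
#' @export
align_energy_map <- function(energy, chain, target) {
  composed <- compose_chain(chain)
  resample(energy, composed, target = target)
}

#' Histogram-based QC of an alignment step
#'
#' Compares normalised intensity histograms (over non-missing voxels)
#' before and after a transformation; the score is the Jensen-Shannon
#' divergence (natural log, in \[0, ln 2\]). A rigid or affine resampling
#' of a smooth map should barely move the histogram; a large score flags
#' intensity distortion introduced by the alignment.
#'
#' @param before,after [brain_volume]s.
#' @param n_bins number of histogram bins over the pooled range.
#' @param threshold flag level for `flagged`.
#' @return `list(score, table, flagged, threshold)` where `table` holds
#'   per-bin proportions.
#' @export
histogram_qc <- function(before, after, n_bins = 64, threshold = 0.02) {
  vb <- before$data[valid_mask(before)]
  va <- after$data[valid_mask(after)]
  if (!length(vb) || !length(va)) stop("all voxels missing")
  rng <- range(c(vb, va))
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  p <- tabulate(findInterval(vb, breaks, all.inside = TRUE), n_bins)
  q <- tabulate(findInterval(va, breaks, all.inside = TRUE), n_bins)
  p <- p / sum(p); q <- q / sum(q)
  m <- (p + q) / 2
  kl <- function(a, b) sum(ifelse(a > 0, a * log(a / b), 0))
  js <- 0.5 * kl(p, m) + 0.5 * kl(q, m)
  list(score = js,
       table = data.frame(bin_low = breaks[-(n_bins + 1)],
                          bin_high = breaks[-1], before = p, after = q),
       flagged = js > threshold, threshold = threshold)
}

#' Pick the most typical volume of a set
#'
#' Registers every volume to every candidate target and measures, for
#' each registration, the mean world displacement (mm) of the moving
#' volume's in-brain voxels under the recovered transform. The most
#' typical volume is the target whose movers need the least average
#' warping; ties break to the lowest index.
#'
#' @param volumes list of [brain_volume]s (>= 2).
#' @param cfg a [registration_config].
#' @param brain_quantile in-brain voxels are those above this quantile
#'   fraction of the maximum intensity.
#' @return `list(index, warp_matrix)` where `warp_matrix[i, j]` is the
#'   displacement of mover i registered to target j (0 on the diagonal).
#' @export
select_most_typical <- function(volumes, cfg = registration_config(),
                                brain_quantile = 0.1) {
  n <- length(volumes)
  if (n < 2) stop("need at least 2 volumes")
  W <- matrix(0, n, n)
  for (j in seq_len(n)) for (i in seq_len(n)) {
    if (i == j) next
    tr <- tryCatch(affine_register(volumes[[i]], volumes[[j]], cfg),
                   error = function(e)
                     stop(sprintf("registration failed for pair (%d -> %d): %s",
                                  i, j, conditionMessage(e))))
    W[i, j] <- warp_magnitude(tr, volumes[[i]], brain_quantile)
  }
  score <- colSums(W) / (n - 1)
  list(index = which.min(score), warp_matrix = W, mean_warp = score)
}

# intensity-weighted centre of mass in world coordinates
intensity_com <- function(vol) {
  a <- vol$data
  a <- a - min(a)
  w <- as.numeric(a) / sum(a)
  d <- dim(a)
  idx <- seq_along(w) - 1
  ijk <- cbind(idx %% d[1], (idx %/% d[1]) %% d[2], idx %/% (d[1] * d[2]))
  colSums(vox_to_world(vol, ijk) * w)
}

# mean world displacement (mm) of in-brain voxels under a transform
warp_magnitude <- function(tr, vol, brain_quantile = 0.1) {
  mask <- vol$data > brain_quantile * max(vol$data)
  idx <- which(mask) - 1L
  d <- dim(vol$data)
  ijk <- cbind(idx %% d[1], (idx %/% d[1]) %% d[2], idx %/% (d[1] * d[2]))
  w <- vox_to_world(vol, ijk)
  w2 <- apply_transform(tr, w)
  mean(sqrt(rowSums((w2 - w)^2)))
}
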