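#' Tract-skeleton statistics
#'
#' Mean-FA construction, skeletonization at the FA >= 0.2 convention,
#' projection of individual FA onto the skeleton, two-group permutation
#' testing with threshold-free cluster enhancement (TFCE), and extraction
#' of significant clusters for the four sex-by-direction contrasts.
#'
#' @name skeleton_stats
NULL

#' Voxelwise mean of aligned FA volumes
#'
#' @param aligned_fa list of [brain_volume]s on one common grid.
#' @return A [brain_volume] holding the voxelwise mean.
#' @export
build_mean_fa <- function(aligned_fa) {
  stopifnot(length(aligned_fa) >= 1)
  d <- dim(aligned_fa[[1]]$data)
  for (v in aligned_fa) {
    if (!all(dim(v$data) == d) ||
        max(abs(v$affine - aligned_fa[[1]]$affine)) > 1e-6)
      stop("grid mismatch: FA volumes must share shape and affine")
  }
  acc <- Reduce(`+`, lapply(aligned_fa, function(v) v$data))
  brain_volume(acc / length(aligned_fa),
               spacing = aligned_fa[[1]]$spacing,
               affine = aligned_fa[[1]]$affine)
}

#' Skeletonize a mean-FA volume
#'
#' A voxel belongs to the skeleton iff its mean FA is at or above the
#' threshold (0.2, the white-matter convention) and it is a local maximum
#' along the tract-perpendicular direction. The perpendicular direction
#' is estimated from the local centre of gravity of the smoothed mean FA
#' (pointing across the tract); where the centre of gravity is ambiguous
#' (on-axis voxels) it falls back to the eigenvector of the
#' largest-magnitude eigenvalue of the Hessian of the smoothed mean FA
#' (sigma = 1 voxel), with the maximum required over both leading
#' directions on tube-like structures. This centre-of-gravity-first rule
#' suppresses the spurious tangential ring maxima a pure Hessian rule
#' produces on radially symmetric tracts. Perpendicular directions are
#' stored for the projection step.
#'
#' @param mean_fa a [brain_volume] with values in \[0, 1\].
#' @param fa_threshold minimum mean FA for skeleton membership.
#' @param sigma smoothing (voxels) before Hessian estimation.
#' @return An object of class `fa_skeleton`: fields `mask` (logical
#'   array), `vox` (0-based linear indices), `dirs` (n x 3 unit vectors,
#'   voxel units), `mean_fa`, `fa_threshold`.
#' @export
skeletonize <- function(mean_fa, fa_threshold = 0.2, sigma = 1) {
  stopifnot(inherits(mean_fa, "brain_volume"))
  d <- dim(mean_fa$data)
  sm <- gaussian_smooth(mean_fa$data, sigma)
  cand <- which(mean_fa$data >= fa_threshold)
  if (!length(cand)) {
    warning("no voxel reaches the FA threshold; empty skeleton")
    return(structure(list(mask = array(FALSE, d), vox = integer(0),
                          dirs = matrix(0, 0, 3), dirs2 = matrix(0, 0, 3),
                          tube_like = logical(0), mean_fa = mean_fa,
                          fa_threshold = fa_threshold),
                     class = "fa_skeleton"))
  }
  eig <- hessian_eigensystem(as.numeric(sm), d, as.integer(cand - 1L))
  idx0 <- cand - 1L
  ijk <- cbind(idx0 %% d[1], (idx0 %/% d[1]) %% d[2], idx0 %/% (d[1] * d[2]))
  smv <- brain_volume(sm, spacing = mean_fa$spacing, affine = mean_fa$affine)
  v0 <- sm[cand]
  # centre-of-gravity offset of the 3x3x3 neighbourhood, in voxel units
  cog <- cog_offsets(sm, cand)
  cog_norm <- sqrt(rowSums(cog^2))
  use_cog <- cog_norm > 0.1
  dirs <- eig$dir1
  dirs[use_cog, ] <- cog[use_cog, , drop = FALSE] / cog_norm[use_cog]
  # a genuine ridge point is strictly above the perpendicular mean; the
  # tolerance rejects plateau voxels where the profile is flat
  tol <- 1e-4 * diff(range(sm))
  is_max_along <- function(dir) {
    vp <- sample_points(smv, ijk + dir)
    vm <- sample_points(smv, ijk - dir)
    v0 >= vp & v0 >= vm & (v0 - (vp + vm) / 2) > tol
  }
  keep <- is_max_along(dirs)
  # on-axis tube voxels: the perpendicular is a plane, require the
  # maximum along both leading Hessian directions
  plane <- !use_cog & eig$tube_like
  if (any(plane)) {
    keep2 <- is_max_along(eig$dir2)
    keep[plane] <- keep[plane] & keep2[plane]
  }
  mask <- array(FALSE, d)
  mask[cand[keep]] <- TRUE
  structure(list(mask = mask, vox = as.integer(cand[keep] - 1L),
                 dirs = dirs[keep, , drop = FALSE],
                 dirs2 = eig$dir2[keep, , drop = FALSE],
                 tube_like = eig$tube_like[keep],
                 mean_fa = mean_fa, fa_threshold = fa_threshold),
            class = "fa_skeleton")
}

#' @export
print.fa_skeleton <- function(x, ...) {
  cat(sprintf("<fa_skeleton> %d voxels (FA >= %g)\n",
              length(x$vox), x$fa_threshold))
  invisible(x)
}

#' Project an individual FA map onto the skeleton
#'
#' Each skeleton voxel receives the maximum of the individual FA along
#' the +/- tract-perpendicular direction within the search radius,
#' absorbing residual misalignment of individual tracts relative to the
#' mean-FA skeleton. Where the perpendicular direction is degenerate
#' (tube-like centerlines, where the two leading Hessian eigenvalues are
#' comparable) the search covers both perpendicular directions.
#'
#' @param individual_fa a [brain_volume] on the skeleton's grid.
#' @param skel an `fa_skeleton`.
#' @param search_radius search half-length in voxels (0 = value at the
#'   voxel itself).
#' @return Numeric vector of projected FA, one value per skeleton voxel
#'   (in `skel$vox` order).
#' @export
project_onto_skeleton <- function(individual_fa, skel, search_radius = 4) {
  d <- dim(skel$mask)
  if (!all(dim(individual_fa$data) == d))
    stop("grid mismatch between FA volume and skeleton")
  n <- length(skel$vox)
  if (!n) return(numeric(0))
  idx0 <- skel$vox
  ijk <- cbind(idx0 %% d[1], (idx0 %/% d[1]) %% d[2], idx0 %/% (d[1] * d[2]))
  best <- individual_fa$data[idx0 + 1L]
  if (search_radius > 0) {
    tube <- if (is.null(skel$tube_like)) rep(FALSE, n) else skel$tube_like
    for (t in seq_len(search_radius)) {
      best <- pmax(best, sample_points(individual_fa, ijk + t * skel$dirs),
                   sample_points(individual_fa, ijk - t * skel$dirs))
      if (any(tube)) {
        v2p <- sample_points(individual_fa, ijk + t * skel$dirs2)
        v2m <- sample_points(individual_fa, ijk - t * skel$dirs2)
        best[tube] <- pmax(best[tube], v2p[tube], v2m[tube])
      }
    }
  }
  best
}

#' Threshold-free cluster enhancement
#'
#' TFCE integrates, over all thresholds h (step `dh`) up to each voxel's
#' height, extent^E x h^H, where the extent is the size of the connected
#' component containing the voxel at threshold h. Positive and negative
#' parts of the map are enhanced separately (the negative part via
#' enhancement of its negation).
#'
#' @param x a [brain_volume] or a numeric statistic vector (with `skel`).
#' @param E,H extent and height exponents (volumetric convention 0.5/2;
#'   skeleton convention 1/2).
#' @param dh threshold step; `NULL` uses max(|stat|)/`nsteps` per sign.
#' @param nsteps number of integration steps when `dh` is `NULL`.
#' @param connectivity 6 or 26.
#' @param skel an `fa_skeleton`; required when `x` is a vector, in which
#'   case connectivity is restricted to skeleton voxels.
#' @return Enhanced map, same form as the input.
#' @export
tfce <- function(x, E = 0.5, H = 2, dh = NULL, nsteps = 100L,
                 connectivity = 26L, skel = NULL) {
  stopifnot(H >= 0, E >= 0)
  if (inherits(x, "brain_volume")) {
    d <- dim(x$data)
    stat <- as.numeric(x$data)
    support <- which(stat != 0)
    out <- numeric(length(stat))
    if (length(support)) {
      adj <- build_adjacency(as.integer(support - 1L), d, connectivity)
      sub <- stat[support]
      enh <- tfce_signed(sub, adj, E, H, dh, nsteps)
      out[support] <- enh
    }
    return(brain_volume(array(out, d), spacing = x$spacing,
                        affine = x$affine))
  }
  if (is.null(skel)) stop("vector input needs a skeleton for adjacency")
  adj <- skeleton_adjacency(skel, connectivity)
  tfce_signed(as.numeric(x), adj, E, H, dh, nsteps)
}

tfce_signed <- function(stat, adj, E, H, dh, nsteps) {
  dh_arg <- if (is.null(dh)) -1 else dh
  pos <- tfce_graph(pmax(stat, 0), adj$a, adj$b, E, H, dh_arg, nsteps)
  neg <- tfce_graph(pmax(-stat, 0), adj$a, adj$b, E, H, dh_arg, nsteps)
  pos - neg
}

skeleton_adjacency <- function(skel, connectivity = 26L) {
  build_adjacency(as.integer(skel$vox), dim(skel$mask), connectivity)
}

# centre-of-gravity offsets (voxel units) of the 3^3 neighbourhood of
# each candidate voxel (1-based linear indices), weighted by intensity
cog_offsets <- function(a, cand) {
  d <- dim(a)
  idx0 <- cand - 1L
  i <- idx0 %% d[1]; j <- (idx0 %/% d[1]) %% d[2]; k <- idx0 %/% (d[1] * d[2])
  num <- matrix(0, length(cand), 3)
  den <- numeric(length(cand))
  for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
    ii <- pmin(pmax(i + di, 0L), d[1] - 1L)
    jj <- pmin(pmax(j + dj, 0L), d[2] - 1L)
    kk <- pmin(pmax(k + dk, 0L), d[3] - 1L)
    w <- a[ii + d[1] * (jj + d[2] * kk) + 1L]
    num[, 1] <- num[, 1] + w * di
    num[, 2] <- num[, 2] + w * dj
    num[, 3] <- num[, 3] + w * dk
    den <- den + w
  }
  num / pmax(den, .Machine$double.eps)
}

# pooled-variance two-sample t statistics, one per column of X
# rows of X are subjects; `ina` logical selector for group A
t_stat_matrix <- function(X, ina) {
  na <- sum(ina); nb <- sum(!ina)
  sa <- colSums(X[ina, , drop = FALSE])
  sb <- colSums(X[!ina, , drop = FALSE])
  sq <- colSums(X^2)
  ssw <- sq - sa^2 / na - sb^2 / nb
  ssw[ssw < 0] <- 0
  sp2 <- ssw / (na + nb - 2)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  tt <- (sa / na - sb / nb) / se
  tt[!is.finite(tt)] <- 0 # constant voxels carry no evidence
  tt
}

#' Two-group permutation test with TFCE on the skeleton
#'
#' Computes the pooled-variance unpaired t statistic per skeleton voxel,
#' enhances it with TFCE, and corrects for family-wise error with the
#' maximum-TFCE permutation null: group labels are permuted (all distinct
#' assignments enumerated when there are no more than `n_perm`, otherwise
#' `n_perm` distinct assignments sampled without replacement), and each
#' voxel's corrected p is the fraction of permutation maxima at or above
#' its observed TFCE score. Both one-sided directions are returned.
#'
#' @param values animals x skeleton-voxels matrix of projected FA.
#' @param labels length-`nrow(values)` factor or character with exactly
#'   two levels; the first level is group A.
#' @param skel the `fa_skeleton` the columns refer to.
#' @param n_perm number of permutations (the study convention is 500).
#' @param E,H,nsteps TFCE parameters (skeleton convention E = 1, H = 2).
#' @param connectivity neighbourhood used on the skeleton.
#' @param alpha significance level recorded in the results.
#' @param seed integer seed for permutation sampling.
#' @param labels_a_gt_b,labels_b_gt_a contrast names for the two
#'   directions.
#' @return List of two `contrast_result` objects (`a_gt_b`, `b_gt_a`),
#'   each with the TFCE map, corrected p values on the skeleton, and the
#'   permutation maxima.
#' @export
permutation_group_test <- function(values, labels, skel, n_perm = 500L,
                                   E = 1, H = 2, nsteps = 100L,
                                   connectivity = 26L, alpha = 0.05,
                                   seed = 1L,
                                   labels_a_gt_b = "A_gt_B",
                                   labels_b_gt_a = "B_gt_A") {
  labels <- as.factor(labels)
  if (nlevels(labels) != 2L) stop("labels must have exactly two levels")
  if (any(table(labels) < 2L)) stop("need >= 2 animals per group")
  if (nrow(values) != length(labels))
    stop("values rows must match labels")
  n <- nrow(values)
  ina_obs <- labels == levels(labels)[1]
  na <- sum(ina_obs)
  adj <- skeleton_adjacency(skel, connectivity)
  t_obs <- t_stat_matrix(values, ina_obs)
  tfce_pos <- tfce_graph(pmax(t_obs, 0), adj$a, adj$b, E, H, -1, nsteps)
  tfce_neg <- tfce_graph(pmax(-t_obs, 0), adj$a, adj$b, E, H, -1, nsteps)

  n_distinct <- choose(n, na)
  exact <- n_distinct <= n_perm
  combos <- if (exact) {
    utils::combn(n, na, simplify = FALSE)
  } else {
    with_seed(seed, {
      seen <- new.env(hash = TRUE)
      out <- vector("list", n_perm)
      got <- 0L
      while (got < n_perm) {
        cmb <- sort(sample.int(n, na))
        key <- paste(cmb, collapse = ",")
        if (is.null(seen[[key]])) {
          seen[[key]] <- TRUE
          got <- got + 1L
          out[[got]] <- cmb
        }
      }
      out
    })
  }
  P <- matrix(FALSE, length(combos), n)
  for (i in seq_along(combos)) P[i, combos[[i]]] <- TRUE
  Tperm <- perm_t_matrix(values, P)
  max_pos <- tfce_graph_max_batch(Tperm, adj$a, adj$b, E, H, nsteps)
  max_neg <- tfce_graph_max_batch(-Tperm, adj$a, adj$b, E, H, nsteps)
  p_from_null <- function(obs, null_max) {
    # tolerance guards the observed-assignment tie against roundoff
    cnt <- vapply(obs, function(o)
      sum(null_max >= o - 1e-8 * (1 + abs(o))), numeric(1))
    if (exact) cnt / length(null_max)
    else (1 + cnt) / (1 + length(null_max))
  }
  p_pos <- p_from_null(tfce_pos, max_pos)
  p_neg <- p_from_null(tfce_neg, max_neg)
  mk <- function(label, tfce_skel, p_skel, null_max) {
    d <- dim(skel$mask)
    tf <- array(0, d); tf[skel$vox + 1L] <- tfce_skel
    pm <- array(1, d); pm[skel$vox + 1L] <- p_skel
    structure(list(
      label = label,
      tfce_map = brain_volume(tf, spacing = skel$mean_fa$spacing,
                              affine = skel$mean_fa$affine),
      corrected_p_map = brain_volume(pm, spacing = skel$mean_fa$spacing,
                                     affine = skel$mean_fa$affine),
      p_skel = p_skel, tfce_skel = tfce_skel, skel = skel,
      null_max = null_max, n_permutations = length(combos),
      exact_enumeration = exact, alpha = alpha, clusters = NULL),
      class = "contrast_result")
  }
  list(a_gt_b = mk(labels_a_gt_b, tfce_pos, p_pos, max_pos),
       b_gt_a = mk(labels_b_gt_a, tfce_neg, p_neg, max_neg))
}

# t statistics for many permutations at once (rows of P select group A)
perm_t_matrix <- function(X, P) {
  n <- nrow(X)
  na <- sum(P[1, ]); nb <- n - na
  S <- colSums(X)
  Sq <- colSums(X^2)
  SA <- P %*% X                      # nperm x nvox group-A sums
  SB <- matrix(S, nrow(P), ncol(X), byrow = TRUE) - SA
  SSW <- matrix(Sq, nrow(P), ncol(X), byrow = TRUE) -
    SA^2 / na - SB^2 / nb
  SSW[SSW < 0] <- 0
  SE <- sqrt(SSW / (n - 2) * (1 / na + 1 / nb))
  TT <- (SA / na - SB / nb) / SE
  TT[!is.finite(TT)] <- 0
  TT
}

#' @export
print.contrast_result <- function(x, ...) {
  cat(sprintf("<contrast_result> %s: %d/%d skeleton voxels with p < %g (%s, %d perms)\n",
              x$label, sum(x$p_skel < x$alpha), length(x$p_skel), x$alpha,
              if (x$exact_enumeration) "exact" else "sampled",
              x$n_permutations))
  invisible(x)
}

#' Extract significant clusters from a contrast result
#'
#' 26-connected components of the skeleton voxels with corrected
#' p < alpha, sorted by size (descending; ties by first raster voxel),
#' with deterministic ids.
#'
#' @param result a `contrast_result`.
#' @param alpha significance threshold on the corrected p values.
#' @param connectivity 6 or 26.
#' @return The `contrast_result` with its `clusters` field set to a list
#'   of clusters (`id`, `voxels` 0-based linear indices, `size`,
#'   `peak_stat`).
#' @export
extract_clusters <- function(result, alpha = 0.05, connectivity = 26L) {
  skel <- result$skel
  d <- dim(skel$mask)
  sig <- logical(prod(d))
  sig[skel$vox[result$p_skel < alpha] + 1L] <- TRUE
  if (!any(sig)) {
    result$clusters <- list()
    return(result)
  }
  lab <- cc_label(sig, d, connectivity)
  ids <- sort(unique(lab[lab > 0]))
  clusters <- lapply(ids, function(id) {
    vox <- which(lab == id) - 1L
    tf <- result$tfce_map$data[vox + 1L]
    list(voxels = as.integer(vox), size = length(vox),
         peak_stat = max(tf), first_vox = min(vox))
  })
  ord <- order(-vapply(clusters, `[[`, numeric(1), "size"),
               vapply(clusters, `[[`, numeric(1), "first_vox"))
  clusters <- clusters[ord]
  for (i in seq_along(clusters)) {
    clusters[[i]]$id <- i
    clusters[[i]]$first_vox <- NULL
  }
  result$clusters <- clusters
  result
}
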